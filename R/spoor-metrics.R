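#' Discard old and duplicate spoor
#'
#' Applies the standard field rules: a track is dropped when it is judged
#' more than 24 hours old, or when it is flagged as a repeat of an earlier
#' record of the same individual or group on that transect that day.
#' Records with unknown age are kept (only a positive judgement of age
#' removes a track). Order is otherwise preserved.
#'
#' @param records records data frame (or a [survey_dataset()], whose records
#'   are filtered in place).
#' @param max_age_hours retention threshold in hours (default 24).
#' @return Object of the same type with offending records removed.
#' @export
filter_spoor <- function(records, max_age_hours = 24) {
  if (inherits(records, "survey_dataset")) {
    records$records <- filter_spoor(records$records, max_age_hours)
    return(records)
  }
  old <- !is.na(records$age_hours) & records$age_hours > max_age_hours
  dup <- !is.na(records$duplicate_of)
  out <- records[!(old | dup), , drop = FALSE]
  # surviving duplicate_of indices would dangle; all are NA by construction
  rownames(out) <- NULL
  out
}

#' Spoor density
#'
#' Number of spoor per 100 km of transect driven.
#'
#' @param n_spoor spoor count (vectorised).
#' @param surveyed_km total kilometres driven (all passes).
#' @return Spoor per 100 km.
#' @export
spoor_density <- function(n_spoor, surveyed_km) {
  if (any(!is.finite(surveyed_km)) || any(surveyed_km <= 0)) {
    stop("surveyed_km must be > 0", call. = FALSE)
  }
  100 * n_spoor / surveyed_km
}

#' Spoor frequency
#'
#' Kilometres of transect driven between spoor of a species: the reciprocal
#' of [spoor_density()] scaled by 100.
#'
#' @param surveyed_km total kilometres driven.
#' @param n_spoor spoor count, at least 1.
#' @return km per spoor.
#' @export
spoor_frequency <- function(surveyed_km, n_spoor) {
  if (any(n_spoor < 1)) {
    stop("spoor frequency undefined for n_spoor = 0 (no spoor)",
         call. = FALSE)
  }
  surveyed_km / n_spoor
}

#' Inter-spoor intervals on the combined transect axis
#'
#' Concatenates transect passes into one linear axis and returns the
#' successive distances between consecutive spoor of one species in one
#' land-use type. With `n` spoor the result has `n - 1` gaps (empty for 0 or
#' 1 spoor). Gaps span empty passes: the axis is the full surveyed length.
#'
#' @param dataset a filtered [survey_dataset()].
#' @param species species to extract.
#' @param lut land-use type to extract.
#' @param ordering optional data frame with columns `transect_id`, `pass`
#'   giving the concatenation order of every pass in the land-use type.
#'   Default: chronological order (pass date where recoverable from the
#'   records, then transect id).
#' @return Numeric vector of km gaps.
#' @export
inter_spoor_intervals <- function(dataset, species, lut, ordering = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  pt <- pass_table(dataset)
  pt <- pt[pt$lut == lut, , drop = FALSE]
  if (!is.null(ordering)) {
    key <- paste(pt$transect_id, pt$pass)
    want <- paste(ordering$transect_id, ordering$pass)
    if (!setequal(key, want) || anyDuplicated(want)) {
      stop("ordering must list every (transect, pass) in '", lut,
           "' exactly once", call. = FALSE)
    }
    pt <- pt[match(want, key), , drop = FALSE]
  }
  rec <- dataset$records
  rec <- rec[rec$species == species & rec$lut == lut, , drop = FALSE]
  if (nrow(rec) == 0L) return(numeric(0))

  # offset of each pass on the combined axis
  offs <- c(0, cumsum(pt$length_km))[seq_len(nrow(pt))]
  # map each record to its pass: k-th distinct date on its transect
  pos <- vapply(seq_len(nrow(rec)), function(i) {
    id <- rec$transect_id[i]
    rows <- which(pt$transect_id == id)
    if (!length(rows)) {
      stop("ordering omits transect '", id, "' which carries records",
           call. = FALSE)
    }
    k <- 1L
    dts <- pt$date[rows]
    hit <- which(!is.na(dts) & dts == rec$recorded_on[i])
    if (length(hit)) k <- hit[1L] else k <- 1L
    offs[rows[k]] + rec$position_km[i]
  }, numeric(1))
  diff(sort(pos))
}

#' Survey effort summary by land-use type
#'
#' One row per land-use type: stratum area, single-pass transect sum, the
#' coverage heuristic "sample penetration" (km2 of area per km of transect;
#' values near 7 are conventionally considered adequate) and total surveyed
#' km over all passes. Penetration is reported at 1 decimal place.
#'
#' @param dataset a [survey_dataset()] with strata.
#' @return data frame with columns `lut`, `area_km2`, `transect_sum_km`,
#'   `sample_penetration`, `surveyed_km`.
#' @export
effort_summary <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  eff <- effort_by_lut(dataset$transects)
  st <- dataset$strata
  eff$area_km2 <- st$area_km2[match(eff$lut, st$lut)]
  eff$sample_penetration <- round(eff$area_km2 / eff$transect_sum_km, 1)
  eff[c("lut", "area_km2", "transect_sum_km", "sample_penetration",
        "surveyed_km")]
}

#' Spoor density matrix (species by land-use type)
#'
#' Cell (s, l) is the spoor density of species s in land-use type l over all
#' surveyed km of that type; species with no records get 0.
#'
#' @param dataset a filtered [survey_dataset()].
#' @param species character vector of species (rows); defaults to the six
#'   focal large carnivores.
#' @return Numeric matrix, species in rows, land-use types in columns.
#' @export
density_matrix <- function(dataset, species = SPECIES_LEVELS) {
  stopifnot(inherits(dataset, "survey_dataset"))
  eff <- effort_by_lut(dataset$transects)
  luts <- eff$lut
  m <- matrix(0, nrow = length(species), ncol = length(luts),
              dimnames = list(species, luts))
  rec <- dataset$records
  for (l in luts) {
    km <- eff$surveyed_km[eff$lut == l]
    for (s in species) {
      n <- sum(rec$species == s & rec$lut == l)
      m[s, l] <- spoor_density(n, km)
    }
  }
  m
}
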