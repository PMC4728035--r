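LAND_CATEGORIES <- c("large_scale_private", "small_scale_private",
                     "old_resettlement", "new_resettlement", "communal",
                     "parks_forest", "other")

#' National land-distribution ledger
#'
#' Areas (million ha) per land-use category at two epochs bracketing the
#' fast-track land reform programme. Each epoch must sum to the national
#' total within 0.05 million ha.
#'
#' @param areas_2000,areas_2010 named numeric vectors over the categories
#'   large_scale_private, small_scale_private, old_resettlement,
#'   new_resettlement, communal, parks_forest, other.
#' @param total_mha national land area in million ha (default 39.1).
#' @return An object of class `land_ledger`.
#' @export
land_ledger <- function(areas_2000, areas_2010, total_mha = 39.1) {
  for (a in list(areas_2000, areas_2010)) {
    missing <- setdiff(LAND_CATEGORIES, names(a))
    if (length(missing)) {
      stop("missing land categor(ies): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (abs(sum(a) - total_mha) > 0.05) {
      stop("epoch areas sum to ", sum(a), ", expected ", total_mha,
           call. = FALSE)
    }
  }
  structure(list(areas_2000 = areas_2000[LAND_CATEGORIES],
                 areas_2010 = areas_2010[LAND_CATEGORIES],
                 total_mha = total_mha),
            class = "land_ledger")
}

#' Zimbabwe land distribution, 2000 vs 2010
#'
#' The national ledger before the onset of fast-track land reform and a
#' decade in: large-scale private farms shrank from 11.7 to 3.4 million ha
#' while new resettlement grew from 0 to 7.6 million ha, of 39.1 million ha
#' total.
#'
#' @return A [land_ledger()].
#' @export
zimbabwe_ledger <- function() {
  land_ledger(
    areas_2000 = c(large_scale_private = 11.7, small_scale_private = 1.4,
                   old_resettlement = 3.5, new_resettlement = 0.0,
                   communal = 16.4, parks_forest = 5.1, other = 1.0),
    areas_2010 = c(large_scale_private = 3.4, small_scale_private = 1.4,
                   old_resettlement = 3.5, new_resettlement = 7.6,
                   communal = 16.4, parks_forest = 5.1, other = 1.7)
  )
}

#' Land shares per category
#'
#' Percentage of the national total per category at one epoch, at 1 decimal
#' place.
#'
#' @param ledger a [land_ledger()].
#' @param epoch `"2000"` or `"2010"`.
#' @return Named numeric vector of percentages.
#' @export
land_shares <- function(ledger, epoch = c("2000", "2010")) {
  stopifnot(inherits(ledger, "land_ledger"))
  epoch <- match.arg(epoch)
  a <- ledger[[paste0("areas_", epoch)]]
  round(100 * a / ledger$total_mha, 1)
}

#' Fraction of large-scale private land resettled
#'
#' `(area_2000 - area_2010) / area_2000` for large-scale private farms.
#'
#' @param ledger a [land_ledger()].
#' @return Fraction in [0, 1].
#' @export
fraction_private_resettled <- function(ledger) {
  stopifnot(inherits(ledger, "land_ledger"))
  a0 <- ledger$areas_2000[["large_scale_private"]]
  a1 <- ledger$areas_2010[["large_scale_private"]]
  if (a0 <= 0) stop("no private land in 2000", call. = FALSE)
  (a0 - a1) / a0
}

#' Build a national decline scenario
#'
#' @param species character vector.
#' @param share_private fraction of each species' national population on
#'   large-scale private land before reform, in [0, 1].
#' @param fraction_resettled fraction of private land lost to resettlement,
#'   in [0, 1] (scalar or per species).
#' @param retention fraction of carnivores surviving on resettled land, in
#'   [0, 1] (default 0: resettled land supports none).
#' @return An object of class `decline_scenario`.
#' @export
decline_scenario <- function(species, share_private, fraction_resettled,
                             retention = 0) {
  fr <- rep_len(fraction_resettled, length(species))
  rt <- rep_len(retention, length(species))
  sp <- rep_len(share_private, length(species))
  for (x in list(sp, fr, rt)) {
    if (any(x < 0 | x > 1)) stop("all fractions must be in [0, 1]",
                                 call. = FALSE)
  }
  structure(data.frame(species = species, share_private = sp,
                       fraction_resettled = fr, retention = rt),
            class = c("decline_scenario", "data.frame"))
}

#' National population decline under a land-reform scenario
#'
#' Proportional-loss model: the share of a species' national population that
#' sat on large-scale private land is reduced by the fraction of that land
#' resettled, discounted by any survival on resettled land:
#' `decline = 100 * share_private * fraction_resettled * (1 - retention)`
#' percent. Species depending more on private land decline more.
#'
#' @param scenario a [decline_scenario()].
#' @return List with `per_species` (named percentages), `mean`, `max`.
#' @export
national_decline <- function(scenario) {
  stopifnot(inherits(scenario, "decline_scenario"))
  d <- 100 * scenario$share_private * scenario$fraction_resettled *
    (1 - scenario$retention)
  names(d) <- scenario$species
  list(per_species = d, mean = mean(d), max = max(d))
}

#' Area share of a land pool
#'
#' Expresses a reserve area (km2) as a percentage of a national land pool
#' (million ha), at 1 decimal place. 1 million ha = 10,000 km2.
#'
#' @param part_km2 area in km2.
#' @param total_mha pool size in million ha (> 0).
#' @return Percentage.
#' @export
area_share <- function(part_km2, total_mha) {
  if (any(total_mha <= 0)) stop("total_mha must be > 0", call. = FALSE)
  round(100 * part_km2 / (total_mha * 1e4), 1)
}
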