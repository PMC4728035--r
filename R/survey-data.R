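#' Assemble a spoor survey dataset
#'
#' Bundles spoor records, the transect register and stratum areas into a
#' validated `survey_dataset` object, the unit every downstream stage
#' consumes.
#'
#' @param records data frame with columns `species`, `transect_id`,
#'   `position_km`, `group_size`, `recorded_on` (ISO-8601 date), `age_hours`
#'   (hours since the track was made, `NA` if unknown), `duplicate_of`
#'   (1-based row index of the earlier record this one duplicates, `NA` if
#'   none) and `lut` (land-use type: `"private"`, `"resettlement"` or
#'   `"communal"`).
#' @param transects data frame with columns `transect_id`, `lut`,
#'   `length_km`, `passes` (number of times the transect was driven).
#' @param strata data frame with columns `lut`, `area_km2`.
#' @param check if `TRUE` (default) fail on any invariant violation.
#'
#' @return An object of class `survey_dataset`: a list with elements
#'   `records`, `transects` and `strata`.
#' @seealso [read_survey()], [validate_survey()]
#' @export
survey_dataset <- function(records, transects, strata, check = TRUE) {
  records <- normalize_records(records)
  transects <- normalize_transects(transects)
  strata <- normalize_strata(strata)
  ds <- structure(list(records = records, transects = transects,
                       strata = strata),
                  class = "survey_dataset")
  if (check) {
    v <- validate_survey(ds)
    if (length(v)) {
      stop("invalid survey dataset:\n  ", paste(v, collapse = "\n  "),
           call. = FALSE)
    }
  }
  ds
}

RECORD_COLS <- c("species", "transect_id", "position_km", "group_size",
                 "recorded_on", "age_hours", "duplicate_of", "lut")
TRANSECT_COLS <- c("transect_id", "lut", "length_km", "passes")
STRATUM_COLS <- c("lut", "area_km2")

#' @noRd
normalize_records <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L && ncol(records) == 0L) {
    records <- data.frame(species = character(), transect_id = character(),
                          position_km = numeric(), group_size = integer(),
                          recorded_on = as.Date(character()),
                          age_hours = numeric(), duplicate_of = integer(),
                          lut = character())
  }
  missing <- setdiff(RECORD_COLS, names(records))
  if (length(missing)) {
    stop("records are missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(records), RECORD_COLS)
  if (length(extra)) {
    warning("ignoring unknown record column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  records <- records[RECORD_COLS]
  records$species <- as.character(records$species)
  records$transect_id <- as.character(records$transect_id)
  records$position_km <- as.numeric(records$position_km)
  records$group_size <- as.integer(records$group_size)
  records$recorded_on <- as.Date(records$recorded_on)
  records$age_hours <- as.numeric(records$age_hours)
  records$duplicate_of <- as.integer(records$duplicate_of)
  records$lut <- as.character(records$lut)
  rownames(records) <- NULL
  records
}

#' @noRd
normalize_transects <- function(transects) {
  transects <- as.data.frame(transects)
  missing <- setdiff(TRANSECT_COLS, names(transects))
  if (length(missing)) {
    stop("transects are missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  transects <- transects[TRANSECT_COLS]
  transects$transect_id <- as.character(transects$transect_id)
  transects$lut <- as.character(transects$lut)
  transects$length_km <- as.numeric(transects$length_km)
  transects$passes <- as.integer(transects$passes)
  rownames(transects) <- NULL
  transects
}

#' @noRd
normalize_strata <- function(strata) {
  strata <- as.data.frame(strata)
  missing <- setdiff(STRATUM_COLS, names(strata))
  if (length(missing)) {
    stop("strata are missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  strata <- strata[STRATUM_COLS]
  strata$lut <- as.character(strata$lut)
  strata$area_km2 <- as.numeric(strata$area_km2)
  rownames(strata) <- NULL
  strata
}

#' Read a spoor survey from delimited text files
#'
#' Expects `records.csv`, `transects.csv` and `strata.csv` in `dir` (or the
#' three paths given explicitly). Comma-delimited by default; tab accepted
#' via `sep = "\t"`. Unknown columns are dropped with a warning; a missing
#' mandatory column is an error naming the column.
#'
#' @param dir directory containing `records.csv`, `transects.csv`,
#'   `strata.csv`.
#' @param records,transects,strata explicit file paths, overriding `dir`.
#' @param sep field separator (`","` default, `"\t"` accepted).
#' @param check validate invariants after reading (default `TRUE`).
#'
#' @return A [survey_dataset()].
#' @export
read_survey <- function(dir = NULL, records = NULL, transects = NULL,
                        strata = NULL, sep = ",", check = TRUE) {
  if (!is.null(dir)) {
    records <- records %||% file.path(dir, "records.csv")
    transects <- transects %||% file.path(dir, "transects.csv")
    strata <- strata %||% file.path(dir, "strata.csv")
  }
  for (p in c(records, transects, strata)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  rd <- function(p) utils::read.table(p, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE,
                                      na.strings = c("NA", ""))
  survey_dataset(rd(records), rd(transects), rd(strata), check = check)
}

#' Write a spoor survey to delimited text files
#'
#' Writes `records.csv`, `transects.csv` and `strata.csv` into `dir` such
#' that [read_survey()] reproduces the dataset field-for-field.
#'
#' @param dataset a [survey_dataset()].
#' @param dir output directory (created if absent).
#' @param sep field separator.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(dataset, dir, sep = ",") {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  wr <- function(df, p) {
    utils::write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "NA")
  }
  wr(dataset$records, file.path(dir, "records.csv"))
  wr(dataset$transects, file.path(dir, "transects.csv"))
  wr(dataset$strata, file.path(dir, "strata.csv"))
  invisible(dir)
}

#' Validate a spoor survey dataset
#'
#' Checks every type invariant and returns violations as character messages
#' (empty when the dataset is valid). Violations are data, not errors.
#'
#' @param dataset a `survey_dataset` (checked structurally, not assumed
#'   valid).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_survey <- function(dataset) {
  v <- character()
  say <- function(...) v <<- c(v, paste0(...))
  rec <- dataset$records
  tr <- dataset$transects
  st <- dataset$strata

  if (anyDuplicated(tr$transect_id)) {
    dup <- unique(tr$transect_id[duplicated(tr$transect_id)])
    say("transect id(s) not unique: ", paste(dup, collapse = ", "))
  }
  for (i in seq_len(nrow(tr))) {
    if (!tr$lut[i] %in% LUT_LEVELS) {
      say("transect ", tr$transect_id[i], ": unknown lut '", tr$lut[i], "'")
    }
    if (!is.finite(tr$length_km[i]) || tr$length_km[i] <= 0) {
      say("transect ", tr$transect_id[i], ": length_km must be > 0")
    }
    if (is.na(tr$passes[i]) || tr$passes[i] < 1L) {
      say("transect ", tr$transect_id[i], ": passes must be >= 1")
    }
    if (tr$lut[i] %in% LUT_LEVELS && !tr$lut[i] %in% st$lut) {
      say("transect ", tr$transect_id[i], ": lut '", tr$lut[i],
          "' has no stratum")
    }
  }
  if (anyDuplicated(st$lut)) say("duplicate stratum lut")
  for (i in seq_len(nrow(st))) {
    if (!st$lut[i] %in% LUT_LEVELS) say("stratum ", i, ": unknown lut")
    if (!is.finite(st$area_km2[i]) || st$area_km2[i] <= 0) {
      say("stratum ", st$lut[i], ": area_km2 must be > 0")
    }
  }

  if (nrow(rec)) {
    ti <- match(rec$transect_id, tr$transect_id)
    bad_sp <- which(!is_known_species(rec$species))
    for (i in bad_sp) say("record ", i, ": unknown species '",
                          rec$species[i], "'")
    unres <- which(is.na(ti))
    for (i in unres) say("record ", i, ": transect_id '",
                         rec$transect_id[i], "' not in register")
    ok <- !is.na(ti)
    len <- tr$length_km[ti]
    bad_pos <- which(ok & (!is.finite(rec$position_km) |
                             rec$position_km < 0 | rec$position_km > len))
    for (i in bad_pos) say("record ", i, ": position_km ",
                           rec$position_km[i], " outside [0, ", len[i],
                           "] on transect ", rec$transect_id[i])
    bad_gs <- which(is.na(rec$group_size) | rec$group_size < 1L)
    for (i in bad_gs) say("record ", i, ": group_size must be >= 1")
    bad_age <- which(!is.na(rec$age_hours) & rec$age_hours < 0)
    for (i in bad_age) say("record ", i, ": age_hours must be >= 0 or NA")
    bad_lut <- which(ok & tr$lut[ti] != rec$lut)
    for (i in bad_lut) say("record ", i, ": lut '", rec$lut[i],
                           "' disagrees with transect ", rec$transect_id[i],
                           " ('", tr$lut[ti[i]], "')")
    dup <- which(!is.na(rec$duplicate_of))
    for (i in dup) {
      j <- rec$duplicate_of[i]
      if (j < 1L || j >= i) {
        say("record ", i, ": duplicate_of must reference an earlier record")
      } else if (rec$transect_id[j] != rec$transect_id[i] ||
                 rec$species[j] != rec$species[i] ||
                 !identical(rec$recorded_on[j], rec$recorded_on[i])) {
        say("record ", i, ": duplicate_of ", j,
            " is not same transect/day/species")
      }
    }
  }
  v
}

#' @export
print.survey_dataset <- function(x, ...) {
  counts <- table(x$records$species)
  cat("<survey_dataset>\n")
  cat("  records:  ", nrow(x$records), " spoor (",
      paste(names(counts), counts, sep = "=", collapse = ", "), ")\n",
      sep = "")
  cat("  transects:", nrow(x$transects), "covering",
      sum(x$transects$length_km), "km,",
      sum(x$transects$length_km * x$transects$passes), "km surveyed\n")
  cat("  strata:   ", paste(x$strata$lut, x$strata$area_km2, sep = "=",
                            collapse = ", "), "km2\n")
  invisible(x)
}

# Per-LUT effort: single-pass transect sum and total surveyed km.
#' @noRd
effort_by_lut <- function(transects) {
  luts <- intersect(LUT_LEVELS, unique(transects$lut))
  data.frame(
    lut = luts,
    transect_sum_km = vapply(luts, function(l) {
      sum(transects$length_km[transects$lut == l])
    }, numeric(1)),
    surveyed_km = vapply(luts, function(l) {
      i <- transects$lut == l
      sum(transects$length_km[i] * transects$passes[i])
    }, numeric(1)),
    row.names = NULL
  )
}

# One row per (transect, pass) with the pass date where recoverable from the
# records (k-th distinct date seen on that transect = pass k); ordered
# chronologically (date, then transect id; undated passes last by pass
# index). This is the default "systematic combination" axis for
# inter-spoor intervals.
#' @noRd
pass_table <- function(dataset) {
  tr <- dataset$transects
  rec <- dataset$records
  out <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    id <- tr$transect_id[i]
    dates <- sort(unique(rec$recorded_on[rec$transect_id == id]))
    np <- tr$passes[i]
    data.frame(
      transect_id = id, lut = tr$lut[i], length_km = tr$length_km[i],
      pass = seq_len(np),
      date = if (length(dates)) c(dates, rep(as.Date(NA), max(0, np - length(dates))))[seq_len(np)]
             else rep(as.Date(NA), np)
    )
  }))
  ord <- order(is.na(out$date), out$date, out$pass, out$transect_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
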