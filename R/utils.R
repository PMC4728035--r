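#' @keywords internal
"_PACKAGE"

# Canonical land-use types and the focal species set. `species` in a record
# may also be free text ("other:<name>") for non-focal mammals.
LUT_LEVELS <- c("private", "resettlement", "communal")
SPECIES_LEVELS <- c("lion", "leopard", "cheetah", "wild_dog",
                    "spotted_hyaena", "brown_hyaena")

#' @noRd
is_known_species <- function(x) {
  x %in% SPECIES_LEVELS | grepl("^other:.+", x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All seeded operations in the package go through this so that a call never
# clobbers the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round() in R is round-half-even; population sizes are reported with the
# conventional half-away-from-zero rule.
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
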