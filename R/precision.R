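#' Bootstrap precision curve for inter-spoor intervals
#'
#' For each sample size n on a grid from 2 upwards, draws `n_bootstrap`
#' resamples of size n with replacement from the observed inter-spoor
#' intervals and records the mean of the resample means, the 2.5th/97.5th
#' percentiles (a 95% percentile interval) and the coefficient of variation
#' of the resample means (the "sampling precision"). Plotting mean and CI
#' against n shows how survey effort buys precision; the CV curve shows when
#' additional spoor stop improving it.
#'
#' @param intervals numeric vector of km gaps, length at least 2.
#' @param n_bootstrap resamples per sample size (default 1000, minimum 100).
#' @param seed integer seed; the curve is deterministic given it.
#' @param max_n largest sample size (default: `length(intervals)`).
#' @param stride grid step (default 1: every integer from 2 to `max_n`).
#' @param sizes optional explicit grid of sample sizes (overrides
#'   `max_n`/`stride`); must be increasing and all at least 2.
#' @return A `precision_curve`: data frame with columns `n`, `mean`,
#'   `ci_low`, `ci_high`, `cv`, with attributes `n_bootstrap` and `seed`.
#' @export
bootstrap_curve <- function(intervals, n_bootstrap = 1000, seed = 1,
                            max_n = NULL, stride = 1L, sizes = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L) {
    stop("need at least 2 inter-spoor intervals", call. = FALSE)
  }
  if (n_bootstrap < 100) stop("n_bootstrap must be >= 100", call. = FALSE)
  if (is.null(sizes)) {
    max_n <- max_n %||% length(intervals)
    sizes <- seq.int(2L, max_n, by = stride)
  } else {
    sizes <- as.integer(sizes)
    if (any(sizes < 2L) || is.unsorted(sizes, strictly = TRUE)) {
      stop("sizes must be strictly increasing and >= 2", call. = FALSE)
    }
  }
  res <- with_seed(seed, {
    t(vapply(sizes, function(n) {
      draws <- matrix(sample(intervals, n * n_bootstrap, replace = TRUE),
                      nrow = n)
      means <- colMeans(draws)
      m <- mean(means)
      ci <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
      cv <- if (m == 0) 0 else stats::sd(means) / m
      c(m, ci, cv)
    }, numeric(4)))
  })
  out <- data.frame(n = sizes, mean = res[, 1], ci_low = res[, 2],
                    ci_high = res[, 3], cv = res[, 4])
  structure(out, class = c("precision_curve", "data.frame"),
            n_bootstrap = n_bootstrap, seed = seed)
}

#' Locate where the precision curve stabilizes
#'
#' The field's by-eye judgement that variation stabilizes around some spoor
#' count is made operational: the stabilization point is the smallest grid
#' sample size n such that over the next `window` grid points the CV never
#' moves by more than `tolerance * cv(n)` in absolute value.
#'
#' @param curve a [bootstrap_curve()] result.
#' @param window number of subsequent grid points that must stay flat
#'   (default 10).
#' @param tolerance relative flatness threshold (default 0.15).
#' @return The stabilizing sample size, or `NA` if the curve never
#'   stabilizes within its grid.
#' @export
stabilization_point <- function(curve, window = 10L, tolerance = 0.15) {
  stopifnot(inherits(curve, "precision_curve"))
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  k <- nrow(curve)
  if (window >= k) {
    stop("window (", window, ") exceeds curve length (", k, ")",
         call. = FALSE)
  }
  cv <- curve$cv
  for (i in seq_len(k - window)) {
    ahead <- cv[(i + 1L):(i + window)]
    if (max(abs(ahead - cv[i])) <= tolerance * cv[i] ||
        all(ahead == cv[i])) {
      return(curve$n[i])
    }
  }
  NA_integer_
}

#' Bootstrap summary of spoor frequency at full sample size
#'
#' Percentile-bootstrap mean and 95% CI of the mean inter-spoor interval
#' (km per spoor), using all observed intervals.
#'
#' @inheritParams bootstrap_curve
#' @return List with elements `mean`, `ci` (length-2 numeric).
#' @export
spoor_frequency_summary <- function(intervals, n_bootstrap = 1000,
                                    seed = 1) {
  curve <- bootstrap_curve(intervals, n_bootstrap = n_bootstrap,
                           seed = seed, sizes = length(intervals))
  list(mean = curve$mean[1], ci = c(curve$ci_low[1], curve$ci_high[1]))
}

#' @export
print.precision_curve <- function(x, ...) {
  cat("<precision_curve> ", nrow(x), " sample sizes (",
      x$n[1], "..", x$n[nrow(x)], "), ", attr(x, "n_bootstrap"),
      " bootstrap replicates, seed ", attr(x, "seed"), "\n", sep = "")
  print(as.data.frame(utils::head(x, 4)))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}
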