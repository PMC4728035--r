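#' Midranks
#'
#' Ranks 1..N with tied values receiving the mean of the ranks they span,
#' so that the rank sum is exactly N(N+1)/2.
#'
#' @param values numeric vector, nonempty.
#' @return Numeric vector of ranks.
#' @export
midranks <- function(values) {
  if (!length(values)) stop("values must be nonempty", call. = FALSE)
  ord <- order(values)
  n <- length(values)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' Tests whether k independent groups come from the same distribution using
#' pooled midranks. The statistic is
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_j R_j^2 / n_j - 3(N+1)}
#'            {1 - \sum_t (t^3 - t)/(N^3 - N)}}
#' with \eqn{R_j} the group rank sums and t running over tie-group sizes;
#' the p-value uses the upper tail of the chi-square distribution with
#' k - 1 degrees of freedom. When every pooled value is identical the test
#' degenerates to H = 0, p = 1. An exact permutation p-value is available
#' for small samples via `permutation`.
#'
#' @param groups list of numeric vectors, each nonempty, at least 2 groups
#'   and 3 values overall.
#' @param permutation if > 0, also compute a Monte-Carlo permutation
#'   p-value from this many random relabellings (seeded by `seed`).
#' @param seed seed for the permutation p-value.
#' @return An object of class `rank_test`: list with `H`, `df`, `p_value`,
#'   `group_sizes`, `n_ties`, and `p_permutation` when requested.
#' @export
kruskal_wallis <- function(groups, permutation = 0, seed = 1) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be nonempty", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  if (N < 3L) stop("need at least 3 values overall", call. = FALSE)
  g <- rep(seq_along(groups), sizes)

  H <- kw_statistic(pooled, g)
  tie_sizes <- table(pooled)
  n_ties <- sum(tie_sizes > 1L)
  df <- length(groups) - 1L
  p <- if (is.na(H)) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  out <- list(H = if (is.na(H)) 0 else H, df = df, p_value = p,
              group_sizes = as.integer(sizes), n_ties = n_ties)
  if (permutation > 0) {
    obs <- out$H
    out$p_permutation <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(permutation)) {
        hb <- kw_statistic(pooled, sample(g))
        if (is.na(hb)) hb <- 0
        if (hb >= obs - 1e-12) hits <- hits + 1L
      }
      (hits + 1L) / (permutation + 1L)
    })
  }
  class(out) <- "rank_test"
  out
}

# Rank-sum form of the tie-corrected statistic; NA when all values tie
# (correction denominator 0), which callers map to H = 0.
#' @noRd
kw_statistic <- function(pooled, g) {
  N <- length(pooled)
  r <- midranks(pooled)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H0 <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  t <- table(pooled)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  if (corr <= 0) return(NA_real_)
  H0 / corr
}

#' @export
print.rank_test <- function(x, ...) {
  cat("Kruskal-Wallis rank test (tie-corrected)\n")
  cat(sprintf("  H = %.4f, df = %d, p = %.4g\n", x$H, x$df, x$p_value))
  cat("  group sizes:", paste(x$group_sizes, collapse = ", "),
      " tied groups:", x$n_ties, "\n")
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation p = %.4g\n", x$p_permutation))
  }
  invisible(x)
}

#' Compare spoor densities between land-use types
#'
#' Runs the tie-corrected Kruskal-Wallis test on the columns of the
#' species-by-land-use spoor [density_matrix()]: each land-use type
#' contributes one density value per species.
#'
#' @param dataset a filtered [survey_dataset()].
#' @param ... passed to [kruskal_wallis()].
#' @return A `rank_test`, with an extra `group_medians` element.
#' @export
compare_lut_densities <- function(dataset, ...) {
  m <- density_matrix(dataset)
  groups <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(groups) <- colnames(m)
  out <- kruskal_wallis(groups, ...)
  out$group_medians <- vapply(groups, stats::median, numeric(1))
  out
}
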