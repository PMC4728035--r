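# Shared fixtures and independent oracles, built in code.

# three records on two transects, all invariants satisfied
tiny_dataset <- function() {
  survey_dataset(
    records = data.frame(
      species = c("lion", "lion", "leopard"),
      transect_id = c("T1", "T1", "T2"),
      position_km = c(2, 5, 3.5),
      group_size = c(2L, 1L, 1L),
      recorded_on = as.Date("2008-10-01") + c(0, 0, 1),
      age_hours = c(3, 10, NA),
      duplicate_of = NA_integer_,
      lut = c("private", "private", "private")
    ),
    transects = data.frame(transect_id = c("T1", "T2"),
                           lut = "private", length_km = c(10, 8),
                           passes = 1L),
    strata = data.frame(lut = "private", area_km2 = 100)
  )
}

# random valid dataset for round-trip property tests
random_dataset <- function(seed) {
  set.seed(seed)
  nt <- sample(2:4, 1)
  luts <- sample(c("private", "resettlement", "communal"), nt,
                 replace = TRUE)
  tr <- data.frame(
    transect_id = sprintf("T%02d", seq_len(nt)), lut = luts,
    length_km = round(runif(nt, 5, 50), 1),
    passes = sample(1:3, nt, replace = TRUE)
  )
  n <- sample(0:30, 1)
  ti <- sample(nt, n, replace = TRUE)
  rec <- data.frame(
    species = sample(c("lion", "leopard", "wild_dog", "other:caracal"), n,
                     replace = TRUE),
    transect_id = tr$transect_id[ti],
    position_km = round(runif(n) * tr$length_km[ti], 3),
    group_size = sample(1:6, n, replace = TRUE),
    recorded_on = as.Date("2008-10-01") + sample(0:5, n, replace = TRUE),
    age_hours = ifelse(runif(n) < 0.2, NA, round(runif(n, 0.5, 48), 1)),
    duplicate_of = NA_integer_,
    lut = tr$lut[ti]
  )
  st <- data.frame(lut = unique(tr$lut),
                   area_km2 = round(runif(length(unique(tr$lut)), 100, 3000)))
  survey_dataset(rec, tr, st, check = FALSE)
}

# Independent Kruskal-Wallis oracle in the between/within rank-variance
# form: H = (N - 1) * sum n_j (Rbar_j - Rbar)^2 / sum (r_i - Rbar)^2.
# Algebraically equal to the tie-corrected rank-sum formula, computed by a
# different route (base-R rank() with ties.method = "average").
kw_oracle <- function(groups) {
  pooled <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(pooled)
  rb <- mean(r)
  num <- sum(tapply(r, g, function(x) length(x) * (mean(x) - rb)^2))
  den <- sum((r - rb)^2)
  if (den == 0) return(0)
  (length(pooled) - 1) * num / den
}

# exhaustive distribution of two-draw resample means
two_draw_means <- function(intervals) {
  g <- expand.grid(a = intervals, b = intervals)
  (g$a + g$b) / 2
}
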