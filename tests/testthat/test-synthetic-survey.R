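plan1 <- function(km = 100, passes = 1L) {
  data.frame(lut = "private", length_km = km, passes = passes)
}
dens1 <- function(d) {
  data.frame(species = "lion", lut = "private", density = d)
}

test_that("zero true density gives an empty survey", {
  cfg <- simulation_config(dens1(0), transect_plan = plan1(), seed = 3)
  ds <- simulate_survey(cfg)
  expect_equal(nrow(ds$records), 0L)
  expect_identical(validate_survey(ds), character(0))
})

test_that("simulation is bitwise reproducible for a fixed seed", {
  cfg <- make_svc_scenario(contamination = 0.2, seed = 11)
  expect_identical(simulate_survey(cfg), simulate_survey(cfg))
  # different seed, different draw
  cfg2 <- make_svc_scenario(contamination = 0.2, seed = 12)
  expect_false(identical(simulate_survey(cfg), simulate_survey(cfg2)))
})

test_that("genuine spoor counts are Poisson with the calibrated mean", {
  # slope 3.26, density 2.85, 696 km: mean 3.26 * 2.85 * 696 / 100 = 64.66
  mu <- 3.26 * 2.85 * 696 / 100
  counts <- vapply(1:2000, function(s) {
    cfg <- simulation_config(dens1(2.85), transect_plan = plan1(696),
                             seed = s)
    nrow(simulate_survey(cfg)$records)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # and the variance is Poisson-like, not degenerate
  expect_gt(var(counts), 0.7 * mu)
  expect_lt(var(counts), 1.3 * mu)
})

test_that("doubling true density doubles the mean count", {
  n1 <- vapply(1:2000, function(s) {
    nrow(simulate_survey(simulation_config(dens1(1.5),
                                           transect_plan = plan1(200),
                                           seed = s))$records)
  }, numeric(1))
  n2 <- vapply(1:2000, function(s) {
    nrow(simulate_survey(simulation_config(dens1(3.0),
                                           transect_plan = plan1(200),
                                           seed = 5000 + s))$records)
  }, numeric(1))
  se <- sqrt(var(n2) / 2000 + 4 * var(n1) / 2000)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * se)
})

test_that("contamination spawns flagged records at the configured rate", {
  # each genuine record spawns one contaminant with p = 0.5; over many
  # surveys flagged ~ Binomial(genuine, 0.5)
  tot <- c(genuine = 0, flagged = 0)
  for (s in 1:2000) {
    cfg <- simulation_config(dens1(3), transect_plan = plan1(30),
                             contamination = 0.5, seed = s)
    ds <- simulate_survey(cfg)
    rec <- ds$records
    flag <- (!is.na(rec$age_hours) & rec$age_hours > 24) |
      !is.na(rec$duplicate_of)
    tot["genuine"] <- tot["genuine"] + sum(!flag)
    tot["flagged"] <- tot["flagged"] + sum(flag)
  }
  bt <- binom.test(tot[["flagged"]], tot[["genuine"]], p = 0.5)
  expect_gt(bt$p.value, 0.001)
  # and filter_spoor removes exactly the flagged ones
  cfg <- simulation_config(dens1(5), transect_plan = plan1(200),
                           contamination = 0.3, seed = 77)
  ds <- simulate_survey(cfg)
  kept <- filter_spoor(ds$records)
  expect_true(all(is.na(kept$duplicate_of)))
  expect_true(all(kept$age_hours <= 24))
  genuine <- ds$records[is.na(ds$records$duplicate_of) &
                          ds$records$age_hours <= 24, ]
  rownames(genuine) <- NULL
  expect_equal(kept, genuine)
})

test_that("contaminated surveys still validate", {
  cfg <- make_svc_scenario(contamination = 0.4, seed = 9)
  expect_identical(validate_survey(simulate_survey(cfg)), character(0))
})

test_that("negative-binomial switch produces overdispersed counts", {
  counts <- vapply(1:800, function(s) {
    cfg <- simulation_config(dens1(3), transect_plan = plan1(696),
                             dispersion = 2, seed = s)
    nrow(simulate_survey(cfg)$records)
  }, numeric(1))
  mu <- 3.26 * 3 * 696 / 100
  expect_gt(var(counts), 1.5 * mu) # NB variance mu + mu^2/size >> mu
})

test_that("the svc scenario states the published world", {
  cfg <- make_svc_scenario()
  expect_equal(true_density(cfg, "lion", "private"), 2.85)
  expect_equal(true_density(cfg, "spotted_hyaena", "resettlement"), 0.61)
  for (s in c("lion", "leopard", "cheetah", "wild_dog", "spotted_hyaena",
              "brown_hyaena")) {
    expect_equal(true_density(cfg, s, "communal"), 0)
  }
  plan <- cfg$transect_plan
  priv <- plan$lut == "private"
  expect_equal(sum(plan$length_km[priv] * plan$passes[priv]), 696)
  expect_equal(sum(plan$length_km[plan$lut == "resettlement"]), 149)
  expect_equal(sum(plan$length_km[plan$lut == "communal"]), 110)
})

test_that("config validation rejects pathological inputs", {
  expect_error(simulation_config(dens1(-1), transect_plan = plan1()),
               ">= 0")
  expect_error(
    simulation_config(dens1(1), transect_plan = plan1(),
                      contamination = 1),
    "contamination")
  # negative expected count from a pathological intercept
  cal <- calibration_model("lion", slope = 3.26, intercept = -100)
  expect_error(simulation_config(dens1(1), calibration = cal,
                                 transect_plan = plan1()),
               "negative expected")
})
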