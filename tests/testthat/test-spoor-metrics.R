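test_that("filter_spoor applies the two discard rules and nothing else", {
  rec <- tiny_dataset()$records
  expect_equal(filter_spoor(rec), rec) # all fresh and unique

  rec$age_hours[2] <- 30
  out <- filter_spoor(rec)
  expect_equal(nrow(out), 2L)
  expect_false(30 %in% out$age_hours)

  rec2 <- tiny_dataset()$records
  rec2$duplicate_of[2] <- 1L
  expect_equal(nrow(filter_spoor(rec2)), 2L)
  # order preserved
  expect_equal(filter_spoor(rec2)$position_km, c(2, 3.5))
  # unknown age is kept
  expect_equal(nrow(filter_spoor(tiny_dataset()$records)), 3L)
})

test_that("spoor density and frequency are reciprocal arithmetic", {
  expect_equal(spoor_density(0, 110), 0)
  expect_equal(spoor_density(101, 696), 14.5114943, tolerance = 1e-7)
  expect_equal(spoor_density(65, 696), 9.3390805, tolerance = 1e-7)
  expect_equal(spoor_frequency(696, 101), 6.8910891, tolerance = 1e-7)
  expect_equal(spoor_frequency(696, 65), 10.7076923, tolerance = 1e-7)
  expect_equal(spoor_frequency(100, 1), 100)
  # reciprocity to machine precision
  for (n in c(1, 7, 65, 129)) {
    expect_equal(spoor_frequency(696, n) * spoor_density(n, 696), 100)
  }
  # linearity in count; invariance under splitting effort into passes
  expect_equal(spoor_density(20, 500), 2 * spoor_density(10, 500))
  expect_equal(spoor_density(10, 500), spoor_density(10, 2 * 250))
  expect_error(spoor_density(5, 0), "surveyed_km")
  expect_error(spoor_frequency(100, 0), "no spoor")
})

test_that("inter-spoor intervals difference positions on the combined axis", {
  # spoor at combined km 2, 5, 9 on a single transect
  ds <- survey_dataset(
    data.frame(species = "lion", transect_id = "T1",
               position_km = c(2, 5, 9), group_size = 1L,
               recorded_on = as.Date("2008-10-01"), age_hours = 1,
               duplicate_of = NA_integer_, lut = "private"),
    data.frame(transect_id = "T1", lut = "private", length_km = 10,
               passes = 1L),
    data.frame(lut = "private", area_km2 = 100))
  expect_equal(inter_spoor_intervals(ds, "lion", "private"), c(3, 4))
  # single spoor -> no interval
  one <- ds
  one$records <- one$records[1, ]
  expect_equal(inter_spoor_intervals(one, "lion", "private"), numeric(0))
  # gaps span transect boundaries: spoor at 9 on T1 (10 km) and 1 on T2
  two <- survey_dataset(
    data.frame(species = "lion", transect_id = c("T1", "T2"),
               position_km = c(9, 1), group_size = 1L,
               recorded_on = as.Date("2008-10-01") + c(0, 1),
               age_hours = 1, duplicate_of = NA_integer_, lut = "private"),
    data.frame(transect_id = c("T1", "T2"), lut = "private",
               length_km = c(10, 8), passes = 1L),
    data.frame(lut = "private", area_km2 = 100))
  expect_equal(inter_spoor_intervals(two, "lion", "private"), 2)
  # explicit ordering reverses the axis
  expect_equal(
    inter_spoor_intervals(two, "lion", "private",
                          ordering = data.frame(transect_id = c("T2", "T1"),
                                                pass = 1L)),
    16)
  expect_error(
    inter_spoor_intervals(two, "lion", "private",
                          ordering = data.frame(transect_id = "T1",
                                                pass = 1L)),
    "exactly once")
})

test_that("interval sum telescopes to last minus first position", {
  for (seed in 1:20) {
    ds <- filter_spoor(simulate_survey(make_svc_scenario(seed = seed)))
    iv <- inter_spoor_intervals(ds, "leopard", "private")
    n <- sum(ds$records$species == "leopard" &
               ds$records$lut == "private")
    expect_length(iv, max(0, n - 1))
    expect_true(all(iv >= 0))
    expect_lte(sum(iv), 696)
  }
})

test_that("simulated Poisson intervals have mean near 1/rate", {
  # rate per km for leopard at svc truth: 1.90 * 7.64 / 100
  lambda <- 1.90 * 7.64 / 100
  means <- vapply(1:2000, function(s) {
    cfg <- simulation_config(
      data.frame(species = "leopard", lut = "private", density = 7.64),
      transect_plan = data.frame(lut = "private", length_km = 696,
                                 passes = 1L),
      seed = s)
    iv <- inter_spoor_intervals(simulate_survey(cfg), "leopard", "private")
    if (length(iv) < 2) NA_real_ else mean(iv)
  }, numeric(1))
  means <- means[!is.na(means)]
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1 / lambda), 3 * se)
})

test_that("effort summary reproduces the penetration heuristic", {
  # printed private row: area 2,530 km2, 346 km of transects -> 7.3
  ds <- survey_dataset(
    data.frame(),
    data.frame(transect_id = c("P1", "C1"), lut = c("private", "communal"),
               length_km = c(346, 110), passes = c(2L, 1L)),
    data.frame(lut = c("private", "communal"), area_km2 = c(2530, 984)))
  eff <- effort_summary(ds)
  expect_equal(eff$sample_penetration[eff$lut == "private"], 7.3)
  expect_equal(eff$sample_penetration[eff$lut == "communal"], 8.9)
  expect_equal(eff$surveyed_km[eff$lut == "private"], 692)
  # area equal to transect sum -> 1.0
  ds2 <- survey_dataset(
    data.frame(),
    data.frame(transect_id = "T1", lut = "private", length_km = 50,
               passes = 1L),
    data.frame(lut = "private", area_km2 = 50))
  expect_equal(effort_summary(ds2)$sample_penetration, 1.0)
})

test_that("density matrix covers every species-by-land-use cell", {
  ds <- filter_spoor(svc_survey())
  dm <- density_matrix(ds)
  expect_equal(dim(dm), c(6, 3))
  expect_equal(dm["cheetah", "communal"], 0)
  expect_equal(dm["leopard", "private"], 14.5114943, tolerance = 1e-7)
  expect_true(all(dm[, "communal"] == 0))
  # empty dataset -> all-zero table
  empty <- ds
  empty$records <- empty$records[0, ]
  expect_true(all(density_matrix(empty) == 0))
})
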