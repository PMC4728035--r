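test_that("read/write round-trips a dataset field-for-field", {
  ds <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_survey(ds, dir)
  back <- read_survey(dir)
  expect_equal(back$records, ds$records)
  expect_equal(back$transects, ds$transects)
  expect_equal(back$strata, ds$strata)
  # empty dataset writes header-only records file
  empty <- survey_dataset(data.frame(), ds$transects, ds$strata)
  write_survey(empty, dir)
  expect_length(readLines(file.path(dir, "records.csv")), 1L)
  expect_equal(nrow(read_survey(dir)$records), 0L)
})

test_that("round-trip identity holds for generated datasets", {
  dir <- withr::local_tempdir()
  for (seed in 1:15) {
    ds <- random_dataset(seed)
    write_survey(ds, dir)
    back <- read_survey(dir, check = FALSE)
    expect_equal(back$records, ds$records, info = paste("seed", seed))
    expect_equal(back$transects, ds$transects)
    expect_equal(back$strata, ds$strata)
  }
  # tab dialect
  ds <- tiny_dataset()
  write_survey(ds, dir, sep = "\t")
  expect_equal(read_survey(dir, sep = "\t")$records, ds$records)
})

test_that("simulated dataset round-trips through disk (seed 1)", {
  ds <- simulate_survey(make_svc_scenario(seed = 1))
  dir <- withr::local_tempdir()
  write_survey(ds, dir)
  expect_equal(read_survey(dir)$records, ds$records)
})

test_that("schema errors are specific", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  write_survey(ds, dir)
  # missing mandatory column named in the error
  rec <- ds$records
  rec$group_size <- NULL
  utils::write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE)
  expect_error(read_survey(dir), "group_size")
  # unknown columns ignored with a warning
  rec <- ds$records
  rec$observer <- "st"
  utils::write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE)
  expect_warning(out <- read_survey(dir), "observer")
  expect_named(out$records, names(ds$records))
})

test_that("validate_survey flags invariant violations and is pure", {
  ds <- tiny_dataset()
  expect_identical(validate_survey(ds), character(0))

  bad <- ds
  bad$records$position_km[1] <- 12 # beyond the 10 km transect
  v <- validate_survey(bad)
  expect_length(v, 1L)
  expect_match(v, "position_km")
  expect_error(survey_dataset(bad$records, bad$transects, bad$strata),
               "position_km")

  bad <- ds
  bad$records$group_size[2] <- 0L
  expect_match(validate_survey(bad), "group_size")

  bad <- ds
  bad$transects <- rbind(bad$transects, bad$transects[1, ])
  expect_match(validate_survey(bad), "not unique", all = FALSE)

  bad <- ds
  bad$records$transect_id[3] <- "T9"
  expect_match(validate_survey(bad), "not in register")

  # duplicate_of must point to an earlier same transect/day/species record
  bad <- ds
  bad$records$duplicate_of[3] <- 1L # different species/transect
  expect_match(validate_survey(bad), "duplicate_of")
  ok <- ds
  ok$records$duplicate_of[2] <- 1L
  expect_identical(validate_survey(ok), character(0))

  # purity: identical output on repeated calls
  expect_identical(validate_survey(bad), validate_survey(bad))
})

test_that("packaged svc2008 fixture matches the published survey totals", {
  ds <- svc_survey()
  counts <- table(ds$records$species, ds$records$lut)
  expect_equal(sum(counts[, "private"]) + sum(counts[, "resettlement"]),
               423)
  expect_equal(unname(counts["lion", "private"]), 65)
  expect_equal(unname(counts["leopard", "private"]), 101)
  expect_equal(unname(counts["cheetah", "private"]), 10)
  expect_equal(unname(counts["wild_dog", "private"]), 129)
  expect_equal(unname(counts["brown_hyaena", "private"]), 12)
  expect_equal(unname(counts["spotted_hyaena", "private"]), 103)
  expect_equal(unname(counts["spotted_hyaena", "resettlement"]), 3)
  expect_identical(validate_survey(ds), character(0))
  # effort register: 696 km surveyed private, 149 resettlement, 110 communal
  eff <- effort_summary(ds)
  expect_equal(eff$surveyed_km[eff$lut == "private"], 696)
  expect_equal(eff$surveyed_km[eff$lut == "resettlement"], 149)
  expect_equal(eff$surveyed_km[eff$lut == "communal"], 110)
})
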