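test_that("dataset round-trips through CSV files unchanged", {
  d <- tiny_dataset()
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  d2 <- read_dataset(paths[["participants"]], paths[["ratings"]],
                     paths[["temperatures"]])
  expect_equal(d2$participants, d$participants)
  expect_equal(d2$ratings, d$ratings)
  expect_equal(d2$temperatures, d$temperatures)
})

test_that("empty dataset writes header-only files that read back empty", {
  d <- hygro_dataset(empty_participants())
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  for (p in paths) expect_length(readLines(p), 1)
  d2 <- read_dataset(paths[["participants"]], paths[["ratings"]],
                     paths[["temperatures"]])
  expect_equal(nrow(d2$participants), 0)
})

test_that("non-ASCII medication strings survive the round trip", {
  p <- tiny_participants()
  p$medications[1] <- "béta-interféron β1a"
  d <- hygro_dataset(p)
  dir <- withr::local_tempdir()
  paths <- write_dataset(d, dir)
  d2 <- read_dataset(paths[["participants"]])
  expect_identical(d2$participants$medications[1], p$medications[1])
})

test_that("random synthetic cohorts round-trip (property)", {
  for (seed in c(11, 12)) {
    cfg <- simulation_config(seed = seed, n_ms = 3, n_ctr = 2)
    d <- generate_cohort(cfg, include_temperatures = (seed == 11), hz = 0.1)
    dir <- withr::local_tempdir()
    paths <- write_dataset(d, dir)
    d2 <- read_dataset(paths[["participants"]], paths[["ratings"]],
                       paths[["temperatures"]])
    expect_equal(d2$participants, d$participants)
    expect_equal(d2$ratings, d$ratings)
    expect_equal(d2$temperatures, d$temperatures)
  }
})

test_that("validation raises distinct classed errors", {
  # VAS bound violation
  expect_error(
    hygro_dataset(tiny_participants(), tiny_rating(wetness = 101)),
    class = "hygro_vas_out_of_range"
  )
  # duplicate rating key
  expect_error(
    hygro_dataset(tiny_participants(),
                  dplyr::bind_rows(tiny_rating(), tiny_rating())),
    class = "hygro_duplicate_key"
  )
  # unknown participant reference
  expect_error(
    hygro_dataset(tiny_participants(), tiny_rating("GHOST")),
    class = "hygro_unknown_participant"
  )
  # missing column
  expect_error(
    hygro_dataset(tiny_participants()[, -2], tiny_rating()),
    class = "hygro_missing_column"
  )
  # EDSS on a control
  p <- tiny_participants(); p$edss[2] <- 2
  expect_error(hygro_dataset(p), class = "hygro_invalid_field")
  # temperature range
  expect_error(
    hygro_dataset(tiny_participants(), NULL, tiny_temperature(base = 44)),
    class = "hygro_out_of_range"
  )
})

test_that("enums parse case-insensitively from files", {
  dir <- withr::local_tempdir()
  paths <- write_dataset(tiny_dataset(), dir)
  writeLines(
    c("participant_id,session,site,quality,mode,wetness_mm,thermal_mm",
      "P1,Neutral,forehead,cold_wet,Dynamic,54,30"),
    paths[["ratings"]]
  )
  d2 <- read_dataset(paths[["participants"]], paths[["ratings"]])
  expect_identical(d2$ratings$site, "FOREHEAD")
  expect_identical(d2$ratings$mode, "DYNAMIC")
  expect_identical(d2$ratings$session, "NEUTRAL")
})

test_that("bundled MS individual ratings load as a valid dataset", {
  w <- ms_wetness_table()
  expect_equal(nrow(w), 72)
  r <- tibble::tibble(
    participant_id = w$participant_id, session = "NEUTRAL", site = w$site,
    quality = w$quality, mode = "DYNAMIC",
    wetness_mm = w$wetness_mm, thermal_mm = 50
  )
  d <- hygro_dataset(ms_participants_table(), r)
  expect_equal(nrow(d$ratings), 72)
  expect_equal(sum(d$ratings$site == "FOREHEAD"), 36)
})

test_that("cohort summary uses sample SD and handles n = 1", {
  s <- summarize_cohort(ms_participants_table(), groups = "MS")
  expect_equal(s$age_mean, 48.3, tolerance = 0.05)
  expect_equal(s$age_sd, 10.8, tolerance = 0.05)
  expect_equal(s$edss_mean, 4.7, tolerance = 0.05)
  one <- summarize_cohort(tiny_participants()[1, ], groups = "MS")
  expect_true(is.na(one$age_sd))
  expect_error(summarize_cohort(tiny_participants()[1, ], groups = "CTR"),
               class = "hygro_empty_group")
})

test_that("stimulus constants follow quality", {
  expect_equal(probe_temperature(c("cold_wet", "NEUTRAL_WET", "WARM_WET")),
               c(25, 30, 35))
  expect_equal(stimulus_constants()$contact_area_cm2, 1.32)
  expect_error(probe_temperature("WET"), class = "hygro_invalid_enum")
})
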