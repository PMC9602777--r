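test_that("log transform handles zero, offsets and errors", {
  cfg <- profiling_config()
  expect_equal(log_transform(0, cfg), 0)
  expect_equal(log_transform(99, cfg), 2)  # log10(100)
  expect_error(log_transform(-1, cfg), class = "hygro_out_of_range")
  raw <- profiling_config(transform = "RAW")
  expect_equal(log_transform(c(0, 42), raw), c(0, 42))
  expect_error(log_transform(0, profiling_config(log_offset = 0)),
               class = "hygro_out_of_range")
})

test_that("normative references are recomputed from raw values", {
  ref <- build_normative(c(9, 99), "FOREHEAD", "COLD_WET")
  expect_equal(ref$mean_t, 1.5)  # logs {1, 2}
  expect_equal(ref$n, 2)
  expect_equal(ref$mean_raw, 54)
  expect_error(build_normative(50), class = "hygro_degenerate_ref")
  expect_error(build_normative(c(50, 50)), class = "hygro_degenerate_ref")
  expect_error(build_normative(c(9, 999)), class = "hygro_out_of_range")
})

test_that("z-scores standardize on the transformed scale", {
  ref <- build_normative(c(0, 9, 99))  # logs {0, 1, 2}: mean 1, sd 1
  expect_equal(z_score(9, ref), 0)
  expect_equal(z_score(999, ref), 2)   # log10(1000) = 3
  # monotone in raw value
  xs <- seq(0, 100, by = 5)
  expect_true(all(diff(z_score(xs, ref)) > 0))
  # a rating at the back-transformed normative mean scores 0
  ref2 <- build_normative(c(20, 35, 50, 70, 90))
  x0 <- 10^ref2$mean_t - 1
  expect_equal(z_score(x0, ref2), 0, tolerance = 1e-12)
})

test_that("z of normative members has sample mean 0 and SD 1", {
  withr::local_seed(31)
  for (cfg in list(profiling_config(), profiling_config(transform = "RAW"))) {
    vals <- round(runif(51, 5, 95), 1)
    ref <- build_normative(vals, cfg = cfg)
    z <- z_score(vals, ref, cfg)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  }
})

test_that("classification uses strict inequalities at the threshold", {
  expect_identical(classify_z(c(-16.47, -1.97)), c("LOSS", "LOSS"))
  expect_identical(classify_z(c(-1.96, 0, 1.96)), rep("NORMAL", 3))
  expect_identical(classify_z(2.2), "GAIN")
  expect_error(classify_z(NaN), class = "hygro_out_of_range")
  # LOSS region is a lower interval in raw value for a fixed reference
  ref <- build_normative(c(30, 45, 55, 60, 62, 64, 70, 80))
  lab <- classify_z(z_score(seq(0, 100, by = 1), ref))
  expect_true(all(diff(match(lab, c("LOSS", "NORMAL", "GAIN"))) >= 0))
})

test_that("participant profiles cover referenced cells and warn on others", {
  refs <- build_normative_table(tibble::tibble(
    site = rep(c("FOREHEAD", "FINGER_PAD"), each = 4),
    quality = "COLD_WET",
    value_mm = c(40, 50, 60, 70, 55, 65, 75, 85)
  ))
  ratings <- tibble::tibble(
    participant_id = "P1",
    site = c("FOREHEAD", "FINGER_PAD", "FOREARM"),
    quality = "COLD_WET",
    wetness_mm = c(55, 1, 50)
  )
  expect_warning(prof <- profile_participant(ratings, refs), "FOREARM")
  expect_equal(nrow(prof), 2)
  expect_identical(prof$label[prof$site == "FINGER_PAD"], "LOSS")
  expect_identical(prof$label[prof$site == "FOREHEAD"], "NORMAL")
  expect_error(
    suppressWarnings(profile_participant(ratings[c(1, 1), ], refs)),
    class = "hygro_duplicate_key"
  )
})

test_that("published z-scores classify to the published abnormality table", {
  w <- ms_wetness_table()
  prof <- tibble::tibble(
    participant_id = w$participant_id, site = w$site, quality = w$quality,
    raw_value = w$wetness_mm, z = w$z, label = classify_z(w$z)
  )
  expect_equal(sum(prof$label == "LOSS"), 7)
  expect_equal(sum(prof$label == "GAIN"), 0)
  ab <- summarize_abnormalities(prof, group_size = 12)
  expect_setequal(ab$flagged_participants, c("1", "2", "10"))
  expect_equal(ab$proportion, 0.25)
  pat <- ab$flagged
  expect_equal(pat$n_sites[pat$participant_id == "1"], 2)
  expect_equal(pat$n_qualities[pat$participant_id == "1"], 2)
  expect_equal(pat$n_sites[pat$participant_id == "10"], 1)
})

test_that("all-normal profiles summarize to an empty flag set", {
  prof <- tibble::tibble(
    participant_id = c("A", "B"), site = "FOREHEAD", quality = "COLD_WET",
    raw_value = 50, z = 0, label = "NORMAL"
  )
  ab <- summarize_abnormalities(prof)
  expect_equal(ab$n_flagged, 0)
  expect_equal(ab$proportion, 0)
})

test_that("injected loss participants are recovered end to end", {
  inj <- loss_injections(c("MS01", "MS02"), c("FINGER_PAD", "FOREHEAD"),
                         c("COLD_WET", "COLD_WET"))
  cfg <- simulation_config(seed = 5150, n_ms = 6, n_ctr = 51,
                           injections = inj)
  d <- generate_cohort(cfg, include_temperatures = FALSE)
  refs <- normative_from_ratings(d)
  prof <- suppressWarnings(profile_cohort(d, refs))
  flagged_cells <- prof[prof$label == "LOSS", ]
  expect_true(all(c("MS01", "MS02") %in% flagged_cells$participant_id))
  expect_identical(
    flagged_cells$site[flagged_cells$participant_id == "MS01" &
                         flagged_cells$quality == "COLD_WET" &
                         flagged_cells$site == "FINGER_PAD"],
    "FINGER_PAD"
  )
})

test_that("normative members flag at about the nominal 5% rate", {
  # coverage of the z machinery on unbounded-normal cells, raw transform
  withr::local_seed(99)
  cfg <- profiling_config(transform = "RAW")
  rates <- purrr::map_dbl(1:40, function(i) {
    vals <- stats::rnorm(51, 50, 10)
    ref <- build_normative(pmin(pmax(vals, 0), 100), cfg = cfg)
    mean(classify_z(z_score(ref$values, ref, cfg), cfg) != "NORMAL")
  })
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})
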