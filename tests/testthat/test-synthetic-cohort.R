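test_that("generation is deterministic given the seed", {
  cfg <- simulation_config(seed = 42, n_ms = 2, n_ctr = 2)
  d1 <- generate_cohort(cfg, include_temperatures = TRUE, hz = 0.1)
  d2 <- generate_cohort(cfg, include_temperatures = TRUE, hz = 0.1)
  expect_identical(d1$participants, d2$participants)
  expect_identical(d1$ratings, d2$ratings)
  expect_identical(d1$temperatures, d2$temperatures)
  d3 <- generate_cohort(simulation_config(seed = 43, n_ms = 2, n_ctr = 2),
                        include_temperatures = FALSE)
  expect_false(identical(d1$ratings$wetness_mm, d3$ratings$wetness_mm))
})

test_that("zero-noise cells collapse to the configured (clipped) means", {
  cd <- default_cell_distributions()
  cd$sd_mm <- 0
  cfg <- simulation_config(seed = 5, n_ms = 1, n_ctr = 1,
                           cell_distributions = cd)
  d <- generate_cohort(cfg, include_temperatures = FALSE)
  r <- d$ratings[d$ratings$session == "NEUTRAL" & d$ratings$mode == "STATIC", ]
  key <- paste(r$site, r$quality)
  expected <- cd$mean_mm[match(key, paste(cd$site, cd$quality))]
  expect_equal(r$wetness_mm, pmin(pmax(expected, 0), 100), tolerance = 1e-12)
})

test_that("generated values respect physical ranges (property)", {
  for (seed in c(1, 2, 3)) {
    cfg <- simulation_config(seed = seed, n_ms = 4, n_ctr = 4)
    d <- generate_cohort(cfg, include_temperatures = (seed == 1), hz = 0.1)
    expect_true(all(d$ratings$wetness_mm >= 0 & d$ratings$wetness_mm <= 100))
    expect_true(all(d$ratings$thermal_mm >= 0 & d$ratings$thermal_mm <= 100))
    if (nrow(d$temperatures) > 0) {
      tv <- unlist(d$temperatures[, 4:10])
      expect_true(all(tv > 10 & tv < 45))
    }
  }
})

test_that("truncated sampler hits the configured cell mean", {
  # distribution-level check equivalent to averaging the forehead cold-wet
  # control cell over 2000 replicate 51-control cohorts
  withr::local_seed(101)
  mu <- hygrosense:::solve_latent_mean(53.7, 27.4)
  draws <- hygrosense:::rtrunc_norm(2000 * 51, mu, 27.4)
  expect_lt(abs(mean(draws) - 53.7), 1)
  expect_true(all(draws >= 0 & draws <= 100))
})

test_that("cohort cell means recover configured means end to end", {
  cfg <- simulation_config(seed = 77, n_ms = 0, n_ctr = 51)
  vals <- purrr::map_dbl(1:8, function(i) {
    d <- generate_cohort(simulation_config(seed = 77 + i, n_ms = 0,
                                           n_ctr = 51),
                         include_temperatures = FALSE)
    r <- d$ratings
    mean(r$wetness_mm[r$session == "NEUTRAL" & r$mode == "DYNAMIC" &
                        r$site == "FOREHEAD" & r$quality == "COLD_WET"])
  })
  # pooled mean over 8 x 51 draws; 3 SE band around the configured 53.7
  expect_lt(abs(mean(vals) - 53.7), 3 * 27.4 / sqrt(8 * 51))
})

test_that("per-cell sample means track configured means across cells", {
  cfg <- simulation_config(seed = 15, n_ms = 0, n_ctr = 51)
  d <- generate_cohort(cfg, include_temperatures = FALSE)
  cd <- cfg$cell_distributions
  inc <- cfg$dynamic_increment
  r <- d$ratings[d$ratings$session == "NEUTRAL" & d$ratings$mode == "DYNAMIC", ]
  obs <- r |>
    dplyr::group_by(site, quality) |>
    dplyr::summarise(m = mean(wetness_mm), .groups = "drop")
  expected <- cd$mean_mm[match(paste(obs$site, obs$quality),
                               paste(cd$site, cd$quality))] + inc[obs$site]
  sds <- cd$sd_mm[match(paste(obs$site, obs$quality),
                        paste(cd$site, cd$quality))]
  expect_true(all(abs(obs$m - expected) < 3 * sds / sqrt(51)))
})

test_that("noiseless temperature traces satisfy the session targets", {
  cfg <- noiseless_sim_config()
  for (s in c("NEUTRAL", "HEAT", "COLD")) {
    tt <- generate_temperatures(cfg, "MS01", s)
    expect_equal(nrow(tt), 6000)
    wa <- window_average(tt)
    target <- default_session_configs()
    expect_equal(wa$mean_tsk,
                 target$target_mean_tsk[target$session == s],
                 tolerance = 1e-9)
    expect_equal(wa$mean_trec, 37, tolerance = 1e-9)
  }
})

test_that("rectal series stays near 37 degC with default noise", {
  cfg <- simulation_config(seed = 4, n_ms = 1, n_ctr = 0)
  means <- purrr::map_dbl(c("NEUTRAL", "HEAT", "COLD"), function(s) {
    mean(generate_temperatures(cfg, "MS01", s)$rectal_c)
  })
  expect_true(all(abs(means - 37) < 0.2))
})

test_that("loss injection replaces only the designated cells", {
  cfg <- simulation_config(seed = 21, n_ms = 2, n_ctr = 1)
  d <- generate_cohort(cfg, include_temperatures = FALSE)
  expect_identical(inject_loss(d, loss_injections(character(), character(),
                                                  character()))$ratings,
                   d$ratings)
  inj <- loss_injections("MS01", "FINGER_PAD", "COLD_WET", floor_mean = 0)
  d2 <- inject_loss(d, inj, seed = 99)
  hit <- d2$ratings$participant_id == "MS01" &
    d2$ratings$site == "FINGER_PAD" & d2$ratings$quality == "COLD_WET"
  expect_true(all(d2$ratings$wetness_mm[hit] <= 6))  # 3-sigma truncated bound
  expect_identical(d2$ratings$wetness_mm[!hit], d$ratings$wetness_mm[!hit])
  expect_error(
    inject_loss(d, loss_injections("NOBODY", "FOREHEAD", "COLD_WET")),
    class = "hygro_unknown_cell"
  )
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(simulation_config(), class = "hygro_invalid_config")
  cd <- default_cell_distributions()[-1, ]
  expect_error(simulation_config(seed = 1, cell_distributions = cd),
               class = "hygro_invalid_config")
  sc <- default_session_configs()
  sc$target_mean_tsk[1] <- 45
  expect_error(simulation_config(seed = 1, session_configs = sc),
               class = "hygro_invalid_config")
})
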