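test_that("studentized-range CDF matches the reference distribution", {
  # independent oracle: base R ptukey/qtukey
  cases <- expand.grid(q = c(0.5, 2, 3.5, 5), k = c(2, 3, 4),
                       df = c(5, 21, 42))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      expect_equal(ptukey_numeric(q, k, df), stats::ptukey(q, k, df),
                   tolerance = 1e-7)
    })
  }
  expect_equal(ptukey_numeric(3.5, 3, Inf), stats::ptukey(3.5, 3, Inf),
               tolerance = 1e-7)
  expect_equal(ptukey_numeric(0, 3, 10), 0)
  expect_error(ptukey_numeric(2, 3, 0.5), class = "hygro_invalid_config")
})

test_that("critical value for k = 3, df = 42 matches published tables", {
  expect_equal(qtukey_numeric(0.95, 3, 42), 3.436, tolerance = 5e-4)
})

test_that("Tukey HSD reduces to the two-sample t test at k = 2", {
  withr::local_seed(11)
  for (i in 1:10) {
    x <- rnorm(8, 0, 2)
    y <- rnorm(6, 0.5, 2)
    s2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    res <- tukey_hsd(c(a = mean(x), b = mean(y)), c(length(x), length(y)),
                     ms_error = s2, df_error = length(x) + length(y) - 2)
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(res$p_adj, tt$p.value, tolerance = 1e-6)
    expect_equal(res$diff, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
    expect_equal(c(res$lo, res$hi), as.numeric(tt$conf.int), tolerance = 1e-5)
  }
})

test_that("Tukey HSD on identical means gives zero difference, p near 1", {
  res <- tukey_hsd(c(a = 5, b = 5, c = 5), ns = 4, ms_error = 1,
                   df_error = 9)
  expect_true(all(res$diff == 0))
  expect_true(all(res$p_adj > 0.999))
  expect_true(all(res$lo <= res$diff & res$diff <= res$hi))
})

test_that("Tukey adjusted p is non-decreasing in the number of means", {
  ps <- purrr::map_dbl(2:5, function(k) {
    1 - ptukey_numeric(3.0, k, 30)
  })
  expect_true(all(diff(ps) > 0))
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.02, 3), 0.058808)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(0.9, 10), 1)
  # monotone in m; never below the raw p
  p <- 0.03
  adj <- purrr::map_dbl(1:8, ~ sidak_adjust(p, .x))
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_error(sidak_adjust(1.2, 2), class = "hygro_out_of_range")
})

test_that("paired contrasts carry exact t intervals", {
  # differences {10, 10, 20, 20}: mean 15, t(3) interval
  res <- paired_contrast(c(20, 30, 50, 60), c(10, 20, 30, 40))
  expect_equal(res$diff, 15)
  se <- stats::sd(c(10, 10, 20, 20)) / 2
  tc <- stats::qt(0.975, 3)
  expect_equal(res$lo, 15 - tc * se)
  expect_equal(res$hi, 15 + tc * se)
  # degenerate zero-variance differences
  res0 <- paired_contrast(c(1, 2, 3), c(0, 1, 2))
  expect_true(res0$degenerate)
  expect_equal(c(res0$lo, res0$hi), c(1, 1))
  expect_error(paired_contrast(1, 2), class = "hygro_empty_group")
})

test_that("dynamic-increment recovery via paired contrast", {
  cfg <- simulation_config(seed = 404, n_ms = 0, n_ctr = 150)
  d <- generate_cohort(cfg, include_temperatures = FALSE)
  r <- d$ratings[d$ratings$session == "NEUTRAL" &
                   d$ratings$site == "FINGER_PAD" &
                   d$ratings$quality == "COLD_WET", ]
  wide <- tidyr::pivot_wider(r[, c("participant_id", "mode", "wetness_mm")],
                             names_from = "mode", values_from = "wetness_mm")
  res <- paired_contrast(wide$DYNAMIC, wide$STATIC)
  expect_true(res$lo <= 15.5 && 15.5 <= res$hi)
})

test_that("KS normality screen separates normal from uniform samples", {
  withr::local_seed(55)
  norm_p <- purrr::map_dbl(1:30, ~ ks_normality(rnorm(500))$p)
  unif_p <- purrr::map_dbl(1:30, ~ ks_normality(runif(500))$p)
  expect_gte(mean(norm_p > 0.05), 0.9)
  expect_gte(mean(unif_p < 0.05), 0.9)
  expect_error(ks_normality(rep(3, 10)), class = "hygro_degenerate_ref")
  expect_error(ks_normality(c(1, 2)), class = "hygro_empty_group")
})

test_that("noncentral-F sample size search matches direct evaluation", {
  expect_error(sample_size_for_power(0), class = "hygro_invalid_config")
  # enormous effect: smallest feasible n with positive error df
  expect_equal(sample_size_for_power(10, k = 2)$n_per_group, 2)
  res <- sample_size_for_power(0.93, alpha = 0.05, power = 0.8, k = 2)
  # direct noncentral-F check of the returned n and its predecessor
  pow <- function(n) {
    stats::pf(stats::qf(0.95, 1, 2 * (n - 1)), 1, 2 * (n - 1),
              ncp = 0.93^2 * 2 * n, lower.tail = FALSE)
  }
  expect_gte(pow(res$n_per_group), 0.8)
  expect_lt(pow(res$n_per_group - 1), 0.8)
  expect_equal(res$achieved_power, pow(res$n_per_group), tolerance = 1e-12)
})
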