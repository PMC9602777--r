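# Post hoc machinery: studentized-range distribution by numerical
# integration, Tukey HSD, Sidak adjustment, paired contrasts, and a
# Kolmogorov-Smirnov normality check.

# P(range of k std normals <= y)
range_cdf <- function(y, k) {
  if (y <= 0) return(0)
  stats::integrate(
    function(u) {
      k * stats::dnorm(u) * (stats::pnorm(u) - stats::pnorm(u - y))^(k - 1)
    },
    lower = -Inf, upper = Inf,
    rel.tol = 1e-11, abs.tol = 1e-12
  )$value
}

#' Studentized-range CDF by adaptive quadrature
#'
#' Distribution of the studentized range `q = range / (s / 1)` of `k`
#' independent standard normals with an independent chi-based scale
#' estimate on `df` degrees of freedom. Computed by nested adaptive
#' quadrature: the range CDF integral nested inside an integral over the
#' scale density; `df = Inf` gives the unstudentized range.
#'
#' @param q Quantile (scalar).
#' @param k Number of means, >= 2.
#' @param df Error degrees of freedom (>= 1, may be `Inf`).
#' @return Lower-tail probability.
#' @export
#' @examples
#' ptukey_numeric(3.5, k = 3, df = 42)
ptukey_numeric <- function(q, k, df = Inf) {
  stopifnot(length(q) == 1, k >= 2)
  if (df < 1) {
    rlang::abort("Need error df >= 1", class = "hygro_invalid_config")
  }
  if (!is.finite(q)) return(as.numeric(q > 0))
  if (q <= 0) return(0)
  if (is.infinite(df)) return(range_cdf(q, k))
  # density of s = sqrt(chisq_df / df)
  log_c <- (df / 2) * log(df / 2) - lgamma(df / 2) + log(2)
  s_dens <- function(s) exp(log_c + (df - 1) * log(s) - df * s^2 / 2)
  stats::integrate(
    function(s) vapply(s, function(si) s_dens(si) * range_cdf(q * si, k),
                       numeric(1)),
    lower = 0, upper = Inf, rel.tol = 1e-9, abs.tol = 1e-10
  )$value
}

#' Studentized-range quantile
#'
#' Inverse of [ptukey_numeric()] by root bracketing.
#'
#' @param p Lower-tail probability in (0, 1).
#' @param k Number of means.
#' @param df Error degrees of freedom.
#' @return Quantile q with `ptukey_numeric(q, k, df) = p`.
#' @export
qtukey_numeric <- function(p, k, df = Inf) {
  stopifnot(p > 0, p < 1)
  upper <- 10
  while (ptukey_numeric(upper, k, df) < p && upper < 1e4) upper <- upper * 2
  stats::uniroot(function(q) ptukey_numeric(q, k, df) - p,
                 lower = 1e-8, upper = upper, tol = 1e-9)$root
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise differences between level means with studentized-range
#' adjusted p-values and simultaneous confidence intervals
#' `diff +/- q_crit * SE`, where `SE = sqrt(ms_error/2 * (1/ni + 1/nj))`
#' (Tukey-Kramer for unequal n). The caller supplies the error mean square
#' and df appropriate to the design stratum (subjects MS for between
#' contrasts, residual MS for within contrasts of a mixed design).
#'
#' @param means Named numeric vector of level means.
#' @param ns Per-level sample sizes (recycled if scalar).
#' @param ms_error Error mean square.
#' @param df_error Error degrees of freedom (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `comparison`, `diff`, `lo`, `hi`, `p_adj`, `method`.
#' @export
tukey_hsd <- function(means, ns, ms_error, df_error, conf = 0.95) {
  k <- length(means)
  stopifnot(k >= 2, ms_error >= 0)
  if (df_error < 1) {
    rlang::abort("Need error df >= 1", class = "hygro_invalid_config")
  }
  ns <- rep_len(ns, k)
  if (is.null(names(means))) names(means) <- paste0("L", seq_len(k))
  qc <- qtukey_numeric(conf, k, df_error)
  pairs <- utils::combn(k, 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- means[i1] - means[i2]
    se <- sqrt(ms_error / 2 * (1 / ns[i1] + 1 / ns[i2]))
    qstat <- if (se == 0) Inf * sign(abs(d)) else abs(d) / se
    if (se == 0 && d == 0) qstat <- 0
    tibble::tibble(
      comparison = paste(names(means)[i1], "-", names(means)[i2]),
      diff = unname(d),
      lo = unname(d - qc * se),
      hi = unname(d + qc * se),
      p_adj = 1 - ptukey_numeric(qstat, k, df_error),
      method = "TUKEY"
    )
  }) |> dplyr::bind_rows()
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1.
#'
#' @param p Unadjusted p-value(s) in \[0, 1\].
#' @param m Number of comparisons, >= 1.
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' sidak_adjust(0.02, 3)  # 0.058808
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  if (any(p < 0 | p > 1)) {
    rlang::abort("p must lie in [0, 1]", class = "hygro_out_of_range")
  }
  pmin(1 - (1 - p)^m, 1)
}

#' Paired contrast between two within-subject conditions
#'
#' Mean of the paired differences with a t-based confidence interval on
#' `n - 1` degrees of freedom. A zero-variance difference vector yields a
#' width-0 interval flagged as degenerate.
#'
#' @param x,y Paired observations (same subjects, two conditions).
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `diff`, `lo`, `hi`, `p`, `n`, `degenerate`,
#'   `method`.
#' @export
paired_contrast <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) {
    rlang::abort("Need >= 2 paired observations", class = "hygro_empty_group")
  }
  m <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  if (degenerate) {
    return(tibble::tibble(diff = m, lo = m, hi = m, p = NA_real_, n = n,
                          degenerate = TRUE, method = "PAIRED_T"))
  }
  se <- s / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  tstat <- m / se
  tibble::tibble(
    diff = m, lo = m - tcrit * se, hi = m + tcrit * se,
    p = 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE),
    n = n, degenerate = FALSE, method = "PAIRED_T"
  )
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a sample against a normal distribution with the
#' sample's own mean and SD, using the asymptotic Kolmogorov p-value. With
#' estimated parameters this p-value is anti-conservative (true type-I rate
#' below nominal); it is used here as a screening diagnostic.
#'
#' @param x Numeric sample, n >= 4, non-constant.
#' @return List with `statistic` (D) and `p`.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) {
    rlang::abort("Need n >= 4", class = "hygro_empty_group")
  }
  if (stats::sd(x) == 0) {
    rlang::abort("Constant sample", class = "hygro_degenerate_ref")
  }
  res <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x), exact = FALSE)
  )
  list(statistic = unname(res$statistic), p = res$p.value)
}
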