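# A priori power / sample-size computation for a one-way fixed-effects
# design via the noncentral F distribution.

#' Smallest per-group sample size reaching a target power
#'
#' For a one-way fixed-effects ANOVA with `k` groups and Cohen's effect
#' size `f`, the noncentrality parameter at `n` subjects per group is
#' `lambda = f^2 * k * n`. The function returns the smallest integer `n`
#' (with positive error df, i.e. `n >= 2`) such that
#' `P(F > F_crit(alpha); df1 = k - 1, df2 = k(n - 1), lambda) >= power`.
#'
#' @param f Cohen's f, > 0.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param power Target power in (0, 1); default 0.8.
#' @param k Number of groups; default 2.
#' @param n_max Search cap (default 1e5).
#' @return List: `n_per_group`, `achieved_power`, `lambda`, `df1`, `df2`.
#' @export
#' @examples
#' sample_size_for_power(f = 0.93)
sample_size_for_power <- function(f, alpha = 0.05, power = 0.8, k = 2,
                                  n_max = 1e5) {
  if (f <= 0) {
    rlang::abort("Effect size f must be > 0 (power never reached at f = 0)",
                 class = "hygro_invalid_config")
  }
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, k >= 2)
  for (n in 2:n_max) {
    df1 <- k - 1
    df2 <- k * (n - 1)
    lambda <- f^2 * k * n
    crit <- stats::qf(1 - alpha, df1, df2)
    pow <- stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
    if (pow >= power) {
      return(list(n_per_group = n, achieved_power = pow, lambda = lambda,
                  df1 = df1, df2 = df2))
    }
  }
  rlang::abort("Target power not reached within n_max",
               class = "hygro_invalid_config")
}
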