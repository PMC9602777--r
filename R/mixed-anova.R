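# Two-way mixed-design ANOVA (between-group x within-subject), written from
# first principles via the classical sums-of-squares decomposition, with
# Greenhouse-Geisser sphericity correction and a percent-of-total-variation
# effect-size column.
#
# Model strata:
#   between-subjects: group, subjects-within-groups (error for group)
#   within-subjects:  within main effect, group x within interaction,
#                     within-subject residual (error for both)
# Complete cases only; with every subject observed at every within level the
# cell frequencies are proportional, so the weighted means formulas coincide
# with the least-squares projections (checked against a projection oracle in
# the tests).

#' Two-way mixed-design ANOVA
#'
#' Classical split-plot decomposition for one between-subjects factor
#' (2 levels) crossed with one within-subjects factor (2 or 3 levels),
#' complete cases required. For 3 or more within levels the
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance matrix and applied multiplicatively to the within-effect
#' degrees of freedom before p-values are computed (unconditionally, with
#' no sphericity pretest). Effect sizes are reported as percent of total
#' variation, 100 * SS_effect / SS_total, with subjects-within-groups
#' included in the total.
#'
#' @param data Long-format data frame.
#' @param subject,group,within,response Names (strings) of the columns
#'   holding subject id, between-group label, within-factor level and the
#'   numeric response.
#' @return Object of class `anova_table`: tibble with one row per component
#'   (`group`, `subjects_within_groups`, `within`, `group_x_within`,
#'   `residual`) and columns `ss`, `df`, `df_corrected`, `ms`, `f`, `p`,
#'   `pct_total`; attributes `epsilon` and `degenerate`.
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject = paste0("S", 1:6), within = c("A", "B"))
#' d$group <- rep(c("G1", "G2"), each = 6)
#' set.seed(1); d$response <- rnorm(12)
#' mixed_anova(d)
mixed_anova <- function(data, subject = "subject", group = "group",
                        within = "within", response = "response") {
  df <- tibble::tibble(
    subject = as.character(data[[subject]]),
    group = as.character(data[[group]]),
    within = as.character(data[[within]]),
    response = as.numeric(data[[response]])
  )
  if (anyNA(df)) {
    rlang::abort("Missing values not allowed (complete cases required)",
                 class = "hygro_incomplete_design")
  }
  wide <- tidyr::pivot_wider(df, names_from = "within",
                             values_from = "response")
  if (anyNA(wide)) {
    rlang::abort("Every subject must be observed at every within level",
                 class = "hygro_incomplete_design")
  }
  grp_of <- wide$group
  y <- as.matrix(wide[, setdiff(names(wide), c("subject", "group"))])
  mixed_anova_matrix(y, grp_of)
}

# matrix-level workhorse (used directly in simulation loops)
mixed_anova_matrix <- function(y, groups) {
  groups <- as.character(groups)
  m <- ncol(y)
  n_tot <- nrow(y)
  glev <- unique(groups)
  ng <- table(factor(groups, levels = glev))
  if (length(glev) != 2 || any(ng < 2)) {
    rlang::abort("Need exactly 2 groups with >= 2 subjects each",
                 class = "hygro_incomplete_design")
  }
  if (m < 2) {
    rlang::abort("Need >= 2 within levels", class = "hygro_incomplete_design")
  }

  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, factor(groups, levels = glev), mean)
  lev_mean <- colMeans(y)
  cell_mean <- rowsum(y, groups)[glev, , drop = FALSE] / as.vector(ng)

  ss_total <- sum((y - grand)^2)
  ss_bs <- m * sum((subj_mean - grand)^2)
  ss_group <- m * sum(as.vector(ng) * (grp_mean - grand)^2)
  ss_subj <- ss_bs - ss_group
  ss_within <- n_tot * sum((lev_mean - grand)^2)
  ss_cells <- sum(as.vector(ng) * (cell_mean - grand)^2)
  ss_int <- ss_cells - ss_group - ss_within
  ss_resid <- ss_total - ss_bs - ss_within - ss_int

  df_group <- length(glev) - 1
  df_subj <- n_tot - length(glev)
  df_within <- m - 1
  df_int <- df_group * df_within
  df_resid <- df_subj * df_within

  eps <- if (m >= 3) gg_epsilon(y, groups) else 1
  ms_subj <- ss_subj / df_subj
  ms_resid <- ss_resid / df_resid
  degenerate <- ms_resid <= .Machine$double.eps * max(1, ss_total) ||
    ms_subj <= .Machine$double.eps * max(1, ss_total)

  safe_f <- function(ms_eff, ms_err) {
    if (degenerate || ms_err <= 0) NA_real_ else ms_eff / ms_err
  }
  f_group <- safe_f(ss_group / df_group, ms_subj)
  f_within <- safe_f(ss_within / df_within, ms_resid)
  f_int <- safe_f(ss_int / df_int, ms_resid)

  tab <- tibble::tibble(
    effect = c("group", "subjects_within_groups", "within",
               "group_x_within", "residual"),
    ss = c(ss_group, ss_subj, ss_within, ss_int, ss_resid),
    df = c(df_group, df_subj, df_within, df_int, df_resid),
    df_corrected = c(df_group, df_subj, eps * df_within, eps * df_int,
                     eps * df_resid),
    ms = .data$ss / .data$df,
    f = c(f_group, NA, f_within, f_int, NA),
    p = c(
      if (is.na(f_group)) NA else stats::pf(f_group, df_group, df_subj,
                                            lower.tail = FALSE),
      NA,
      if (is.na(f_within)) NA else stats::pf(f_within, eps * df_within,
                                             eps * df_resid, lower.tail = FALSE),
      if (is.na(f_int)) NA else stats::pf(f_int, eps * df_int, eps * df_resid,
                                          lower.tail = FALSE),
      NA
    ),
    pct_total = 100 * .data$ss / ss_total
  )
  structure(tab, class = c("anova_table", class(tab)),
            epsilon = eps, degenerate = degenerate,
            group_levels = glev, n_per_group = as.vector(ng),
            ms_error = c(between = ms_subj, within = ms_resid),
            df_error = c(between = df_subj, within = df_resid))
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA (GG epsilon = %.4f%s)\n",
              attr(x, "epsilon"),
              if (isTRUE(attr(x, "degenerate"))) ", DEGENERATE" else ""))
  NextMethod()
}

#' Greenhouse-Geisser sphericity correction factor
#'
#' Epsilon is computed from the double-centered pooled within-group
#' covariance matrix of the within-level responses:
#' `eps = tr(S*)^2 / ((m - 1) * sum(S*^2))`. It satisfies
#' `1/(m - 1) <= eps <= 1`, with eps = 1 exactly when `m = 2` or when the
#' covariance matrix is compound symmetric (sphericity holds).
#'
#' @param y Numeric subject x within-level response matrix.
#' @param groups Optional group labels; when given, the covariance is
#'   pooled within groups (each group centered on its own cell means).
#' @return Epsilon in `[1/(m-1), 1]`.
#' @export
gg_epsilon <- function(y, groups = NULL) {
  y <- as.matrix(y)
  m <- ncol(y)
  if (m < 2) {
    rlang::abort("Need >= 2 within levels", class = "hygro_incomplete_design")
  }
  if (nrow(y) < 2) {
    rlang::abort("Need >= 2 subjects", class = "hygro_incomplete_design")
  }
  if (is.null(groups)) groups <- rep("all", nrow(y))
  groups <- as.character(groups)
  glev <- unique(groups)
  resid <- y
  for (g in glev) {
    i <- groups == g
    resid[i, ] <- sweep(y[i, , drop = FALSE], 2,
                        colMeans(y[i, , drop = FALSE]))
  }
  s <- crossprod(resid) / (nrow(y) - length(glev))
  # double-center
  rm <- rowMeans(s); cm <- colMeans(s); gm <- mean(s)
  s_star <- s - outer(rm, rep(1, m)) - outer(rep(1, m), cm) + gm
  tr <- sum(diag(s_star))
  denom <- (m - 1) * sum(s_star^2)
  if (denom <= 0) return(1)
  max(min(tr^2 / denom, 1), 1 / (m - 1))
}

#' Apply a sphericity correction to a pair of degrees of freedom
#'
#' @param epsilon Correction factor in `(0, 1]`.
#' @param df1,df2 Uncorrected numerator and denominator dfs.
#' @return Numeric `c(df1, df2) * epsilon`.
#' @export
#' @examples
#' corrected_dfs(0.9, 2, 42)  # 1.8, 37.8
corrected_dfs <- function(epsilon, df1, df2) {
  stopifnot(epsilon > 0, epsilon <= 1)
  c(df1 = epsilon * df1, df2 = epsilon * df2)
}
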