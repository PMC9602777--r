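# Independent least-squares projection oracle for the split-plot ANOVA.
# Sums of squares are computed as differences in fitted sums of squares
# between nested design subspaces (sequential projections); this shares no
# code with the means-formula implementation.

oracle_mixed_anova <- function(data) {
  y <- data$response
  g <- factor(data$group)
  s <- factor(data$subject)
  w <- factor(data$within)
  fit_ss <- function(x) {
    q <- qr(x)
    sum(qr.fitted(q, y)^2)
  }
  m0 <- fit_ss(matrix(1, length(y), 1))
  m_g <- fit_ss(model.matrix(~g))
  m_s <- fit_ss(model.matrix(~s))          # subjects span groups
  m_sw <- fit_ss(model.matrix(~s + w))
  m_swgw <- fit_ss(model.matrix(~s + w + g:w))
  list(
    ss_group = m_g - m0,
    ss_subj = m_s - m_g,
    ss_within = m_sw - m_s,
    ss_int = m_swgw - m_sw,
    ss_resid = sum(y^2) - m_swgw,
    ss_total = sum((y - mean(y))^2)
  )
}

# random complete mixed design for property loops
random_design <- function(n1, n2, m, sd = 1) {
  n <- n1 + n2
  y <- matrix(stats::rnorm(n * m, sd = sd), n, m)
  groups <- rep(c("G1", "G2"), c(n1, n2))
  long_design(y, groups)
}
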