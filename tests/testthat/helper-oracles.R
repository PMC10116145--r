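# Independent oracles used across test files. These deliberately avoid the
# package's own code paths for the quantity they check.

# AUC as the pairwise probability P(case > control) + 0.5 P(tie).
brute_force_auc <- function(cases, controls) {
  grid <- expand.grid(case = cases, control = controls)
  mean((grid$case > grid$control) + 0.5 * (grid$case == grid$control))
}

# Pooled-SD Cohen's d from group summaries (computed by hand, not via the
# package).
pooled_d_from_summaries <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m2 - m1) / sp
}

# A vector with exact sample mean m and sample sd s.
vector_with_moments <- function(n, m, s, seed = 1) {
  x <- withr::with_seed(seed, rnorm(n))
  m + s * (x - mean(x)) / sd(x)
}

# A hand-built 2-cell stimulus-like fixture on known cells for scoring tests.
fixed_stimulus <- function() {
  board <- tibble::tibble(
    row = c(1L, 1L, 2L, 2L, 3L, 4L, 4L),
    col = c(1L, 3L, 2L, 5L, 4L, 1L, 6L),
    symbol = paste0(c3b::vmt_categories(), "_1")
  )
  structure(list(pattern_id = 1L, board = board), class = "vmt_stimulus")
}

# Analytic mean and SD of z = (clip(N(mu_i, rmse), 0, hi) - mu_i) / rmse
# over a cohort's linear predictors, by numerical integration.
clipped_z_moments <- function(cohort, model, hi = 70) {
  mu <- as.numeric(c3b::predict_score(model, cohort$age, cohort$education,
                                      cohort$sex, cohort$race))
  s <- model$rmse
  mom <- function(mui, k) {
    f <- function(x) pmin(pmax(x, 0), hi)^k * stats::dnorm(x, mui, s)
    stats::integrate(f, mui - 8 * s, mui + 8 * s)$value
  }
  e1 <- vapply(mu, mom, 0, k = 1)
  e2 <- vapply(mu, mom, 0, k = 2)
  ez <- mean(e1 - mu) / s
  ez2 <- mean(e2 - 2 * mu * e1 + mu^2) / s^2
  list(mean = ez, sd = sqrt(ez2 - ez^2))
}

# Direct two-way ANOVA mean squares via lm(), as an independent route to the
# ICC components.
anova_mean_squares <- function(t1, t2) {
  long <- data.frame(
    y = c(t1, t2),
    subject = factor(rep(seq_along(t1), 2)),
    occasion = factor(rep(1:2, each = length(t1)))
  )
  a <- stats::anova(stats::lm(y ~ subject + occasion, data = long))
  list(msr = a["subject", "Mean Sq"],
       msc = a["occasion", "Mean Sq"],
       mse = a["Residuals", "Mean Sq"])
}
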