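#' Test-retest reliability statistics
#'
#' Two-occasion stability of a test score: the paired t-test and paired
#' Cohen's d quantify systematic change (practice effects), the intraclass
#' correlation coefficient (ICC) quantifies agreement between occasions.
#' The same machinery serves the waiting-room versus quiet-room
#' comparison, which is also a paired design.
#'
#' @name reliability
NULL

get_pairs <- function(data, t1, t2) {
  data <- as_tibble(data)
  x <- rlang::eval_tidy(rlang::enquo(t1), data)
  y <- rlang::eval_tidy(rlang::enquo(t2), data)
  keep <- !is.na(x) & !is.na(y)
  if (any(!keep)) {
    inform(paste0("Excluding ", sum(!keep),
                  " pair(s) with a missing occasion (listwise)."))
  }
  list(t1 = x[keep], t2 = y[keep])
}

#' Paired-occasions summary: t-test and paired Cohen's d
#'
#' The difference is taken as occasion 1 minus occasion 2, so a negative
#' `mean_diff` (and d) means scores improved at retest. The paired effect
#' size is `d = mean_diff / sd_diff`, identically equal to `t / sqrt(n)`.
#' A constant non-zero difference yields infinite `t` and `d` with a
#' warning; identical occasions are a degenerate-data error.
#'
#' @param data Data frame of paired measurements.
#' @param t1,t2 Columns holding the two occasions (tidy-eval; default
#'   `t1`, `t2`).
#' @return One-row tibble: `n`, `mean1`, `sd1`, `mean2`, `sd2`,
#'   `mean_diff`, `sd_diff`, `t`, `df`, `p.value`, `cohens_d`.
#' @examples
#' generate_retest(seed = 1) |> paired_summary()
#' @export
paired_summary <- function(data, t1 = t1, t2 = t2) {
  p <- get_pairs(data, {{ t1 }}, {{ t2 }})
  n <- length(p$t1)
  stopifnot(n >= 2)
  d <- p$t1 - p$t2
  sd_diff <- sd(d)
  mean_diff <- mean(d)
  if (sd_diff == 0) {
    if (mean_diff == 0) {
      abort("Degenerate data: the two occasions are identical.",
            class = "c3b_degenerate")
    }
    warn("Zero variance of a non-zero difference: t and d are infinite.")
    tstat <- sign(mean_diff) * Inf
    pval <- 0
  } else {
    tstat <- mean_diff / (sd_diff / sqrt(n))
    pval <- 2 * pt(-abs(tstat), df = n - 1)
  }
  tibble(
    n = n,
    mean1 = mean(p$t1), sd1 = sd(p$t1),
    mean2 = mean(p$t2), sd2 = sd(p$t2),
    mean_diff = mean_diff, sd_diff = sd_diff,
    t = tstat, df = n - 1, p.value = pval,
    cohens_d = if (sd_diff == 0) tstat else mean_diff / sd_diff
  )
}

#' Intraclass correlation for two occasions
#'
#' Single-measurement ICC from the two-way mean squares of an
#' occasions-by-subjects layout. The default `"ICC2_1"` is the two-way
#' random-effects absolute-agreement form
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`;
#' `"ICC3_1"` is the two-way mixed consistency form
#' `(MSR - MSE) / (MSR + (k-1) MSE)`. Here `k = 2` occasions, `MSR`,
#' `MSC`, `MSE` are the subject, occasion and residual mean squares.
#'
#' @inheritParams paired_summary
#' @param form `"ICC2_1"` (absolute agreement, default) or `"ICC3_1"`
#'   (consistency).
#' @return One-row tibble: `icc`, `form`, `n`, and the mean squares.
#' @examples
#' generate_retest(retest_spec(rho = 0.83, n = 200), seed = 1) |> icc()
#' @export
icc <- function(data, t1 = t1, t2 = t2, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  p <- get_pairs(data, {{ t1 }}, {{ t2 }})
  n <- length(p$t1)
  if (n < 3) abort("ICC needs at least 3 complete pairs.")
  m <- cbind(p$t1, p$t2)
  k <- 2
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    abort("Degenerate data: zero total variance.", class = "c3b_degenerate")
  }
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  value <- switch(form,
    ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3_1 = (msr - mse) / (msr + (k - 1) * mse)
  )
  tibble(icc = value, form = form, n = n, msr = msr, msc = msc, mse = mse)
}
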