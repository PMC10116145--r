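test_that("the min-z rule calls impairment strictly below the cutoff", {
  d <- tibble::tibble(z_pst = c(-0.5, -0.4, 1.0, 0.2),
                      z_vmt = c(0.2, -0.4, 1.0, -2.0))
  out <- classify_impairment(d)
  expect_equal(out$min_z, c(-0.5, -0.4, 1.0, -2.0))
  expect_equal(out$call, c("impaired", "WNL", "WNL", "impaired"))
  # boundary is not below: exactly -0.4 stays WNL
  expect_equal(out$call[2], "WNL")
})

test_that("missing z-scores are classified on the available test or excluded", {
  d <- tibble::tibble(z_pst = c(NA, -1, NA), z_vmt = c(-1, NA, NA))
  expect_message(out <- classify_impairment(d), "2 subject")
  expect_equal(out$call[1:2], c("impaired", "impaired"))
  expect_true(is.na(out$call[3]))
  expect_message(out2 <- classify_impairment(d, missing = "exclude"),
                 "excluded")
  expect_true(all(is.na(out2$call)))
})

test_that("lowering the cutoff never increases sensitivity", {
  d <- generate_case_control(case_control_spec(n_per_group = 200), seed = 9) |>
    add_adjusted_z()
  sens_at <- function(cutoff) {
    cm <- confusion_matrix(classify_impairment(d, cutoff = cutoff))
    screen_diagnostics(cm)$sensitivity
  }
  cutoffs <- seq(0.5, -2.5, by = -0.25)
  sens <- vapply(cutoffs, sens_at, 0)
  expect_true(all(diff(sens) <= 0))
})

test_that("confusion counts tally calls against truth", {
  records <- tibble::tibble(
    truth = c(rep("MCI", 30), rep("HC", 30)),
    call = c(rep("impaired", 27), rep("WNL", 3),
             rep("impaired", 5), rep("WNL", 25))
  )
  cm <- confusion_matrix(records)
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 27L, fp = 5L, tn = 25L, fn = 3L))
  # invariant to record order
  shuffled <- records[withr::with_seed(1, sample(nrow(records))), ]
  expect_equal(confusion_matrix(shuffled), cm)
  # empty input and all-correct calls
  expect_equal(confusion_matrix(records[0, ]), confusion_counts(0, 0, 0, 0))
  perfect <- tibble::tibble(truth = rep(c("MCI", "HC"), each = 10),
                            call = rep(c("impaired", "WNL"), each = 10))
  expect_equal(confusion_matrix(perfect), confusion_counts(10, 0, 10, 0))
  # missing truth is an error listing the offenders
  bad <- records; bad$truth[2] <- NA
  expect_error(confusion_matrix(bad), "2")
})

test_that("sensitivity, specificity and Youden J follow their definitions", {
  d1 <- screen_diagnostics(confusion_counts(27, 5, 25, 3))
  expect_equal(round(d1$sensitivity, 3), 0.900)
  expect_equal(round(d1$specificity, 3), 0.833)
  expect_equal(round(d1$youden_j, 3), 0.733)
  d2 <- screen_diagnostics(confusion_counts(13, 0, 30, 16))
  expect_equal(round(d2$sensitivity, 3), 0.448)
  expect_equal(d2$specificity, 1)
  expect_equal(round(d2$youden_j, 3), 0.448)
  d3 <- screen_diagnostics(confusion_counts(12, 0, 8, 0))
  expect_equal(d3$youden_j, 1)
  expect_error(screen_diagnostics(confusion_counts(0, 5, 25, 0)),
               class = "c3b_undefined_metric")
  expect_error(screen_diagnostics(confusion_counts(5, 0, 0, 5)),
               class = "c3b_undefined_metric")
})

test_that("the empirical ROC matches hand-checked instances", {
  perfect <- tibble::tibble(s = c(2, 1.5, 0.1, -0.3),
                            g = c("MCI", "MCI", "HC", "HC"))
  expect_equal(glance(roc_curve(perfect, s, g))$auc, 1)
  ties <- tibble::tibble(s = rep(1, 6), g = rep(c("MCI", "HC"), 3))
  expect_equal(glance(roc_curve(ties, s, g))$auc, 0.5)
  mixed <- tibble::tibble(s = c(3, 1, 2, 0), g = c("MCI", "MCI", "HC", "HC"))
  expect_equal(glance(roc_curve(mixed, s, g))$auc, 0.75)
  expect_error(roc_curve(mixed[1:2, ], s, g), class = "c3b_single_class")
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  d <- generate_case_control(seed = 5) |> add_adjusted_z() |>
    classify_impairment()
  roc <- roc_curve(d, -min_z, truth)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  auc <- attr(roc, "auc")
  expect_true(auc >= 0 && auc <= 1)
})

test_that("trapezoidal AUC equals the pairwise-comparison AUC", {
  for (seed in 1:30) {
    n_case <- withr::with_seed(seed, sample(2:25, 1))
    n_ctrl <- withr::with_seed(seed + 1, sample(2:25, 1))
    scores <- withr::with_seed(seed + 2, round(rnorm(n_case + n_ctrl), 1))
    d <- tibble::tibble(s = scores,
                        g = c(rep("MCI", n_case), rep("HC", n_ctrl)))
    expect_equal(glance(roc_curve(d, s, g))$auc,
                 brute_force_auc(d$s[d$g == "MCI"], d$s[d$g == "HC"]))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  d <- generate_case_control(case_control_spec(n_per_group = 100),
                             seed = 41) |>
    add_adjusted_z() |> classify_impairment()
  ours <- glance(roc_curve(d, -min_z, truth))$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = d$truth, predictor = -d$min_z, levels = c("HC", "MCI"),
    direction = "<")))
  expect_equal(ours, as.numeric(ref))
})

test_that("AUC is invariant under strictly increasing transforms", {
  d <- generate_case_control(seed = 6) |> add_adjusted_z() |>
    classify_impairment()
  a0 <- glance(roc_curve(d, -min_z, truth))$auc
  d$mono <- exp(2 * (-d$min_z)) - 5
  expect_equal(glance(roc_curve(d, mono, truth))$auc, a0)
})

test_that("the Youden scan dominates every observed threshold", {
  for (seed in 1:10) {
    d <- withr::with_seed(seed, tibble::tibble(
      s = round(c(rnorm(20, 1), rnorm(20)), 1),
      g = c(rep("MCI", 20), rep("HC", 20))
    ))
    best <- youden_optimal_cutoff(d, s, g)
    cases <- d$s[d$g == "MCI"]; controls <- d$s[d$g == "HC"]
    for (t in unique(d$s)) {
      j_t <- mean(cases > t) + mean(controls <= t) - 1
      expect_gte(best$youden_j + 1e-12, j_t)
    }
  }
})

test_that("Youden cutoff lands in the gap for separated groups, near zero for null", {
  sep <- tibble::tibble(s = c(2, 3, 4, -1, -2, 0),
                        g = rep(c("MCI", "HC"), each = 3))
  best <- youden_optimal_cutoff(sep, s, g)
  expect_equal(best$youden_j, 1)
  expect_true(best$cutoff > 0 && best$cutoff < 2)

  null <- withr::with_seed(77, tibble::tibble(
    s = rnorm(2000), g = rep(c("MCI", "HC"), 1000)))
  expect_lt(youden_optimal_cutoff(null, s, g)$youden_j, 0.15)
})

test_that("a Table-6-like z sample yields its Youden J back at the scan", {
  # construct z-pairs that produce counts (27, 5, 25, 3) at cutoff -0.4
  d <- tibble::tibble(
    z_pst = c(rep(-1, 27), rep(0.2, 3), rep(-0.9, 5), rep(0.4, 25)),
    z_vmt = c(rep(-0.8, 27), rep(0.1, 3), rep(-1.1, 5), rep(0.3, 25)),
    truth = c(rep("MCI", 30), rep("HC", 30))
  ) |> classify_impairment()
  cm <- screen_diagnostics(confusion_matrix(d))
  expect_equal(cm$youden_j, 27 / 30 + 25 / 30 - 1)
  best <- youden_optimal_cutoff(d, -min_z, truth)
  expect_gte(best$youden_j, cm$youden_j)
})

test_that("independent-groups summaries match the pooled-SD formulas", {
  a <- vector_with_moments(30, 28.61, 11.27, seed = 1)
  b <- vector_with_moments(30, 44.27, 8.48, seed = 2)
  res <- independent_groups_summary(a, b)
  expect_equal(res$cohens_d,
               pooled_d_from_summaries(28.61, 11.27, 30, 44.27, 8.48, 30))
  expect_equal(round(res$cohens_d, 2), 1.57)
  expect_gt(res$t, 0)
  expect_equal(res$df, 58)

  # identical groups: t = 0, d = 0
  same <- independent_groups_summary(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)

  # shifting by exactly the pooled SD gives d = 1
  sp <- sqrt(((30 - 1) * var(a) + (30 - 1) * var(a)) / 58)
  shifted <- independent_groups_summary(a, a + sp)
  expect_equal(shifted$cohens_d, 1)

  expect_error(independent_groups_summary(rep(1, 5), rep(1, 5)),
               class = "c3b_degenerate")
})

test_that("Welch's variant relaxes the equal-variance assumption", {
  a <- vector_with_moments(20, 10, 1, seed = 3)
  b <- vector_with_moments(40, 12, 6, seed = 4)
  student <- independent_groups_summary(a, b)
  welch <- independent_groups_summary(a, b, welch = TRUE)
  expect_lt(welch$df, student$df)
  expect_equal(student$cohens_d, welch$cohens_d)
})
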