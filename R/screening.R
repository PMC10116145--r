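#' Screening classification and signal-detection diagnostics
#'
#' A subject is called impaired when the lower of the two adjusted
#' z-scores falls strictly below the cutoff (default z < -0.4): the
#' min-of-two rule accommodates patients whose deficit is confined to
#' either episodic memory or processing speed. Discrimination between
#' groups is summarized by the confusion matrix, sensitivity, specificity,
#' Youden's J, and the empirical ROC curve with its AUC.
#'
#' @name screening
NULL

#' Classify impairment from a pair of adjusted z-scores
#'
#' Appends `min_z` and `call` (`"impaired"` / `"WNL"`, within normal
#' limits) to a cohort table. The rule is strict: `min_z < cutoff`.
#' Subjects with one missing z are, by default, classified on the available
#' score; with `missing = "exclude"` their call is `NA`. Subjects with both
#' z's missing are always `NA` (unscorable). Either way the affected count
#' is reported via a message.
#'
#' @param data Data frame with columns `z_pst` and `z_vmt`.
#' @param cutoff Impairment cutoff in z units (default -0.4).
#' @param missing How to handle a single missing z: `"available"` (use the
#'   other test) or `"exclude"`.
#' @return `data` with `min_z` and `call` appended.
#' @examples
#' tibble::tibble(z_pst = c(-0.5, -0.4), z_vmt = c(0.2, -0.4)) |>
#'   classify_impairment()
#' @export
classify_impairment <- function(data, cutoff = -0.4,
                                missing = c("available", "exclude")) {
  missing <- match.arg(missing)
  data <- as_tibble(data)
  if (!all(c("z_pst", "z_vmt") %in% names(data))) {
    abort("classify_impairment() needs columns z_pst and z_vmt.")
  }
  stopifnot(is.finite(cutoff))
  n_one_missing <- sum(xor(is.na(data$z_pst), is.na(data$z_vmt)))
  n_both_missing <- sum(is.na(data$z_pst) & is.na(data$z_vmt))
  min_z <- if (missing == "available") {
    pmin(data$z_pst, data$z_vmt, na.rm = TRUE)
  } else {
    pmin(data$z_pst, data$z_vmt)
  }
  min_z[is.na(data$z_pst) & is.na(data$z_vmt)] <- NA_real_
  if (n_one_missing > 0) {
    inform(paste0(n_one_missing, " subject(s) have one missing z-score (",
                  if (missing == "available") "classified on the available test"
                  else "excluded", ")."))
  }
  if (n_both_missing > 0) {
    inform(paste0(n_both_missing, " unscorable subject(s) with both z-scores missing."))
  }
  data$min_z <- min_z
  data$call <- dplyr::if_else(min_z < cutoff, "impaired", "WNL")
  data
}

#' Confusion matrix from calls and truth
#'
#' Counts `tp` (impaired & MCI), `fp` (impaired & HC), `tn` (WNL & HC) and
#' `fn` (WNL & MCI). Records with a missing call (unscorable) are dropped
#' with a message; records with missing truth are an error.
#'
#' @param data Data frame with `call` (`impaired`/`WNL`) and `truth`
#'   (`MCI`/`HC`) columns, e.g. from [classify_impairment()].
#' @return A `confusion_matrix` object (also buildable directly with
#'   [confusion_counts()]).
#' @export
confusion_matrix <- function(data) {
  data <- as_tibble(data)
  if (!all(c("call", "truth") %in% names(data))) {
    abort("confusion_matrix() needs columns call and truth.")
  }
  if (anyNA(data$truth)) {
    ids <- if ("id" %in% names(data)) data$id[is.na(data$truth)]
           else which(is.na(data$truth))
    abort(paste0("Missing truth label for record(s): ",
                 paste(head(ids, 10), collapse = ", ")))
  }
  if (!all(data$truth %in% c("MCI", "HC"))) {
    abort("truth must be 'MCI' or 'HC'.")
  }
  dropped <- sum(is.na(data$call))
  if (dropped > 0) {
    inform(paste0("Dropping ", dropped, " record(s) with no impairment call."))
    data <- data[!is.na(data$call), ]
  }
  confusion_counts(
    tp = sum(data$call == "impaired" & data$truth == "MCI"),
    fp = sum(data$call == "impaired" & data$truth == "HC"),
    tn = sum(data$call == "WNL" & data$truth == "HC"),
    fn = sum(data$call == "WNL" & data$truth == "MCI")
  )
}

#' @rdname confusion_matrix
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.")
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(call = c("impaired", "WNL"),
                              truth = c("MCI", "HC")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and Youden's J
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`,
#' `youden_j = sensitivity + specificity - 1`. A Youden index of 0.5 or
#' higher is conventionally read as acceptable discriminability.
#'
#' @param cm A [confusion_matrix()] / [confusion_counts()] object.
#' @return One-row tibble: counts, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @examples
#' screen_diagnostics(confusion_counts(27, 5, 25, 3))
#' @export
screen_diagnostics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) {
    abort("Sensitivity undefined: no true-positive class (MCI) records.",
          class = "c3b_undefined_metric")
  }
  if (cm$tn + cm$fp == 0) {
    abort("Specificity undefined: no control (HC) records.",
          class = "c3b_undefined_metric")
  }
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  tibble(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
         sensitivity = sens, specificity = spec,
         youden_j = sens + spec - 1)
}

check_two_classes <- function(score, truth, positive) {
  keep <- !is.na(score) & !is.na(truth)
  score <- score[keep]; truth <- truth[keep]
  is_pos <- truth == positive
  if (!any(is_pos) || all(is_pos)) {
    abort("ROC needs both classes present.", class = "c3b_single_class")
  }
  list(cases = score[is_pos], controls = score[!is_pos])
}

#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC over all distinct observed scores, oriented
#' so that larger scores indicate the positive class (for the min-z rule
#' pass `score = -min_z`, so that more impaired subjects score higher).
#' The AUC is the trapezoidal area, identical to the pairwise probability
#' `P(case > control) + 0.5 P(tie)`.
#'
#' @param data Data frame holding the score and truth columns.
#' @param score Column with the discriminant score (tidy-eval).
#' @param truth Column with class labels.
#' @param positive Label of the positive (case) class, default `"MCI"`.
#' @return A `roc_curve` object: tibble of `threshold`, `fpr`, `tpr` (one
#'   row per distinct threshold plus the two endpoints) with the AUC in
#'   attribute `"auc"`; see [glance()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(s = c(3, 1, 2, 0), g = c("MCI", "MCI", "HC", "HC"))
#' glance(roc_curve(d, s, g))
#' @export
roc_curve <- function(data, score, truth, positive = "MCI") {
  data <- as_tibble(data)
  score <- rlang::eval_tidy(rlang::enquo(score), data)
  truth <- rlang::eval_tidy(rlang::enquo(truth), data)
  cls <- check_two_classes(score, truth, positive)
  thresholds <- sort(unique(c(cls$cases, cls$controls)), decreasing = TRUE)
  pts <- tibble(
    threshold = c(Inf, thresholds),
    tpr = vapply(c(Inf, thresholds),
                 function(t) mean(cls$cases >= t), 0),
    fpr = vapply(c(Inf, thresholds),
                 function(t) mean(cls$controls >= t), 0)
  )
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(pts[, c("threshold", "fpr", "tpr")],
            auc = auc,
            class = c("roc_curve", class(pts)))
}

#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_thresholds = nrow(x))
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    )
}

#' Youden-optimal cutoff
#'
#' Scans candidate thresholds midway between adjacent distinct observed
#' scores (plus the two infinite endpoints), calling a subject positive
#' when `score > cutoff`, and returns the cutoff maximizing Youden's J.
#' Ties are broken toward higher specificity (the larger cutoff). When the
#' discriminant is `-min_z`, a returned cutoff `c` corresponds to the
#' impairment rule `min_z < -c`.
#'
#' @inheritParams roc_curve
#' @return One-row tibble: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_optimal_cutoff <- function(data, score, truth, positive = "MCI") {
  data <- as_tibble(data)
  score <- rlang::eval_tidy(rlang::enquo(score), data)
  truth <- rlang::eval_tidy(rlang::enquo(truth), data)
  cls <- check_two_classes(score, truth, positive)
  v <- sort(unique(c(cls$cases, cls$controls)))
  candidates <- c(-Inf, if (length(v) > 1) (head(v, -1) + v[-1]) / 2, Inf)
  sens <- vapply(candidates, function(t) mean(cls$cases > t), 0)
  spec <- vapply(candidates, function(t) mean(cls$controls <= t), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  tibble(cutoff = candidates[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = j[best])
}

#' Independent-groups comparison with Cohen's d
#'
#' Student's two-sample t-test (pooled variance; Welch optionally) with the
#' pooled-SD standardized mean difference
#' `d = (mean_b - mean_a) / s_pooled`, `s_pooled^2 = ((n_a - 1) s_a^2 +
#' (n_b - 1) s_b^2) / (n_a + n_b - 2)`. With the case group passed first
#' (`a` = MCI, `b` = HC) a positive `d` means cases score lower.
#'
#' @param group_a,group_b Numeric vectors of the two groups' values.
#' @param welch Use Welch's unequal-variance t instead of Student's.
#' @return One-row tibble with group summaries, `t`, `df`, `p.value` and
#'   `cohens_d`.
#' @examples
#' independent_groups_summary(rnorm(30, 28.6, 11.3), rnorm(30, 44.3, 8.5))
#' @export
independent_groups_summary <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 <= 0) {
    abort("Degenerate data: zero pooled variance.", class = "c3b_degenerate")
  }
  tt <- stats::t.test(group_b, group_a, var.equal = !welch)
  tibble(
    mean_a = mean(group_a), sd_a = sd(group_a), n_a = na,
    mean_b = mean(group_b), sd_b = sd(group_b), n_b = nb,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value,
    cohens_d = (mean(group_b) - mean(group_a)) / sqrt(sp2)
  )
}
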