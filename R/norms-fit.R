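#' Basis specifications for normative regressions
#'
#' A basis describes the design of a normative regression: how age enters
#' nonlinearly and whether a sex term is included. `pst_basis()` and
#' `vmt_basis()` are the published forms; `linear_age_basis()` is the
#' simplest candidate for model selection.
#'
#' @param name Label used in selection/comparison tables.
#' @param nonlinear Nonlinear age term type.
#' @param constant Centering value (`centered_quadratic`) or knot in years
#'   (`knot_quadratic`).
#' @param center Centering constant for the quadratic age term.
#' @param knot Knot (years) for the spline term `max(0, age - knot)^2`.
#' @param include_sex Include a sex indicator column?
#' @return A `norm_basis` list: `name`, `nonlinear`, `constant`,
#'   `include_sex`.
#' @export
norm_basis <- function(name, nonlinear = c("none", "centered_quadratic",
                                           "knot_quadratic"),
                       constant = NA_real_, include_sex = TRUE) {
  nonlinear <- match.arg(nonlinear)
  if (nonlinear != "none" && !is.finite(constant)) {
    abort("A nonlinear basis needs its centering/knot constant.")
  }
  structure(list(name = name, nonlinear = nonlinear, constant = constant,
                 include_sex = include_sex),
            class = "norm_basis")
}

#' @rdname norm_basis
#' @export
pst_basis <- function(center = 50.26714) {
  norm_basis("quadratic_age_centered", "centered_quadratic", center,
             include_sex = TRUE)
}

#' @rdname norm_basis
#' @export
vmt_basis <- function(knot = 71) {
  norm_basis("knot_quadratic_age", "knot_quadratic", knot, include_sex = FALSE)
}

#' @rdname norm_basis
#' @export
linear_age_basis <- function(include_sex = TRUE) {
  norm_basis("linear_age", "none", include_sex = include_sex)
}

basis_design <- function(basis, data) {
  X <- cbind(
    intercept = rep(1, nrow(data)),
    age = data$age,
    education = data$education
  )
  if (basis$nonlinear != "none") {
    X <- cbind(X, nonlinear_age = nonlinear_basis(basis$nonlinear,
                                                  basis$constant, data$age))
  }
  if (basis$include_sex) X <- cbind(X, sex = normalize_sex(data$sex))
  X <- cbind(X, race = normalize_race(data$race))
  X
}

#' Fit a normative regression on a cohort
#'
#' Ordinary least squares fit of the specified basis to one raw-score
#' outcome. The residual standard deviation (denominator `n - p`) is the
#' RMSE used as the z-score denominator of the resulting normative model.
#'
#' @param data Cohort table with columns `age`, `education`, `sex`, `race`
#'   and the outcome column.
#' @param outcome Outcome column name, e.g. `"pst_raw"`.
#' @param basis A [norm_basis()] (default chosen from the outcome name:
#'   `pst_basis()` for PST, `vmt_basis()` for VMT).
#' @return A `norm_fit` object: the underlying `lm` fit plus the extracted
#'   [norm_model][norms], `adjusted_r2`, `rmse`, `n` and the basis. Use
#'   [tidy()] for the coefficient table and [glance()] for fit statistics.
#' @examples
#' cohort <- generate_normative_cohort(seed = 1)
#' fit <- fit_norm_model(cohort, "pst_raw")
#' glance(fit)
#' @export
fit_norm_model <- function(data, outcome, basis = NULL) {
  data <- as_tibble(data)
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome column '", outcome, "' not found."))
  }
  test <- if (grepl("pst", outcome, ignore.case = TRUE)) "pst"
          else if (grepl("vmt", outcome, ignore.case = TRUE)) "vmt"
          else "pst"
  basis <- basis %||% if (test == "vmt") vmt_basis() else pst_basis()
  keep <- stats::complete.cases(data[, c("age", "education", "sex", "race",
                                         outcome)])
  if (sum(!keep) > 0) {
    inform(paste0("Dropping ", sum(!keep), " incomplete row(s) before fitting."))
  }
  data <- data[keep, ]
  X <- basis_design(basis, data)
  p <- ncol(X)
  if (nrow(data) < max(30, p + 1)) {
    abort("Too few complete rows to fit a normative model (need >= 30).")
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Singular design: column(s) ", paste(bad, collapse = ", "),
                 " are collinear or constant."),
          class = "c3b_singular_design")
  }
  y <- data[[outcome]]
  fit <- lm(y ~ X - 1)
  names(fit$coefficients) <- colnames(X)
  s <- summary(fit)
  # summary(lm) on an explicit intercept column reports the uncentered R^2;
  # recompute both R^2 forms against the mean-centered total sum of squares.
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  coefs <- coef(fit)
  cm <- list(intercept = coefs[["intercept"]], age = coefs[["age"]],
             nonlinear_age = if ("nonlinear_age" %in% names(coefs))
               coefs[["nonlinear_age"]] else 0,
             education = coefs[["education"]])
  if (basis$include_sex) cm$sex <- coefs[["sex"]]
  cm$race <- coefs[["race"]]
  model <- new_norm_model(
    test = test, coefficients = unlist(cm), rmse = s$sigma,
    nonlinear = basis$nonlinear, constant = basis$constant,
    id = paste0(test, "_refit_", basis$name)
  )
  structure(
    list(fit = fit, model = model, basis = basis, outcome = outcome,
         n = n, p = p, r2 = r2, adjusted_r2 = adj_r2, rmse = s$sigma,
         std_errors = stats::setNames(s$coefficients[, "Std. Error"],
                                      colnames(X))),
    class = "norm_fit"
  )
}

#' @export
print.norm_fit <- function(x, ...) {
  cat("<norm_fit>", x$outcome, "~", x$basis$name, "\n")
  cat(sprintf("  n = %d, adjusted R^2 = %.4f, RMSE = %.3f\n",
              x$n, x$adjusted_r2, x$rmse))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.norm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.norm_fit <- function(x, ...) {
  tibble(
    r.squared = x$r2,
    adj.r.squared = x$adjusted_r2,
    rmse = x$rmse,
    n = x$n,
    df.residual = x$n - x$p
  )
}

#' Select the best-fitting normative basis by adjusted R-squared
#'
#' Fits every candidate basis and returns the fit with the highest adjusted
#' R-squared; ties are broken toward the basis with fewer coefficients.
#' Candidates whose design is singular are skipped (an error is raised only
#' when every candidate is singular).
#'
#' @inheritParams fit_norm_model
#' @param candidates List of [norm_basis()] objects.
#' @return The winning `norm_fit`, with the comparison table in attribute
#'   `"comparison"`.
#' @export
select_norm_model <- function(data, outcome, candidates) {
  stopifnot(length(candidates) >= 1)
  fits <- lapply(candidates, function(b) {
    tryCatch(fit_norm_model(data, outcome, b),
             c3b_singular_design = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort("All candidate bases have singular designs.",
          class = "c3b_singular_design")
  }
  fits <- fits[ok]
  adj <- vapply(fits, `[[`, 0, "adjusted_r2")
  p <- vapply(fits, `[[`, 0L, "p")
  best <- order(-adj, p)[1]
  winner <- fits[[best]]
  attr(winner, "comparison") <- tibble(
    basis = vapply(fits, function(f) f$basis$name, ""),
    n_coefficients = p,
    adj.r.squared = adj
  )
  winner
}
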