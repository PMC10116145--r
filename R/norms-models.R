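#' Regression-based normative models
#'
#' Demographically adjusted z-scores compare an observed raw score with the
#' score predicted from age, education, sex and race by a normative
#' regression fitted on healthy adults:
#' `z = (raw - predicted) / RMSE`, where RMSE is the residual standard
#' deviation of the normative fit. The PST model uses a quadratic age term
#' centered at 50.26714; the VMT model uses a quadratic spline term
#' `max(0, age - 71)^2` that only activates above age 71 and has no sex
#' term. Indicator coding is male = 1 / female = 0 and
#' African-American = 1 / other = 0.
#'
#' @name norms
NULL

new_norm_model <- function(test, coefficients, rmse, nonlinear, constant,
                           id = NULL) {
  stopifnot(rmse > 0, test %in% c("pst", "vmt"),
            nonlinear %in% c("none", "centered_quadratic", "knot_quadratic"))
  structure(
    list(test = test, coefficients = coefficients, rmse = rmse,
         nonlinear = nonlinear, constant = constant,
         id = id %||% paste0(test, "_custom")),
    class = "norm_model"
  )
}

#' @export
print.norm_model <- function(x, ...) {
  cat("<norm_model>", x$id, "\n")
  cat("  test:", toupper(x$test), " rmse:", x$rmse, "\n")
  cat("  nonlinear age:", x$nonlinear, "(", x$constant, ")\n")
  print(x$coefficients)
  invisible(x)
}

#' Published normative coefficient sets
#'
#' The normative study's final parametric regressions. PST:
#' intercept 65.2217, age -0.4591, quadratic age (centered on 50.26714)
#' -0.0053, education 0.7999, sex (male = 1) -2.2132, race (AA = 1)
#' -4.0893, RMSE 8.958. VMT: intercept 58.8785, age -0.3118,
#' `max(0, age - 71)^2` -0.0329, education 0.7152, race -5.6555, no sex
#' term, RMSE 12.879.
#'
#' @return Named list with `pst` and `vmt` [norm_model][norms] objects.
#' @examples
#' builtin_models()$pst$rmse
#' @export
builtin_models <- function() {
  read_norm_models(system.file("extdata", "normative_coefficients.json",
                               package = "c3b"))
}

#' Read / write normative coefficient sets
#'
#' Coefficient sets are serialized as JSON with fields `id`, `test`,
#' `coefficients` (named), `rmse`, `nonlinear` and `constant` (the
#' centering value or knot). The shipped file
#' `extdata/normative_coefficients.json` holds the published sets verbatim.
#'
#' @param path File path.
#' @return `read_norm_models()`: named list of `norm_model`s keyed by test.
#' @export
read_norm_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(raw$models, function(m) {
    new_norm_model(
      test = m$test,
      coefficients = unlist(m$coefficients),
      rmse = m$rmse,
      nonlinear = m$nonlinear,
      constant = m$constant,
      id = m$id
    )
  })
  stats::setNames(models, vapply(models, `[[`, "", "test"))
}

#' @rdname read_norm_models
#' @param models Named list of `norm_model`s.
#' @export
write_norm_models <- function(models, path) {
  out <- list(
    schema_version = 1L,
    models = lapply(unname(models), function(m) {
      list(id = m$id, test = m$test,
           coefficients = as.list(m$coefficients),
           rmse = m$rmse, nonlinear = m$nonlinear, constant = m$constant)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Nonlinear age basis term
#'
#' PST uses a quadratic centered on 50.26714: `(age - 50.26714)^2`. VMT
#' uses a single-knot quadratic spline: `max(0, age - 71)^2`, zero at or
#' below the knot.
#'
#' @param test `"pst"` or `"vmt"`.
#' @param age Age in years (vectorized).
#' @return Numeric vector of basis values.
#' @export
nonlinear_age_term <- function(test, age) {
  test <- match.arg(test, c("pst", "vmt"))
  stopifnot(all(age >= 0))
  if (test == "pst") (age - 50.26714)^2 else pmax(0, age - 71)^2
}

nonlinear_basis <- function(nonlinear, constant, age) {
  switch(nonlinear,
    none = rep(0, length(age)),
    centered_quadratic = (age - constant)^2,
    knot_quadratic = pmax(0, age - constant)^2,
    abort(paste0("Unknown nonlinear basis: ", nonlinear))
  )
}

normalize_sex <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- toupper(trimws(as.character(sex)))
    out <- dplyr::case_match(sex, c("M", "MALE", "1") ~ 1,
                             c("F", "FEMALE", "0") ~ 0, "" ~ NA_real_)
    if (any(is.na(out) & !(is.na(sex) | sex == ""))) {
      abort("sex must be coded M/F (or 1/0, male = 1).")
    }
    return(out)
  }
  if (!all(sex %in% c(0, 1, NA))) abort("sex indicator must be 0/1 (male = 1).")
  as.numeric(sex)
}

normalize_race <- function(race) {
  if (is.character(race) || is.factor(race)) {
    race <- toupper(trimws(as.character(race)))
    out <- dplyr::case_match(race, c("AA", "AFRICAN-AMERICAN", "BLACK", "1") ~ 1,
                             c("NONAA", "NON-AA", "OTHER", "WHITE", "0") ~ 0,
                             "" ~ NA_real_)
    if (any(is.na(out) & !(is.na(race) | race == ""))) {
      abort("race must be coded AA/nonAA (or 1/0, African-American = 1).")
    }
    return(out)
  }
  if (!all(race %in% c(0, 1, NA))) abort("race indicator must be 0/1 (AA = 1).")
  as.numeric(race)
}

check_age_range <- function(age) {
  out_of_range <- !is.na(age) & (age < 18 | age > 89)
  if (any(out_of_range)) {
    warn(paste0(sum(out_of_range), " age value(s) outside the normed range ",
                "18-89; predictions are extrapolations."))
  }
  out_of_range
}

#' Demographically predicted score
#'
#' Evaluates the normative linear predictor
#' `intercept + b_age*age + b_nl*basis(age) + b_edu*education +
#' b_sex*sex + b_race*race` (the sex term exists only for the PST model).
#'
#' @param model A `norm_model`.
#' @param age,education Years (vectorized).
#' @param sex Male = 1, female = 0 (or `"M"`/`"F"`); ignored by models
#'   without a sex term.
#' @param race African-American = 1, other = 0 (or `"AA"`/`"nonAA"`).
#' @return Numeric vector of predicted raw scores, with attribute
#'   `extrapolated` flagging ages outside 18-89 (also warned about).
#' @examples
#' predict_score(builtin_models()$vmt, age = 30, education = 16, race = 0)
#' @export
predict_score <- function(model, age, education, sex = 0, race = 0) {
  stopifnot(inherits(model, "norm_model"), all(education >= 0, na.rm = TRUE))
  sex <- normalize_sex(sex)
  race <- normalize_race(race)
  extrapolated <- check_age_range(age)
  b <- model$coefficients
  pred <- b[["intercept"]] + b[["age"]] * age +
    b[["nonlinear_age"]] * nonlinear_basis(model$nonlinear, model$constant, age) +
    b[["education"]] * education +
    (if ("sex" %in% names(b)) b[["sex"]] * sex else 0) +
    b[["race"]] * race
  attr(pred, "extrapolated") <- extrapolated
  pred
}

#' Demographically adjusted z-score
#'
#' `z = (raw - predicted) / RMSE`. Values below about -1.5 are typically
#' read as below expectation for the subject's demographics; the screening
#' cutoff used downstream is z < -0.4 on the lower of the two tests.
#'
#' @inheritParams predict_score
#' @param raw Observed raw score(s).
#' @return Numeric vector of z-scores (full precision; round to 2 decimals
#'   for display).
#' @examples
#' adjusted_z(33, builtin_models()$vmt, age = 30, education = 16, race = 0)
#' @export
adjusted_z <- function(raw, model, age, education, sex = 0, race = 0) {
  if (!inherits(model, "norm_model") || !is.numeric(model$rmse) ||
      model$rmse <= 0) {
    abort("Invalid normative model: rmse must be positive.",
          class = "c3b_config_error")
  }
  as.numeric(raw - predict_score(model, age, education, sex, race)) / model$rmse
}

#' Add predicted scores and adjusted z-scores to a cohort table
#'
#' Pipe-friendly wrapper around [predict_score()] and [adjusted_z()]: for
#' each raw-score column present (`pst_raw`, `vmt_raw`) it appends the
#' prediction (`pst_pred`, `vmt_pred`) and z-score (`z_pst`, `z_vmt`).
#'
#' @param data Data frame with columns `age`, `education`, `sex`, `race`
#'   and at least one of `pst_raw`, `vmt_raw`.
#' @param models Named list of `norm_model`s (default the published sets).
#' @return `data` as a tibble with prediction and z columns appended.
#' @examples
#' tibble::tibble(age = 30, education = 16, sex = "F", race = "nonAA",
#'                vmt_raw = 33) |> add_adjusted_z()
#' @export
add_adjusted_z <- function(data, models = builtin_models()) {
  data <- as_tibble(data)
  needed <- c("age", "education", "sex", "race")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing demographic column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("pst_raw", "vmt_raw") %in% names(data))) {
    abort("Need at least one raw-score column (pst_raw, vmt_raw).")
  }
  for (test in intersect(c("pst", "vmt"), names(models))) {
    raw_col <- paste0(test, "_raw")
    if (!raw_col %in% names(data)) next
    m <- models[[test]]
    pred <- predict_score(m, data$age, data$education, data$sex, data$race)
    data[[paste0(test, "_pred")]] <- as.numeric(pred)
    data[[paste0("z_", test)]] <- (data[[raw_col]] - as.numeric(pred)) / m$rmse
  }
  data
}
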