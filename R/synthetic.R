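#' Synthetic cohort generators
#'
#' Seeded generators for every input the pipeline consumes: a stratified
#' normative cohort whose raw scores follow the published regression
#' models plus residual noise, MCI / healthy-control case-control samples
#' with the published group means and SDs, bivariate-normal retest pairs
#' with a known true reliability, and simulated VMT trial responses. All
#' generators are bit-reproducible under a fixed seed and attach their
#' generating spec to the result (attribute `"spec"`).
#'
#' @name synthetic
NULL

#' Normative stratification cell counts
#'
#' The 3 age bands x 3 education bands x 2 sexes layout of the normative
#' sample (total n = 428).
#'
#' @return Tibble with `sex` (`F`/`M`), `age_band`, `edu_band`, `n`.
#' @export
normative_strata <- function() {
  tibble(
    sex = rep(c("F", "M"), each = 9),
    age_band = rep(rep(c("18-39", "40-59", "60-89"), each = 3), 2),
    edu_band = rep(c("9-12", "13-15", "16-20"), 6),
    n = c(22, 28, 24, 17, 25, 24, 27, 33, 29,
          22, 24, 23, 17, 21, 26, 11, 21, 34)
  )
}

band_range <- function(band) {
  parts <- as.integer(strsplit(band, "-", fixed = TRUE)[[1]])
  parts[1]:parts[2]
}

#' Specification of a synthetic normative cohort
#'
#' Defaults reproduce the normative study conditions: the stratification
#' of [normative_strata()] (n = 428), a 17.1% African-American fraction
#' assigned independently of stratum, raw scores generated from the
#' published regression models with Gaussian noise whose SD equals each
#' model's RMSE, rounded to integers and clipped to the attainable range
#' (PST >= 0; VMT 0-70). Within bands, ages and education years are
#' uniform on integers. `total_n` rescales the strata proportionally
#' (largest-remainder rounding) while keeping the published mix.
#'
#' @param total_n Optional total size replacing the default 428.
#' @param strata Stratification table as in [normative_strata()].
#' @param aa_fraction Probability a subject is African-American.
#' @param models Generating models (named list, default [builtin_models()]).
#' @param noise_sd Named residual SDs per test; default each model's RMSE.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(total_n = NULL, strata = normative_strata(),
                        aa_fraction = 0.171, models = builtin_models(),
                        noise_sd = NULL) {
  stopifnot(all(strata$n >= 0), aa_fraction >= 0, aa_fraction <= 1)
  noise_sd <- noise_sd %||%
    vapply(models, `[[`, 0, "rmse")
  stopifnot(all(noise_sd > 0))
  if (!is.null(total_n)) {
    stopifnot(total_n >= nrow(strata))
    share <- strata$n / sum(strata$n) * total_n
    n_new <- floor(share)
    rem <- total_n - sum(n_new)
    if (rem > 0) {
      top_up <- order(share - n_new, decreasing = TRUE)[seq_len(rem)]
      n_new[top_up] <- n_new[top_up] + 1L
    }
    strata$n <- as.integer(n_new)
  }
  structure(list(strata = strata, aa_fraction = aa_fraction,
                 models = models, noise_sd = noise_sd),
            class = "cohort_spec")
}

clip_scores <- function(x, test) {
  x <- round(x)
  if (test == "vmt") pmin(pmax(x, 0), 70) else pmax(x, 0)
}

#' Generate a stratified normative cohort
#'
#' One record per stratum slot: age and education uniform on the integer
#' years of the stratum's bands, sex from the stratum, race Bernoulli at
#' the specified fraction; raw scores are each model's linear predictor
#' plus Gaussian noise, rounded and clipped.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return Tibble `id, age, education, sex, race, pst_raw, vmt_raw` with
#'   the spec attached as attribute `"spec"`.
#' @examples
#' cohort <- generate_normative_cohort(seed = 1)
#' nrow(cohort)  # 428
#' @export
generate_normative_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed_if(seed, {
    strata <- spec$strata
    rows <- tidyr::uncount(strata, n)
    n <- nrow(rows)
    age <- vapply(rows$age_band,
                  function(b) sample(band_range(b), 1), 0L)
    education <- vapply(rows$edu_band,
                        function(b) sample(band_range(b), 1), 0L)
    out <- tibble(
      id = sprintf("norm_%04d", seq_len(n)),
      age = as.integer(age),
      education = as.integer(education),
      sex = as.integer(rows$sex == "M"),
      race = rbinom(n, 1, spec$aa_fraction)
    )
    for (test in names(spec$models)) {
      m <- spec$models[[test]]
      mu <- as.numeric(predict_score(m, out$age, out$education, out$sex,
                                     out$race))
      out[[paste0(test, "_raw")]] <-
        clip_scores(mu + rnorm(n, 0, spec$noise_sd[[test]]), test)
    }
    attr(out, "spec") <- spec
    out
  })
}

#' Specification of an MCI / healthy-control case-control sample
#'
#' Defaults follow the clinical validation sample: 30 subjects per group;
#' PST means (SD) 28.61 (11.27) for MCI versus 44.27 (8.48) for controls;
#' VMT 26.57 (14.97) versus 51.63 (14.18); elderly demographics (MCI age
#' 75.07 (7.23), 60% male, 20% African-American; controls 73.53 (5.25),
#' 56.7% male, 16.7% AA; education about 15.7 (3) in both), ages kept in
#' the 60-89 normative band.
#'
#' @param n_per_group Subjects per group.
#' @param score_params Named list `pst`/`vmt`, each a list with `mci` and
#'   `hc` mean-SD pairs `c(mean, sd)`.
#' @param demo_params Named list `mci`/`hc` of demographic parameters
#'   (`age_mean`, `age_sd`, `edu_mean`, `edu_sd`, `male_frac`, `aa_frac`).
#' @return A `case_control_spec` list.
#' @export
case_control_spec <- function(
    n_per_group = 30,
    score_params = list(
      pst = list(mci = c(28.61, 11.27), hc = c(44.27, 8.48)),
      vmt = list(mci = c(26.57, 14.97), hc = c(51.63, 14.18))
    ),
    demo_params = list(
      mci = list(age_mean = 75.07, age_sd = 7.23, edu_mean = 15.77,
                 edu_sd = 2.90, male_frac = 0.600, aa_frac = 0.200),
      hc = list(age_mean = 73.53, age_sd = 5.25, edu_mean = 15.70,
                edu_sd = 3.06, male_frac = 0.567, aa_frac = 0.167)
    )) {
  stopifnot(n_per_group >= 2)
  for (test in names(score_params)) {
    for (g in c("mci", "hc")) stopifnot(score_params[[test]][[g]][2] > 0)
  }
  structure(list(n_per_group = n_per_group, score_params = score_params,
                 demo_params = demo_params),
            class = "case_control_spec")
}

#' Generate an MCI / healthy-control sample
#'
#' Per-group Gaussian raw-score draws, rounded and clipped to the
#' attainable ranges (PST >= 0, VMT 0-70), with demographics drawn from
#' the elderly normative band (ages clipped to 60-89, education to 2-20).
#'
#' @param spec A [case_control_spec()].
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return Tibble `id, truth, age, education, sex, race, pst_raw,
#'   vmt_raw`, `truth` in `{"MCI", "HC"}`; spec in attribute `"spec"`.
#' @export
generate_case_control <- function(spec = case_control_spec(), seed = NULL) {
  stopifnot(inherits(spec, "case_control_spec"))
  with_seed_if(seed, {
    one_group <- function(label) {
      g <- tolower(ifelse(label == "MCI", "mci", "hc"))
      n <- spec$n_per_group
      dp <- spec$demo_params[[g]]
      out <- tibble(
        id = sprintf("%s_%03d", tolower(label), seq_len(n)),
        truth = label,
        age = as.integer(pmin(pmax(round(rnorm(n, dp$age_mean, dp$age_sd)),
                                   60), 89)),
        education = as.integer(pmin(pmax(round(rnorm(n, dp$edu_mean,
                                                     dp$edu_sd)), 2), 20)),
        sex = rbinom(n, 1, dp$male_frac),
        race = rbinom(n, 1, dp$aa_frac)
      )
      for (test in names(spec$score_params)) {
        ms <- spec$score_params[[test]][[g]]
        out[[paste0(test, "_raw")]] <-
          clip_scores(rnorm(n, ms[1], ms[2]), test)
      }
      out
    }
    out <- dplyr::bind_rows(one_group("MCI"), one_group("HC"))
    attr(out, "spec") <- spec
    out
  })
}

#' Specification of a retest sample
#'
#' Bivariate-normal pairs with a known true correlation. Defaults mimic
#' the reliability sample: 30 healthy elders with occasion means and SDs
#' near the observed PST values and a true reliability of 0.83.
#'
#' @param n Number of pairs.
#' @param mean1,sd1,mean2,sd2 Occasion means and SDs.
#' @param rho True correlation between occasions (in `[-1, 1]`).
#' @return A `retest_spec` list.
#' @export
retest_spec <- function(n = 30, mean1 = 44.4, sd1 = 8.6,
                        mean2 = 45.7, sd2 = 8.2, rho = 0.83) {
  stopifnot(n >= 2, sd1 > 0, sd2 > 0, rho >= -1, rho <= 1)
  structure(list(n = n, mean1 = mean1, sd1 = sd1, mean2 = mean2, sd2 = sd2,
                 rho = rho),
            class = "retest_spec")
}

#' Generate retest pairs
#'
#' @param spec A [retest_spec()].
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return Tibble `id, t1, t2`; spec in attribute `"spec"`.
#' @export
generate_retest <- function(spec = retest_spec(), seed = NULL) {
  stopifnot(inherits(spec, "retest_spec"))
  with_seed_if(seed, {
    sigma <- matrix(c(spec$sd1^2, spec$rho * spec$sd1 * spec$sd2,
                      spec$rho * spec$sd1 * spec$sd2, spec$sd2^2), 2, 2)
    m <- MASS::mvrnorm(spec$n, mu = c(spec$mean1, spec$mean2), Sigma = sigma)
    out <- tibble(id = sprintf("retest_%04d", seq_len(spec$n)),
                  t1 = m[, 1], t2 = m[, 2])
    attr(out, "spec") <- spec
    out
  })
}

#' Simulate VMT trial responses of given accuracy
#'
#' Symbols are placed one at a time in random order: with probability
#' `accuracy` a symbol goes to its correct cell (if still free; otherwise
#' to a random free cell), else to a random free cell other than its
#' correct one. Used to exercise session scoring end-to-end.
#'
#' @param stimulus A [generate_vmt_stimulus()] stimulus.
#' @param accuracy Per-trial placement probability, scalar or one value
#'   per trial.
#' @param n_trials Number of trials to simulate (default 5).
#' @param avoid_targets If `TRUE`, wrong placements avoid every target
#'   cell, so location credit is impossible (score counts correct
#'   placements only).
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return List of placement tibbles, one per trial.
#' @export
generate_vmt_responses <- function(stimulus, accuracy = 0.7, n_trials = 5,
                                   avoid_targets = FALSE, seed = NULL) {
  stopifnot(inherits(stimulus, "vmt_stimulus"),
            all(accuracy >= 0), all(accuracy <= 1))
  accuracy <- rep_len(accuracy, n_trials)
  all_cells <- cell_key(rep(1:4, times = 6), rep(1:6, each = 4))
  target <- stats::setNames(cell_key(stimulus$board$row, stimulus$board$col),
                            stimulus$board$symbol)
  with_seed_if(seed, {
    purrr::map(seq_len(n_trials), function(trial) {
      free <- all_cells
      placed_cell <- character(0)
      placed_symbol <- character(0)
      for (s in sample(names(target))) {
        own <- target[[s]]
        hit <- runif(1) < accuracy[trial]
        cell <- if (hit && own %in% free) {
          own
        } else {
          choices <- setdiff(free, own)
          if (avoid_targets) choices <- setdiff(choices, target)
          if (length(choices) == 0) own else sample(choices, 1)
        }
        free <- setdiff(free, cell)
        placed_cell <- c(placed_cell, cell)
        placed_symbol <- c(placed_symbol, s)
      }
      parts <- do.call(rbind, strsplit(placed_cell, ",", fixed = TRUE))
      tibble(row = as.integer(parts[, 1]), col = as.integer(parts[, 2]),
             symbol = placed_symbol)
    })
  })
}
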