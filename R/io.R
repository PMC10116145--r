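#' Readers, writers and report rendering
#'
#' Cohort and pairs tables travel as comma-separated text (header row,
#' UTF-8, empty fields = missing). Session records, generator specs,
#' coefficient sets and analysis reports are JSON with a `schema_version`
#' field. Every report embeds provenance: package version, coefficient-set
#' identifier and seed.
#'
#' @name cli_io
NULL

#' Read a cohort table
#'
#' Expects a header with a subset of
#' `id, age, education, sex, race, pst_raw, vmt_raw, z_pst, z_vmt, truth,
#' t1, t2`. Sex is accepted as `M`/`F` or 1/0 and race as `AA`/`nonAA` or
#' 1/0 and normalized to indicators on read. Unknown columns are an error;
#' malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Tibble with normalized columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  known <- c("id", "age", "education", "sex", "race", "pst_raw", "vmt_raw",
             "z_pst", "z_vmt", "truth", "t1", "t2", "group")
  # parse problems are collected and reported with line numbers below, so
  # readr's own warning is redundant here
  data <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA"))
  )
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(paste0("Malformed input row(s) at line(s): ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  unknown <- setdiff(names(data), known)
  if (length(unknown)) {
    abort(paste0("Unknown column(s): ", paste(unknown, collapse = ", ")))
  }
  if ("sex" %in% names(data)) data$sex <- normalize_sex(data$sex)
  if ("race" %in% names(data)) data$race <- normalize_race(data$race)
  for (col in intersect(c("age", "education", "pst_raw", "vmt_raw",
                          "z_pst", "z_vmt", "t1", "t2"), names(data))) {
    if (!is.numeric(data[[col]])) {
      abort(paste0("Column '", col, "' must be numeric."))
    }
  }
  data
}

#' @rdname read_cohort
#' @param data Cohort tibble.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(as_tibble(data), path, na = "")
  invisible(path)
}

provenance <- function(seed = NULL, coefficient_set = NULL) {
  list(
    tool = "c3b",
    tool_version = as.character(utils::packageVersion("c3b")),
    coefficient_set = coefficient_set %||% NA,
    seed = seed %||% NA,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Write an analysis report as JSON
#'
#' Wraps a named list of results (tibbles become arrays of records) with a
#' provenance block (tool version, coefficient-set id, seed) and a schema
#' version.
#'
#' @param results Named list of tibbles / scalars.
#' @param path Output path.
#' @param seed Seed used for any randomness (recorded, may be `NULL`).
#' @param coefficient_set Identifier of the coefficient set used.
#' @export
write_report <- function(results, path, seed = NULL, coefficient_set = NULL) {
  out <- c(list(schema_version = 1L,
                provenance = provenance(seed, coefficient_set)),
           results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read / write a VMT or PST session record
#'
#' A VMT session holds the stimulus (pattern id and board placements) and
#' the per-trial responses; a PST session holds the symbol-digit key, the
#' press stream and the scoring window. Coordinates are 1-based
#' `(row 1-4, col 1-6)`.
#'
#' @param path JSON file path.
#' @return `read_session()`: a list with `test` (`"vmt"`/`"pst"`) and the
#'   deserialized components.
#' @export
read_session <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$test) || !raw$test %in% c("vmt", "pst")) {
    abort("Session file must declare test: 'vmt' or 'pst'.")
  }
  if (raw$test == "vmt") {
    stim <- structure(
      list(pattern_id = raw$stimulus$pattern_id,
           board = as_tibble(raw$stimulus$board)),
      class = "vmt_stimulus"
    )
    responses <- lapply(raw$responses, as_tibble)
    list(test = "vmt", stimulus = stim, responses = responses)
  } else {
    key <- validate_pst_key(as_tibble(raw$key))
    list(test = "pst", key = key, stream = as_tibble(raw$stream),
         duration_s = raw$duration_s %||% 120)
  }
}

#' @rdname read_session
#' @param session A list as returned by [read_session()] (or assembled
#'   from the same components).
#' @export
write_session <- function(session, path) {
  stopifnot(session$test %in% c("vmt", "pst"))
  out <- if (session$test == "vmt") {
    list(schema_version = 1L, test = "vmt",
         coordinates = "row 1-4, col 1-6, 1-based",
         stimulus = list(pattern_id = session$stimulus$pattern_id,
                         board = session$stimulus$board),
         responses = session$responses)
  } else {
    list(schema_version = 1L, test = "pst",
         key = as_tibble(session$key),
         stream = session$stream,
         duration_s = session$duration_s %||% 120)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
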