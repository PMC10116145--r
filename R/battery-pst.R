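#' Processing speed test: key generation and scoring
#'
#' The processing speed test (PST) shows a symbol-to-digit key (9 symbols
#' mapped to the digits 1-9, regenerated for each administration from a pool
#' of 30 symbols) and rows of symbols the subject answers in order by digit
#' keypress. The test runs for 120 seconds; presses after the cutoff are not
#' scored. Both total correct and total incorrect presses are recorded.
#'
#' @name pst
NULL

#' The 30-symbol PST pool
#' @return Character vector of 30 abstract symbol identifiers.
#' @export
pst_symbol_pool <- function() sprintf("pst_symbol_%02d", 1:30)

#' Generate a PST symbol-digit key
#'
#' Samples 9 distinct symbols from the 30-symbol pool without replacement
#' and maps them to a random permutation of the digits 1-9. Deterministic
#' per seed.
#'
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A `pst_key`: tibble with columns `symbol` and `digit`.
#' @export
generate_pst_key <- function(seed = NULL) {
  with_seed_if(seed, {
    key <- tibble(
      symbol = sample(pst_symbol_pool(), 9),
      digit = sample.int(9)
    )
    class(key) <- c("pst_key", class(key))
    key
  })
}

validate_pst_key <- function(key) {
  key <- as_tibble(key)
  if (!all(c("symbol", "digit") %in% names(key)) || nrow(key) != 9 ||
      anyDuplicated(key$symbol) || !setequal(key$digit, 1:9)) {
    abort("A PST key must map 9 distinct symbols to the digits 1-9.",
          class = "c3b_invalid_key")
  }
  key
}

#' Score a PST response stream
#'
#' Each press answers the presented symbol at its position, in order. A
#' press is in-window when its timestamp is at most `duration_s` (closed
#' boundary at 120 s by default); later presses are ignored. An in-window
#' press is correct when its digit equals the key's digit for that symbol.
#'
#' @param key A [generate_pst_key()] key.
#' @param stream Data frame with one row per press, columns `symbol`
#'   (the item answered), `time_s` (non-decreasing seconds from test start)
#'   and `digit` (1-9).
#' @param duration_s Scoring window in seconds (default 120).
#' @return One-row tibble: `n_correct`, `n_incorrect`, `n_scored` (their
#'   sum) and `n_late` (presses beyond the window).
#' @export
score_pst <- function(key, stream, duration_s = 120) {
  key <- validate_pst_key(key)
  stream <- as_tibble(stream)
  if (nrow(stream) == 0) {
    return(tibble(n_correct = 0L, n_incorrect = 0L, n_scored = 0L, n_late = 0L))
  }
  if (!all(c("symbol", "time_s", "digit") %in% names(stream))) {
    abort("A PST stream needs columns symbol, time_s, digit.",
          class = "c3b_invalid_response")
  }
  if (is.unsorted(stream$time_s)) {
    abort("PST timestamps must be non-decreasing.", class = "c3b_invalid_response")
  }
  bad <- !(stream$digit %in% 1:9)
  if (any(bad)) {
    abort(paste0("Invalid response: digit outside 1-9 at press ",
                 paste(which(bad), collapse = ", ")),
          class = "c3b_invalid_response")
  }
  unknown <- setdiff(stream$symbol, key$symbol)
  if (length(unknown)) {
    abort(paste0("Stream contains symbols not in the key: ",
                 paste(unknown, collapse = ", ")),
          class = "c3b_invalid_response")
  }
  in_window <- stream$time_s <= duration_s
  scored <- stream[in_window, ]
  expected <- key$digit[match(scored$symbol, key$symbol)]
  n_correct <- sum(scored$digit == expected)
  tibble(
    n_correct = as.integer(n_correct),
    n_incorrect = as.integer(nrow(scored) - n_correct),
    n_scored = as.integer(nrow(scored)),
    n_late = as.integer(sum(!in_window))
  )
}

#' Simulate a PST response stream
#'
#' Items are drawn uniformly from the key's symbols (rows of 15, presented
#' on demand); inter-press intervals are Gamma-distributed with the given
#' mean; each press is correct with probability `accuracy`, otherwise a
#' uniformly random wrong digit. Used to exercise scoring end-to-end.
#'
#' @param key A PST key.
#' @param mean_interval_s Mean seconds between presses.
#' @param accuracy Probability a press is correct.
#' @param duration_s Stream length in seconds; a few presses beyond the
#'   window are included so the cutoff rule is exercised.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return A press tibble suitable for [score_pst()].
#' @export
simulate_pst_stream <- function(key, mean_interval_s = 2.5, accuracy = 0.95,
                                duration_s = 120, seed = NULL) {
  key <- validate_pst_key(key)
  stopifnot(accuracy >= 0, accuracy <= 1, mean_interval_s > 0)
  with_seed_if(seed, {
    n_max <- ceiling(1.5 * duration_s / mean_interval_s) + 10
    gaps <- stats::rgamma(n_max, shape = 4, rate = 4 / mean_interval_s)
    times <- cumsum(gaps)
    keep <- seq_len(min(n_max, sum(times <= duration_s) + 2))
    times <- times[keep]
    symbols <- sample(key$symbol, length(keep), replace = TRUE)
    right <- key$digit[match(symbols, key$symbol)]
    correct <- runif(length(keep)) < accuracy
    digit <- ifelse(correct, right,
                    vapply(right, function(d) sample(setdiff(1:9, d), 1),
                           integer(1)))
    tibble(symbol = symbols, time_s = times, digit = as.integer(digit))
  })
}
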