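#' Visual memory test: stimuli and scoring
#'
#' The visual memory test (VMT) presents 7 symbols on a 4x6 checkerboard for
#' 10 seconds; the subject then replaces the symbols from memory. Each of the
#' 7 target cells earns 2 points when it holds the correct symbol, 1 point
#' when it holds some (wrong) symbol, and 0 when empty, so a trial scores
#' 0-14. A session comprises 5 learning trials (maximum 70); after two
#' consecutive perfect trials the test is discontinued and the remaining
#' trials are allotted 14 points each.
#'
#' Symbols are abstract identifiers `<category>_<exemplar>`: one exemplar
#' (1-6) from each of 7 semantic categories, a universe of 42 symbols. No
#' artwork is rendered. Board coordinates are 1-based `(row 1-4, col 1-6)`.
#'
#' @name vmt
NULL

#' The 7 semantic symbol categories
#'
#' Each category contributes 6 exemplars, for a universe of 42 symbols.
#' @return Character vector of length 7.
#' @export
vmt_categories <- function() {
  c("fruits_vegetables", "human_activities", "animals", "plants",
    "vehicles", "clothing", "tools")
}

# The 6 canonical 7-cell location patterns, frozen constants. Chosen so that
# no two patterns share more than 3 cells; each cell is (row, col) on the
# 4x6 board. test-battery-vmt.R asserts the overlap bound.
vmt_location_patterns <- function() {
  list(
    matrix(c(1,1, 4,1, 1,2, 2,3, 1,5, 2,5, 4,6), ncol = 2, byrow = TRUE),
    matrix(c(2,1, 3,1, 4,1, 1,2, 1,3, 1,4, 1,6), ncol = 2, byrow = TRUE),
    matrix(c(1,1, 3,1, 4,2, 2,3, 3,3, 3,4, 4,6), ncol = 2, byrow = TRUE),
    matrix(c(2,1, 3,1, 2,2, 1,5, 2,5, 3,5, 3,6), ncol = 2, byrow = TRUE),
    matrix(c(2,1, 3,1, 2,2, 2,3, 4,5, 1,6, 4,6), ncol = 2, byrow = TRUE),
    matrix(c(3,1, 1,3, 2,3, 3,3, 4,3, 4,5, 3,6), ncol = 2, byrow = TRUE)
  )
}

vmt_symbol_id <- function(category, exemplar) paste(category, exemplar, sep = "_")

#' Generate a VMT stimulus
#'
#' Draws one of the 6 canonical location patterns uniformly, then one
#' exemplar (uniform on 1-6) from each of the 7 semantic categories, and
#' assigns the 7 symbols to the pattern's cells in random order. The draw is
#' reproducible: the same seed always yields the identical stimulus.
#'
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return An object of class `vmt_stimulus`: a list with `pattern_id`
#'   (1-6) and `board`, a tibble with columns `row`, `col`, `symbol`
#'   (7 rows, one symbol per category).
#' @examples
#' stim <- generate_vmt_stimulus(seed = 1)
#' stim$board
#' @export
generate_vmt_stimulus <- function(seed = NULL) {
  with_seed_if(seed, {
    pattern_id <- sample.int(6, 1)
    cells <- vmt_location_patterns()[[pattern_id]]
    cats <- vmt_categories()
    exemplars <- vapply(cats, function(x) sample.int(6, 1), integer(1))
    symbols <- vmt_symbol_id(cats, exemplars)
    ord <- sample.int(7)
    board <- tibble(
      row = as.integer(cells[, 1]),
      col = as.integer(cells[, 2]),
      symbol = symbols[ord]
    )
    structure(list(pattern_id = pattern_id, board = board),
              class = "vmt_stimulus")
  })
}

#' @export
print.vmt_stimulus <- function(x, ...) {
  cat("<vmt_stimulus> pattern", x$pattern_id, "\n")
  print(x$board)
  invisible(x)
}

cell_key <- function(row, col) paste(row, col, sep = ",")

validate_vmt_response <- function(response) {
  response <- as_tibble(response)
  required <- c("row", "col", "symbol")
  if (!all(required %in% names(response))) {
    abort("A VMT response needs columns row, col, symbol.",
          class = "c3b_invalid_response")
  }
  if (anyDuplicated(response$symbol)) {
    abort(paste0("Invalid response: symbol(s) placed more than once: ",
                 paste(unique(response$symbol[duplicated(response$symbol)]),
                       collapse = ", ")),
          class = "c3b_invalid_response")
  }
  if (anyDuplicated(cell_key(response$row, response$col))) {
    abort("Invalid response: two symbols placed on the same cell.",
          class = "c3b_invalid_response")
  }
  off <- response$row < 1 | response$row > 4 | response$col < 1 | response$col > 6
  if (any(off)) {
    abort("Invalid response: placement outside the 4x6 board.",
          class = "c3b_invalid_response")
  }
  if (nrow(response) > 7) {
    abort("Invalid response: more than 7 placements.",
          class = "c3b_invalid_response")
  }
  response
}

#' Score one VMT trial
#'
#' For each of the 7 target cells of the stimulus: 2 points if the response
#' placed the correct symbol there, 1 point if it placed some other symbol
#' there, 0 if the cell is empty. Placements on non-target cells earn
#' nothing. The trial score is therefore an integer in 0-14.
#'
#' @param stimulus A [generate_vmt_stimulus()] object.
#' @param response A data frame of placements with columns `row`, `col`,
#'   `symbol` (at most 7 rows; each symbol and each cell used at most once).
#' @return Integer trial score in `0:14`.
#' @export
score_vmt_trial <- function(stimulus, response) {
  stopifnot(inherits(stimulus, "vmt_stimulus"))
  response <- validate_vmt_response(response)
  target <- stats::setNames(stimulus$board$symbol,
                            cell_key(stimulus$board$row, stimulus$board$col))
  placed <- stats::setNames(response$symbol,
                            cell_key(response$row, response$col))
  score <- 0L
  for (cell in names(target)) {
    if (!cell %in% names(placed)) next
    score <- score + if (identical(placed[[cell]], target[[cell]])) 2L else 1L
  }
  score
}

#' Score a VMT session of up to 5 learning trials
#'
#' Trials are scored in order. Once two consecutive trials score a perfect
#' 14, the test is discontinued and every remaining trial is allotted 14
#' without being scored. The session total is the sum over the 5 trials
#' (maximum 70).
#'
#' @param stimuli A single `vmt_stimulus` (the display is identical across
#'   the learning trials of one session) or a list of one per response.
#' @param responses List of trial responses (see [score_vmt_trial()]), 1-5
#'   entries in trial order. Fewer than 5 responses are accepted only when
#'   the discontinue rule has been triggered by the responses provided.
#' @return An object of class `vmt_session`: list with `trial_scores`
#'   (integer, length 5), `discontinued_after` (trial index or `NA`) and
#'   `total`.
#' @export
score_vmt_session <- function(stimuli, responses) {
  if (inherits(stimuli, "vmt_stimulus")) {
    stimuli <- rep(list(stimuli), length(responses))
  }
  if (length(responses) > 5) {
    abort("A VMT session has at most 5 trials.", class = "c3b_invalid_response")
  }
  if (length(responses) < 1) {
    abort("At least one trial response is required.", class = "c3b_invalid_response")
  }
  if (length(stimuli) < length(responses)) {
    abort("Need one stimulus per response (or a single shared stimulus).")
  }
  trial_scores <- integer(5)
  discontinued_after <- NA_integer_
  for (i in seq_len(5)) {
    if (!is.na(discontinued_after)) {
      trial_scores[i] <- 14L
      next
    }
    if (i > length(responses)) {
      abort(paste0("Session incomplete: only ", length(responses),
                   " responses and the discontinue rule was not triggered."),
            class = "c3b_invalid_response")
    }
    trial_scores[i] <- score_vmt_trial(stimuli[[i]], responses[[i]])
    if (i >= 2 && trial_scores[i] == 14L && trial_scores[i - 1L] == 14L && i < 5) {
      discontinued_after <- i
    }
  }
  structure(
    list(trial_scores = trial_scores,
         discontinued_after = discontinued_after,
         total = sum(trial_scores)),
    class = "vmt_session"
  )
}

#' @export
print.vmt_session <- function(x, ...) {
  cat("<vmt_session> trials:", paste(x$trial_scores, collapse = " "),
      "| total:", x$total)
  if (!is.na(x$discontinued_after)) {
    cat(" (discontinued after trial", paste0(x$discontinued_after, ")"))
  }
  cat("\n")
  invisible(x)
}

#' A response reproducing the stimulus exactly (for testing and simulation)
#'
#' @param stimulus A `vmt_stimulus`.
#' @return A placement tibble scoring the maximum 14.
#' @export
perfect_vmt_response <- function(stimulus) {
  stopifnot(inherits(stimulus, "vmt_stimulus"))
  stimulus$board
}
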