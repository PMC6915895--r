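#' Selection-bias guessing rules
#'
#' @description
#' Three guessing rules an observer with knowledge of the pre-allocation
#' state (but not the allocator's random stream) might use to predict the
#' next assignment:
#'
#' * `guess_rule1()` guesses the full cell (1 of 16): a uniform choice among
#'   the cells tied at the minimum sample size.
#' * `guess_rule2()` guesses the level of factor 1 (1 of 2): the level with
#'   the smaller combined cell sizes; a tie yields a uniform random level.
#' * `guess_rule3()` also guesses the factor-1 level, awarding each level a
#'   point for the strictly smaller total sample size and a point for the
#'   strictly smaller number of Black-positive participants; the level with
#'   more points is guessed and ties (0-0, 1-1) are resolved at random.
#'
#' "Smaller" is strict throughout: equality yields no point and a random
#' guess.
#'
#' @param state Pre-allocation [new_allocation_state()].
#' @param design The [factorial_design()] (defaults to the state's).
#' @param schema The [covariate_schema()]; must contain `Black` for rule 3.
#' @return `guess_rule1()`: a 0-based cell index; rules 2-3: a binary
#'   factor-1 level.
#' @name guess_rules
NULL

#' @rdname guess_rules
#' @export
guess_rule1 <- function(state) {
  mins <- which(state$cell_counts == min(state$cell_counts)) - 1L
  mins[sample.int(length(mins), 1L)]
}

# combined cell counts for each level of factor 1
factor1_level_totals <- function(state, design) {
  lev <- factor_level_of_cells(seq_len(design$n_cells) - 1L, 1L)
  c(sum(state$cell_counts[lev == 0L]), sum(state$cell_counts[lev == 1L]))
}

#' @rdname guess_rules
#' @export
guess_rule2 <- function(state, design = state$design) {
  totals <- factor1_level_totals(state, design)
  if (totals[1L] == totals[2L]) sample(0:1, 1L)
  else if (totals[1L] < totals[2L]) 0L else 1L
}

#' @rdname guess_rules
#' @export
guess_rule3 <- function(state, design = state$design, schema = state$schema) {
  if (!"Black" %in% schema$name)
    stop("rule 3 requires a 'Black' covariate in the schema", call. = FALSE)
  lev <- factor_level_of_cells(seq_len(design$n_cells) - 1L, 1L)
  totals <- factor1_level_totals(state, design)
  black <- state$cov_positive[, "Black"]
  black_totals <- c(sum(black[lev == 0L]), sum(black[lev == 1L]))
  points <- integer(2L)
  if (totals[1L] != totals[2L])
    points[which.min(totals)] <- points[which.min(totals)] + 1L
  if (black_totals[1L] != black_totals[2L])
    points[which.min(black_totals)] <- points[which.min(black_totals)] + 1L
  if (points[1L] == points[2L]) sample(0:1, 1L)
  else if (points[1L] > points[2L]) 0L else 1L
}

#' Score a guess against the realized allocation
#'
#' Rule 1 guesses are correct when the guessed cell equals the chosen cell;
#' rule 2-3 guesses are correct when the guessed level equals the factor-1
#' level of the chosen cell. Guesses must be made strictly before the
#' allocation's random draw.
#'
#' @param rule Guess rule number (1, 2 or 3).
#' @param guess The guessed cell (rule 1) or factor-1 level (rules 2-3).
#' @param decision The realized [allocation_decision()].
#' @param design The [factorial_design()].
#' @return Logical: was the guess correct?
#' @export
score_guess <- function(rule, guess, decision, design) {
  chosen <- decision$chosen_cell
  if (rule == 1L) {
    guess == chosen
  } else {
    guess == factor_level_of_cells(chosen, 1L)
  }
}
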