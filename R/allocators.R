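#' Allocation procedures
#'
#' @description
#' Five sequential allocation procedures for two-level factorial designs.
#' Each takes the current [new_allocation_state()] (and, where needed, the
#' next participant) and returns an [allocation_decision()] without mutating
#' the state; the caller commits the decision with [commit_decision()].
#'
#' * `allocate_simple()` — simple randomization: every cell is always
#'   eligible and the choice is uniform.
#' * `allocate_mti()` — maximum tolerated imbalance: randomize freely while
#'   the cell-size range (max − min) stays at or below the limit; once the
#'   range *exceeds* the limit, the "big stick" restricts eligibility to the
#'   smallest cells (ties broken at random). The observed range therefore
#'   never exceeds limit + 1.
#' * `allocate_spb()` — stratified permuted blocks: within the participant's
#'   stratum, consume a randomly permuted block containing every cell equally
#'   often; a new block (size drawn uniformly from the configured sizes) is
#'   opened when none is in progress.
#' * `allocate_msb()` — minimal sufficient balance: randomize freely unless a
#'   covariate's across-cell imbalance test triggers, in which case votes
#'   steer the assignment toward cells that restore equivalence (see
#'   [msb_votes()]).
#' * `allocate_minimization()` — minimization by sum of ranges: assign to the
#'   cell minimizing the total range (max − min across cells) of the
#'   hypothetical post-assignment cell sizes and covariate tallies, with ties
#'   broken by simple random assignment.
#'
#' All random draws come from R's global RNG; seed it (or use the harness,
#' which derives one named seed per procedure per simulation) for
#' reproducibility.
#'
#' @param state An [new_allocation_state()].
#' @param participant List with `covariates` (named binary vector) and
#'   `stratum` (integer 1..3, used by `allocate_spb`).
#' @param config Procedure configuration: [mti_config()], [spb_config()] or
#'   [msb_config()].
#' @return An [allocation_decision()].
#' @name allocators
NULL

#' Maximum tolerated imbalance configuration
#' @param mti_limit Positive integer imbalance limit (the study compares
#'   limits 2 and 3).
#' @return An `mti_config` list.
#' @export
mti_config <- function(mti_limit = 2L) {
  mti_limit <- as.integer(mti_limit)
  if (is.na(mti_limit) || mti_limit < 1L)
    stop("`mti_limit` must be a positive integer", call. = FALSE)
  structure(list(mti_limit = mti_limit), class = "mti_config")
}

#' Minimal sufficient balance configuration
#' @param alpha_trigger Significance level of the per-covariate imbalance
#'   test that triggers vote-based steering (default 0.30).
#' @return An `msb_config` list.
#' @export
msb_config <- function(alpha_trigger = 0.30) {
  if (!is.numeric(alpha_trigger) || alpha_trigger <= 0 || alpha_trigger >= 1)
    stop("`alpha_trigger` must lie strictly in (0, 1)", call. = FALSE)
  structure(list(alpha_trigger = alpha_trigger), class = "msb_config")
}

#' Stratified permuted-block configuration
#' @param block_sizes Permitted block sizes; each must be a positive multiple
#'   of the number of cells (default `c(16, 32)`).
#' @param n_strata Number of strata (default 3).
#' @return An `spb_config` list.
#' @export
spb_config <- function(block_sizes = c(16L, 32L), n_strata = 3L) {
  block_sizes <- as.integer(block_sizes)
  if (!length(block_sizes) || anyNA(block_sizes) || any(block_sizes < 1L))
    stop("`block_sizes` must be positive integers", call. = FALSE)
  structure(list(block_sizes = block_sizes, n_strata = as.integer(n_strata)),
            class = "spb_config")
}

#' @rdname allocators
#' @export
allocate_simple <- function(state) {
  n <- state$design$n_cells
  eligible <- seq_len(n) - 1L
  allocation_decision(eligible, eligible[sample.int(n, 1L)], "sr")
}

#' @rdname allocators
#' @export
allocate_mti <- function(state, config = mti_config(2L)) {
  stopifnot(inherits(config, "mti_config"))
  counts <- state$cell_counts
  if (max(counts) - min(counts) > config$mti_limit) {
    eligible <- which(counts == min(counts)) - 1L
  } else {
    eligible <- seq_along(counts) - 1L
  }
  chosen <- eligible[sample.int(length(eligible), 1L)]
  allocation_decision(eligible, chosen, paste0("mti", config$mti_limit))
}

#' Open a permuted block for a stratum
#'
#' Draws a block size uniformly from the configured sizes and lays out a
#' uniformly random permutation of every cell repeated `block_size / n_cells`
#' times.
#'
#' @param stratum Stratum index the block belongs to.
#' @param config An [spb_config()].
#' @param n_cells Number of design cells (default 16).
#' @return A `block_state` list with `stratum`, `block_size` and
#'   `remaining_slots` (0-based cell indices in draw order).
#' @export
open_block <- function(stratum, config = spb_config(), n_cells = 16L) {
  stopifnot(inherits(config, "spb_config"))
  if (any(config$block_sizes %% n_cells != 0L))
    stop(sprintf("block sizes must be multiples of the number of cells (%d)",
                 n_cells), call. = FALSE)
  size <- config$block_sizes[sample.int(length(config$block_sizes), 1L)]
  slots <- rep(seq_len(n_cells) - 1L, size %/% n_cells)
  structure(
    list(stratum = as.integer(stratum), block_size = size,
         remaining_slots = slots[sample.int(length(slots))]),
    class = "block_state"
  )
}

#' @rdname allocators
#' @export
allocate_spb <- function(state, participant, config = spb_config()) {
  stopifnot(inherits(config, "spb_config"))
  s <- as.integer(participant$stratum)
  if (is.na(s) || s < 1L || s > length(state$blocks))
    stop("participant must carry a valid stratum", call. = FALSE)
  block <- state$blocks[[s]]
  if (is.null(block) || !length(block$remaining_slots))
    block <- open_block(s, config, state$design$n_cells)
  eligible <- unique(block$remaining_slots)
  chosen <- block$remaining_slots[[1L]]
  block$remaining_slots <- block$remaining_slots[-1L]
  allocation_decision(eligible, chosen, "spb",
                      block_after = block, stratum = s)
}

#' Compute minimal-sufficient-balance votes for the next participant
#'
#' Before each allocation, every covariate is tested for across-cell
#' imbalance with a Pearson chi-square test over the non-empty cells
#' ([chi_square_binary_across_cells()]). For each covariate whose test is
#' significant at `alpha_trigger`: if the next participant is positive on the
#' covariate, every cell tied at the lowest positive proportion gains a vote;
#' if negative, every cell tied at the highest proportion loses a vote.
#' Empty cells have undefined proportions and neither attract nor repel
#' votes. With fewer than two non-empty cells no test is performed.
#'
#' @inheritParams allocators
#' @return Integer vote vector, one entry per cell.
#' @export
msb_votes <- function(state, participant, config = msb_config()) {
  stopifnot(inherits(config, "msb_config"))
  n <- state$design$n_cells
  votes <- integer(n)
  counts <- state$cell_counts
  nonempty <- counts > 0L
  if (sum(nonempty) < 2L) return(votes)
  covs <- participant$covariates[colnames(state$cov_positive)]
  for (k in seq_len(ncol(state$cov_positive))) {
    test <- chi_square_binary_across_cells(state$cov_positive[, k], counts)
    if (!test$testable || test$p_value >= config$alpha_trigger) next
    prop <- state$cov_positive[nonempty, k] / counts[nonempty]
    idx <- which(nonempty)
    if (covs[[k]] == 1L) {
      target <- idx[prop == min(prop)]
      votes[target] <- votes[target] + 1L
    } else {
      target <- idx[prop == max(prop)]
      votes[target] <- votes[target] - 1L
    }
  }
  votes
}

#' @rdname allocators
#' @export
allocate_msb <- function(state, participant, config = msb_config()) {
  votes <- msb_votes(state, participant, config)
  eligible <- which(votes == max(votes)) - 1L
  chosen <- eligible[sample.int(length(eligible), 1L)]
  allocation_decision(eligible, chosen, "msb")
}

# range of v after incrementing each position in turn: vectorized over the
# candidate cell. Exploits that only one entry changes by +1.
range_after_increment <- function(v) {
  mx <- max(v)
  mn <- min(v)
  unique_min <- sum(v == mn) == 1L
  new_max <- mx + (v == mx)
  new_min <- mn + (unique_min & v == mn)
  new_max - new_min
}

# sum of ranges for every candidate cell at once; `covariates` is the next
# participant's named binary vector. `weights`: list(size=, covariates=).
sum_of_ranges_all <- function(state, covariates, weights = NULL) {
  cp <- state$cov_positive
  covs <- as.integer(covariates[colnames(cp)])
  K <- ncol(cp)
  w_size <- if (is.null(weights)) 1 else weights$size
  w_cov <- if (is.null(weights)) rep(1, K) else rep_len(weights$covariates, K)
  total <- w_size * range_after_increment(state$cell_counts)
  for (k in seq_len(K)) {
    if (covs[k] == 1L) {
      total <- total + w_cov[k] * range_after_increment(cp[, k])
    } else if (state$n_allocated > 0L) {
      total <- total + w_cov[k] * (max(cp[, k]) - min(cp[, k]))
    }
  }
  total
}

#' Sum of ranges for a hypothetical assignment
#'
#' The minimization criterion: if the next participant were assigned to
#' `candidate`, the cell sizes and each covariate's positive tallies would
#' each change in that cell; the score is the sum, over sample size and every
#' covariate, of the range (max − min across cells) of the hypothetical
#' post-assignment tallies. The state is not modified.
#'
#' @inheritParams allocators
#' @param candidate 0-based candidate cell index.
#' @param weights Optional list with `size` (scalar weight on the cell-size
#'   range) and `covariates` (per-covariate weights); all default to 1.
#' @return The (weighted) sum of ranges, a non-negative number.
#' @export
sum_of_ranges <- function(state, participant, candidate, weights = NULL) {
  candidate <- as.integer(candidate)
  if (candidate < 0L || candidate >= state$design$n_cells)
    stop("invalid candidate cell", call. = FALSE)
  sum_of_ranges_all(state, participant$covariates, weights)[candidate + 1L]
}

#' @rdname allocators
#' @param weights Optional minimization weights, see [sum_of_ranges()].
#' @export
allocate_minimization <- function(state, participant, weights = NULL) {
  scores <- sum_of_ranges_all(state, participant$covariates, weights)
  eligible <- which(scores == min(scores)) - 1L
  chosen <- eligible[sample.int(length(eligible), 1L)]
  allocation_decision(eligible, chosen, "min")
}
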