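#' Initialize the running allocation state
#'
#' The state tracks, per cell: the number of participants allocated
#' (`cell_counts`) and the number positive on each covariate
#' (`cov_positive`), plus per-stratum permuted-block state (used only by the
#' stratified permuted-block procedure) and the total number allocated.
#'
#' Allocators never mutate the state; every change goes through a single
#' explicit [commit_decision()].
#'
#' @param design A [factorial_design()].
#' @param schema A [covariate_schema()].
#' @param n_strata Number of strata tracked for blocked allocation (default 3).
#' @return An object of class `allocation_state`.
#' @export
new_allocation_state <- function(design, schema, n_strata = 3L) {
  stopifnot(inherits(design, "factorial_design"))
  n <- design$n_cells
  cov_positive <- matrix(0L, nrow = n, ncol = nrow(schema),
                         dimnames = list(NULL, schema$name))
  structure(
    list(
      design = design,
      schema = schema,
      cell_counts = integer(n),
      cov_positive = cov_positive,
      blocks = vector("list", n_strata),
      n_allocated = 0L
    ),
    class = "allocation_state"
  )
}

#' @export
print.allocation_state <- function(x, ...) {
  cat(sprintf("<allocation_state> %d allocated across %d cells (range %d)\n",
              x$n_allocated, x$design$n_cells,
              if (x$n_allocated) max(x$cell_counts) - min(x$cell_counts) else 0L))
  invisible(x)
}

#' Construct an allocation decision
#'
#' One decision per allocation: the set of cells that were eligible, the cell
#' chosen among them, and whether the allocation was deterministic (exactly
#' one eligible cell). Procedures that consume permuted-block slots attach the
#' post-draw block state so that [commit_decision()] can install it.
#'
#' @param eligible_cells Non-empty integer vector of 0-based eligible cells.
#' @param chosen_cell 0-based chosen cell; must be eligible.
#' @param procedure Procedure identifier string.
#' @param block_after Optional updated block state (stratified blocks only).
#' @param stratum Optional stratum the block update applies to.
#' @return An object of class `allocation_decision` with fields
#'   `eligible_cells`, `chosen_cell`, `deterministic`, `procedure`.
#' @export
allocation_decision <- function(eligible_cells, chosen_cell, procedure,
                                block_after = NULL, stratum = NULL) {
  eligible_cells <- sort(unique(as.integer(eligible_cells)))
  chosen_cell <- as.integer(chosen_cell)
  if (!length(eligible_cells))
    stop("eligible cell set must be non-empty", call. = FALSE)
  if (!chosen_cell %in% eligible_cells)
    stop("chosen cell must be one of the eligible cells", call. = FALSE)
  structure(
    list(
      eligible_cells = eligible_cells,
      chosen_cell = chosen_cell,
      deterministic = length(eligible_cells) == 1L,
      procedure = procedure,
      block_after = block_after,
      stratum = if (is.null(stratum)) NULL else as.integer(stratum)
    ),
    class = "allocation_decision"
  )
}

#' Commit an allocation decision to the state
#'
#' Returns a new state with the participant added to the chosen cell: the
#' cell count is incremented, the cell's covariate-positive tallies are
#' incremented by the participant's covariate vector, and any permuted-block
#' update carried by the decision is installed.
#'
#' @param state An [new_allocation_state()] object.
#' @param decision An [allocation_decision()].
#' @param participant A list with elements `covariates` (named binary vector
#'   aligned to the schema) and, for blocked procedures, `stratum`.
#' @return The updated `allocation_state`.
#' @export
commit_decision <- function(state, decision, participant) {
  stopifnot(inherits(state, "allocation_state"),
            inherits(decision, "allocation_decision"))
  i <- decision$chosen_cell + 1L
  state$cell_counts[i] <- state$cell_counts[i] + 1L
  state$cov_positive[i, ] <- state$cov_positive[i, ] +
    as.integer(participant$covariates[colnames(state$cov_positive)])
  state$n_allocated <- state$n_allocated + 1L
  if (!is.null(decision$stratum))
    state$blocks[[decision$stratum]] <- decision$block_after
  state
}

# internal invariant check used by tests and validate-on-demand
validate_state <- function(state) {
  stopifnot(sum(state$cell_counts) == state$n_allocated,
            all(state$cov_positive >= 0L),
            all(state$cov_positive <= state$cell_counts))
  invisible(state)
}
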