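# shared fixtures built in code

default_design <- function() factorial_design(4L)

# construct an allocation state directly from given tallies
make_state <- function(counts, cov_positive = NULL,
                       schema = default_schema(),
                       design = factorial_design(log2(length(counts)))) {
  state <- new_allocation_state(design, schema)
  state$cell_counts <- as.integer(counts)
  state$n_allocated <- sum(counts)
  if (!is.null(cov_positive)) {
    cov_positive <- as.matrix(cov_positive)
    state$cov_positive[, seq_len(ncol(cov_positive))] <-
      as.integer(cov_positive)
  }
  state
}

# n random participants drawn from the default synthetic generator
random_participants <- function(n, schema = default_schema(), seed = 11) {
  set.seed(seed)
  cfg <- generator_config(n_source = n, schema = schema)
  cohort <- generate_source_population(cfg)
  cm <- cohort_matrix <- as.matrix(as.data.frame(cohort)[, schema$name])
  storage.mode(cm) <- "integer"
  lapply(seq_len(n), function(i)
    list(id = i, covariates = cm[i, ], stratum = cohort$stratum[i]))
}

# run a sequence of allocations with `alloc_fn(state, participant)`,
# returning the decision list and final state
run_sequence <- function(participants, alloc_fn, schema = default_schema(),
                         design = default_design()) {
  state <- new_allocation_state(design, schema)
  decisions <- vector("list", length(participants))
  for (i in seq_along(participants)) {
    d <- alloc_fn(state, participants[[i]])
    decisions[[i]] <- d
    state <- commit_decision(state, d, participants[[i]])
  }
  list(decisions = decisions, state = state)
}

# independent brute-force minimization oracle: rebuilds hypothetical tallies
# for every candidate cell from the raw allocation history
brute_force_min_eligible <- function(history_cells, history_cov, next_cov,
                                     n_cells) {
  scores <- numeric(n_cells)
  K <- ncol(history_cov)
  for (cand in seq_len(n_cells) - 1L) {
    cells <- c(history_cells, cand)
    covs <- rbind(history_cov, next_cov)
    counts <- tabulate(cells + 1L, n_cells)
    total <- max(counts) - min(counts)
    for (k in seq_len(K)) {
      per_cell <- vapply(seq_len(n_cells) - 1L,
                         function(cc) sum(covs[cells == cc, k]), numeric(1))
      total <- total + max(per_cell) - min(per_cell)
    }
    scores[cand + 1L] <- total
  }
  sort(which(scores == min(scores)) - 1L)
}
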