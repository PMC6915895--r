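test_that("simple randomization is uniform over all cells", {
  schema <- default_schema()
  state <- new_allocation_state(default_design(), schema)
  set.seed(1)
  d <- allocate_simple(state)
  expect_length(d$eligible_cells, 16L)
  expect_false(d$deterministic)
  expect_true(d$chosen_cell >= 0L && d$chosen_cell < 16L)
  # frequency of each cell over many draws within 4 SE of 1/16
  set.seed(2)
  draws <- replicate(10000, allocate_simple(state)$chosen_cell)
  freq <- tabulate(draws + 1L, 16L) / 10000
  se <- sqrt((1 / 16) * (15 / 16) / 10000)
  expect_true(all(abs(freq - 1 / 16) < 4 * se))
})

test_that("permuted blocks contain each cell equally often", {
  cfg16 <- spb_config(block_sizes = 16L)
  cfg32 <- spb_config(block_sizes = 32L)
  set.seed(4)
  b16 <- open_block(1L, cfg16)
  expect_equal(sort(b16$remaining_slots), 0:15)
  b32 <- open_block(2L, cfg32)
  expect_equal(sort(b32$remaining_slots), rep(0:15, each = 2L))
  expect_error(open_block(1L, spb_config(block_sizes = 20L)), "multiples")
  # block size drawn uniformly from {16, 32}
  set.seed(5)
  sizes <- replicate(1000, open_block(1L, spb_config())$block_size)
  frac16 <- mean(sizes == 16L)
  expect_lt(abs(frac16 - 0.5), 4 * sqrt(0.25 / 1000))
})

test_that("stratified permuted blocks balance each stratum at block boundaries", {
  schema <- default_schema()
  cfg <- spb_config(block_sizes = 16L)
  state <- new_allocation_state(default_design(), schema)
  p <- list(id = 1L,
            covariates = setNames(integer(nrow(schema)), schema$name),
            stratum = 1L)
  p$covariates["Hispanic"] <- 1L
  set.seed(6)
  first <- allocate_spb(state, p, cfg)
  expect_length(first$eligible_cells, 16L)
  for (i in 1:16) {
    d <- allocate_spb(state, p, cfg)
    if (i < 16) expect_length(d$eligible_cells, 17L - i)
    state <- commit_decision(state, d, p)
  }
  # a completed block of 16 puts exactly one participant in every cell
  expect_equal(state$cell_counts, rep(1L, 16L))
  # with one slot left the allocation is deterministic
  state2 <- new_allocation_state(default_design(), schema)
  for (i in 1:15)
    state2 <- commit_decision(state2, allocate_spb(state2, p, cfg), p)
  last <- allocate_spb(state2, p, cfg)
  expect_true(last$deterministic)
})

test_that("MTI randomizes until the range exceeds the limit, then forces argmin", {
  schema <- default_schema()
  cfg <- mti_config(2L)
  set.seed(7)
  d <- allocate_mti(make_state(rep(0L, 16L), schema = schema), cfg)
  expect_length(d$eligible_cells, 16L)
  d <- allocate_mti(make_state(c(3L, rep(0L, 15L)), schema = schema), cfg)
  expect_equal(d$eligible_cells, 1:15)
  d <- allocate_mti(make_state(c(3L, 1L, rep(0L, 14L)), schema = schema), cfg)
  expect_equal(d$eligible_cells, 2:15)
  # at the limit (not exceeding), randomization continues
  d <- allocate_mti(make_state(c(2L, rep(0L, 15L)), schema = schema), cfg)
  expect_length(d$eligible_cells, 16L)
})

test_that("MTI keeps the running cell-size range at or below limit + 1", {
  schema <- default_schema()
  participants <- random_participants(304, schema, seed = 8)
  for (L in c(2L, 3L)) {
    cfg <- mti_config(L)
    set.seed(100 + L)
    state <- new_allocation_state(default_design(), schema)
    for (p in participants) {
      d <- allocate_mti(state, cfg)
      state <- commit_decision(state, d, p)
      expect_lte(max(state$cell_counts) - min(state$cell_counts), L + 1L)
    }
  }
})

test_that("MSB votes follow the significant-covariate steering rules", {
  schema <- default_schema()
  cfg <- msb_config(0.30)
  base <- setNames(integer(nrow(schema)), schema$name)
  # balanced tallies: nothing significant, all votes zero
  counts <- rep(10L, 16L)
  cov <- matrix(5L, 16L, nrow(schema))
  state <- make_state(counts, cov, schema)
  p <- list(id = 1L, covariates = base, stratum = 3L)
  expect_equal(msb_votes(state, p, cfg), integer(16))
  # one covariate grossly imbalanced: positive participant -> +1 at the
  # unique lowest-proportion cell
  cov2 <- cov
  cov2[, 1L] <- c(0L, rep(8L, 15L))
  state2 <- make_state(counts, cov2, schema)
  p_pos <- p; p_pos$covariates[1L] <- 1L
  v <- msb_votes(state2, p_pos, cfg)
  expect_equal(v[1L], 1L)
  expect_equal(v[-1L], integer(15))
  # negative participant -> -1 at every cell tied at the highest proportion
  p_neg <- p
  v <- msb_votes(state2, p_neg, cfg)
  expect_equal(v[1L], 0L)
  expect_equal(v[-1L], rep(-1L, 15L))
  # two significant covariates pointing at the same cell accumulate
  cov3 <- cov2
  cov3[, 2L] <- c(0L, rep(8L, 15L))
  state3 <- make_state(counts, cov3, schema)
  p_pos2 <- p; p_pos2$covariates[1:2] <- 1L
  v <- msb_votes(state3, p_pos2, cfg)
  expect_equal(v[1L], 2L)
  # fewer than two non-empty cells: no tests, no votes
  state4 <- make_state(c(5L, rep(0L, 15L)), schema = schema)
  expect_equal(msb_votes(state4, p_pos, cfg), integer(16))
})

test_that("MSB assignment is argmax of votes and degenerates to simple randomization", {
  schema <- default_schema()
  base <- setNames(integer(nrow(schema)), schema$name)
  p <- list(id = 1L, covariates = base, stratum = 3L)
  set.seed(12)
  d <- allocate_msb(new_allocation_state(default_design(), schema), p)
  expect_length(d$eligible_cells, 16L)
  # with a vanishing trigger level no test can fire: always fully random
  participants <- random_participants(120, schema, seed = 13)
  cfg0 <- msb_config(1e-12)
  set.seed(14)
  res <- run_sequence(participants,
                      function(state, p) allocate_msb(state, p, cfg0), schema)
  expect_true(all(vapply(res$decisions,
                         function(d) length(d$eligible_cells), integer(1)) == 16L))
})

test_that("sum of ranges matches hand-computed and brute-force values", {
  schema <- default_schema()
  base <- setNames(integer(nrow(schema)), schema$name)
  empty <- new_allocation_state(default_design(), schema)
  p0 <- list(id = 1L, covariates = base, stratum = 3L)
  # empty state, all-negative participant: size range 1, covariate ranges 0
  expect_equal(sum_of_ranges(empty, p0, 0L), 1)
  p2 <- p0; p2$covariates[c("Medicaid", "Sex")] <- 1L
  expect_equal(sum_of_ranges(empty, p2, 3L), 3)
  expect_error(sum_of_ranges(empty, p0, 16L), "candidate")
  # 4-cell toy design, brute-force enumerated expectations
  toy_schema <- covariate_schema("X", "MC", 0.5)
  toy <- make_state(c(1L, 1L, 0L, 0L), matrix(c(1L, 0L, 0L, 0L)), toy_schema)
  p_toy <- list(id = 1L, covariates = c(X = 1L), stratum = 3L)
  sums <- vapply(0:3, function(cand) sum_of_ranges(toy, p_toy, cand),
                 numeric(1))
  expect_equal(sums, c(4, 3, 2, 2))
  set.seed(15)
  d <- allocate_minimization(toy, p_toy)
  expect_equal(d$eligible_cells, c(2L, 3L))
})

test_that("minimization matches a brute-force recomputation along a run", {
  schema <- default_schema()
  participants <- random_participants(120, schema, seed = 16)
  state <- new_allocation_state(default_design(), schema)
  history_cells <- integer(0)
  history_cov <- matrix(integer(0), 0, nrow(schema))
  set.seed(17)
  for (p in participants) {
    d <- allocate_minimization(state, p)
    oracle <- brute_force_min_eligible(history_cells, history_cov,
                                       p$covariates, 16L)
    expect_equal(d$eligible_cells, oracle)
    state <- commit_decision(state, d, p)
    history_cells <- c(history_cells, d$chosen_cell)
    history_cov <- rbind(history_cov, p$covariates)
  }
})

test_that("minimization with no covariate signal reduces to assign-to-smallest", {
  # a schema whose single covariate never varies carries no information
  schema <- covariate_schema("X", "MC", 0.5)
  p <- list(id = 1L, covariates = c(X = 0L), stratum = 3L)
  set.seed(18)
  state <- new_allocation_state(default_design(), schema)
  for (i in 1:200) {
    d <- allocate_minimization(state, p)
    state <- commit_decision(state, d, p)
    expect_lte(max(state$cell_counts) - min(state$cell_counts), 1L)
  }
  # unique argmin is deterministic
  st <- make_state(c(rep(1L, 15L), 0L), schema = schema)
  d <- allocate_minimization(st, p)
  expect_true(d$deterministic)
  expect_equal(d$chosen_cell, 15L)
  # empty state: every candidate ties
  d0 <- allocate_minimization(new_allocation_state(default_design(), schema), p)
  expect_length(d0$eligible_cells, 16L)
})

test_that("allocators never mutate the state they are given", {
  schema <- default_schema()
  participants <- random_participants(40, schema, seed = 19)
  set.seed(20)
  state <- new_allocation_state(default_design(), schema)
  for (p in participants[1:30])
    state <- commit_decision(state, allocate_simple(state), p)
  snapshot <- state
  p <- participants[[31]]
  set.seed(21)
  allocate_simple(state)
  allocate_mti(state, mti_config(2L))
  allocate_msb(state, p)
  allocate_minimization(state, p)
  allocate_spb(state, p, spb_config())
  expect_identical(state, snapshot)
})
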