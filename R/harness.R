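#' Configure a simulation study
#'
#' A study run draws one synthetic source population, then for each of
#' `n_sims` simulated trials draws a bootstrap cohort and allocates it with
#' every requested procedure — all procedures within a simulation consume
#' the identical cohort, so procedures are compared on shared draws. Each
#' procedure gets its own derived random stream per simulation
#' ([derive_seed()]), so adding or removing a procedure never changes
#' another's results under the same master seed.
#'
#' Procedure identifiers: `"sr"` (simple randomization), `"spb"` (stratified
#' permuted blocks), `"mti2"` / `"mti3"` (maximum tolerated imbalance at
#' limits 2 and 3; arbitrary limits via `"mti:<L>"`), `"msb"` (minimal
#' sufficient balance), `"min"` (minimization).
#'
#' @param n_sims Number of simulated trials (default 250).
#' @param procedures Character vector of procedure identifiers.
#' @param generator A [generator_config()] for the synthetic source
#'   population and bootstrap sample size.
#' @param design A [factorial_design()] (default 4 factors, 16 cells).
#' @param msb_alpha MSB imbalance-test trigger level (default 0.30).
#' @param equivalence_alpha End-of-trial significance level for the
#'   equivalence summary (default 0.05).
#' @param weights Optional minimization weights, see [sum_of_ranges()].
#' @param block_sizes Permitted permuted-block sizes (default `c(16, 32)`).
#' @param seed Master integer seed.
#' @param full_logs Keep per-allocation decision and guess logs (roughly
#'   `n_sims * n_sample` rows per procedure; default `FALSE`).
#' @return A `run_config` list.
#' @export
run_config <- function(n_sims = 250L,
                       procedures = c("sr", "spb", "mti2", "mti3", "msb", "min"),
                       generator = generator_config(),
                       design = factorial_design(4L),
                       msb_alpha = 0.30,
                       equivalence_alpha = 0.05,
                       weights = NULL,
                       block_sizes = c(16L, 32L),
                       seed = 1L,
                       full_logs = FALSE) {
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L)
    stop("`n_sims` must be at least 1", call. = FALSE)
  for (p in procedures) parse_procedure(p)  # validates identifiers
  structure(
    list(n_sims = n_sims, procedures = procedures, generator = generator,
         design = design, msb_alpha = msb_alpha,
         equivalence_alpha = equivalence_alpha, weights = weights,
         block_sizes = as.integer(block_sizes), seed = as.integer(seed),
         full_logs = isTRUE(full_logs)),
    class = "run_config"
  )
}

# "mti:<L>" -> list(kind, limit); known ids otherwise
parse_procedure <- function(id) {
  if (id %in% c("sr", "spb", "msb", "min"))
    return(list(kind = id, limit = NULL))
  if (grepl("^mti[0-9]+$", id))
    return(list(kind = "mti", limit = as.integer(sub("^mti", "", id))))
  if (grepl("^mti:[0-9]+$", id))
    return(list(kind = "mti", limit = as.integer(sub("^mti:", "", id))))
  stop(sprintf("unknown procedure identifier '%s'", id), call. = FALSE)
}

# closure implementing one procedure against (state, participant)
make_allocator <- function(id, config) {
  spec <- parse_procedure(id)
  switch(spec$kind,
    sr = function(state, participant) allocate_simple(state),
    mti = {
      cfg <- mti_config(spec$limit)
      function(state, participant) allocate_mti(state, cfg)
    },
    spb = {
      cfg <- spb_config(config$block_sizes)
      function(state, participant) allocate_spb(state, participant, cfg)
    },
    msb = {
      cfg <- msb_config(config$msb_alpha)
      function(state, participant) allocate_msb(state, participant, cfg)
    },
    min = function(state, participant)
      allocate_minimization(state, participant, config$weights)
  )
}

#' Run one simulated trial under one procedure
#'
#' Allocates the cohort strictly in arrival order. Before every allocation
#' the three guessing rules are evaluated on the pre-allocation state; the
#' decision is then drawn, scored against the guesses, and committed. At the
#' end the balance and equivalence summaries are computed on the completed
#' state.
#'
#' @param cohort A [new_cohort()] in arrival order.
#' @param procedure Procedure identifier (see [run_config()]).
#' @param config A [run_config()].
#' @return A list with `log` (per-allocation data frame: `order`,
#'   `participant_id`, `eligible_count`, `chosen_cell`, `deterministic`,
#'   `guess1`-`guess3`, `correct1`-`correct3`), `balance`, `equivalence`, and
#'   the final `state`.
#' @export
run_simulation <- function(cohort, procedure, config = run_config()) {
  stopifnot(inherits(cohort, "cohort"))
  design <- config$design
  schema <- attr(cohort, "schema")
  alloc <- make_allocator(procedure, config)
  state <- new_allocation_state(design, schema)
  n <- nrow(cohort)
  cm <- cohort_matrix(cohort)
  strata <- cohort$stratum
  ids <- cohort$id
  eligible_count <- integer(n)
  chosen_cell <- integer(n)
  guesses <- matrix(NA_integer_, n, 3L)
  correct <- matrix(NA, n, 3L)
  for (i in seq_len(n)) {
    participant <- list(id = ids[i], covariates = cm[i, ], stratum = strata[i])
    g1 <- guess_rule1(state)
    g2 <- guess_rule2(state, design)
    g3 <- guess_rule3(state, design, schema)
    decision <- alloc(state, participant)
    eligible_count[i] <- length(decision$eligible_cells)
    chosen_cell[i] <- decision$chosen_cell
    guesses[i, ] <- c(g1, g2, g3)
    correct[i, ] <- c(score_guess(1L, g1, decision, design),
                      score_guess(2L, g2, decision, design),
                      score_guess(3L, g3, decision, design))
    state <- commit_decision(state, decision, participant)
  }
  list(
    log = data.frame(order = seq_len(n), participant_id = ids,
                     eligible_count = eligible_count,
                     chosen_cell = chosen_cell,
                     deterministic = eligible_count == 1L,
                     guess1 = guesses[, 1L], guess2 = guesses[, 2L],
                     guess3 = guesses[, 3L],
                     correct1 = correct[, 1L], correct2 = correct[, 2L],
                     correct3 = correct[, 3L]),
    balance = balance_summary(state$cell_counts),
    equivalence = equivalence_summary(state, schema,
                                      config$equivalence_alpha),
    state = state
  )
}

#' Run the full Monte Carlo study
#'
#' Generates one source population (or accepts one), then runs `n_sims`
#' bootstrap trials under every configured procedure and aggregates:
#'
#' * `table2` — mean minimum / maximum / range of the 16 cell sizes, per
#'   procedure, averaged over simulations;
#' * `table3` — distribution (percent of simulations) of the number of SC
#'   and MC covariates significantly different across cells at trial end,
#'   plus the average percent significant;
#' * `table4` — percent of allocations at each eligible-cell count 1..16,
#'   pooled over all allocations, plus the average eligible-cell count
#'   (1 = deterministic, 16 = completely random);
#' * `table5` — percent of correct guesses under rules 1-3, pooled over all
#'   allocations.
#'
#' @param config A [run_config()].
#' @param source Optional [new_cohort()] to use as the fixed source
#'   population instead of generating one.
#' @return An `allocation_report` list with the four tables, the per-sim
#'   metrics data frame, pooled guess/eligibility tallies, and run metadata.
#' @export
run_study <- function(config = run_config(), source = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(source)) {
    set.seed(derive_seed(config$seed, "source"))
    source <- generate_source_population(config$generator)
  }
  stopifnot(inherits(source, "cohort"))
  procs <- config$procedures
  n_cells <- config$design$n_cells
  n_mc <- sum(attr(source, "schema")$role == "MC")
  n_sc <- sum(attr(source, "schema")$role == "SC")

  per_sim <- vector("list", config$n_sims * length(procs))
  elig_tab <- matrix(0, length(procs), n_cells,
                     dimnames = list(procs, NULL))
  correct_tab <- matrix(0, length(procs), 3L, dimnames = list(procs, NULL))
  n_alloc <- setNames(numeric(length(procs)), procs)
  logs <- if (config$full_logs) list() else NULL

  row <- 0L
  for (sim in seq_len(config$n_sims)) {
    set.seed(derive_seed(config$seed, "bootstrap", sim))
    cohort <- bootstrap_sample(source, config$generator$n_sample)
    for (p in procs) {
      set.seed(derive_seed(config$seed, "proc", p, sim))
      res <- run_simulation(cohort, p, config)
      row <- row + 1L
      per_sim[[row]] <- data.frame(
        sim = sim, procedure = p,
        min_cell = res$balance$min_cell, max_cell = res$balance$max_cell,
        range = res$balance$range,
        n_sc_sig = res$equivalence$n_sc_significant,
        n_mc_sig = res$equivalence$n_mc_significant,
        stringsAsFactors = FALSE)
      elig_tab[p, ] <- elig_tab[p, ] +
        tabulate(res$log$eligible_count, n_cells)
      correct_tab[p, ] <- correct_tab[p, ] +
        c(sum(res$log$correct1), sum(res$log$correct2), sum(res$log$correct3))
      n_alloc[p] <- n_alloc[p] + nrow(res$log)
      if (config$full_logs)
        logs[[length(logs) + 1L]] <- cbind(sim = sim, procedure = p,
                                           res$log)
    }
  }
  per_sim <- do.call(rbind, per_sim)

  table2 <- do.call(rbind, lapply(procs, function(p) {
    d <- per_sim[per_sim$procedure == p, ]
    data.frame(procedure = p, min = mean(d$min_cell), max = mean(d$max_cell),
               range = mean(d$range), stringsAsFactors = FALSE)
  }))

  table3 <- do.call(rbind, lapply(procs, function(p) {
    d <- per_sim[per_sim$procedure == p, ]
    sc_dist <- 100 * tabulate(d$n_sc_sig + 1L, n_sc + 1L) / nrow(d)
    mc_dist <- 100 * tabulate(d$n_mc_sig + 1L, n_mc + 1L) / nrow(d)
    out <- data.frame(procedure = p, stringsAsFactors = FALSE)
    for (j in 0:n_sc) out[[paste0("sc_", j)]] <- sc_dist[j + 1L]
    out$pct_sc <- 100 * mean(d$n_sc_sig) / n_sc
    for (j in 0:n_mc) out[[paste0("mc_", j)]] <- mc_dist[j + 1L]
    out$pct_mc <- 100 * mean(d$n_mc_sig) / n_mc
    out
  }))

  table4 <- do.call(rbind, lapply(procs, function(p) {
    frac <- 100 * elig_tab[p, ] / n_alloc[p]
    out <- data.frame(procedure = p, stringsAsFactors = FALSE)
    for (j in seq_len(n_cells)) out[[paste0("cells_", j)]] <- frac[j]
    out$ave_cells <- sum(seq_len(n_cells) * elig_tab[p, ]) / n_alloc[p]
    out
  }))

  table5 <- do.call(rbind, lapply(procs, function(p) {
    data.frame(procedure = p,
               guess1 = 100 * correct_tab[p, 1L] / n_alloc[p],
               guess2 = 100 * correct_tab[p, 2L] / n_alloc[p],
               guess3 = 100 * correct_tab[p, 3L] / n_alloc[p],
               stringsAsFactors = FALSE)
  }))

  structure(
    list(table2 = table2, table3 = table3, table4 = table4, table5 = table5,
         per_sim = per_sim,
         logs = if (config$full_logs) do.call(rbind, logs) else NULL,
         n_sims = config$n_sims, n_sample = config$generator$n_sample,
         procedures = procs, seed = config$seed),
    class = "allocation_report"
  )
}

#' @export
print.allocation_report <- function(x, ...) {
  cat(sprintf("<allocation_report> %d simulations x %d participants, procedures: %s\n\n",
              x$n_sims, x$n_sample, paste(x$procedures, collapse = ", ")))
  cat("Cell-size balance (mean over simulations):\n")
  print(transform(x$table2, min = round(min, 1), max = round(max, 1),
                  range = round(range, 1)), row.names = FALSE)
  cat("\nUnpredictability (pooled over allocations):\n")
  tab <- data.frame(procedure = x$table4$procedure,
                    pct_deterministic = round(x$table4$cells_1, 1),
                    pct_fully_random = round(x$table4[[paste0("cells_", ncol(x$table4) - 2L)]], 1),
                    ave_cells = round(x$table4$ave_cells, 1),
                    guess1_pct = round(x$table5$guess1, 1),
                    guess2_pct = round(x$table5$guess2, 1),
                    guess3_pct = round(x$table5$guess3, 1))
  print(tab, row.names = FALSE)
  cat("\nCovariate equivalence (avg % significant at trial end):\n")
  print(data.frame(procedure = x$table3$procedure,
                   pct_sc = round(x$table3$pct_sc, 1),
                   pct_mc = round(x$table3$pct_mc, 1)), row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `table2.csv` through `table5.csv` (percentages rounded to one
#' decimal), a full-precision machine-readable `report.json`, and a
#' `config_echo.json` with the run metadata. Content is deterministic given
#' the report.
#'
#' @param report An `allocation_report` from [run_study()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "allocation_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  round_df <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 1)
    df
  }
  # largest-remainder rounding keeps each distribution row summing to 100.0
  round_to_sum <- function(x, target = 100, digits = 1L) {
    scale <- 10^digits
    lo <- floor(x * scale)
    short <- round(target * scale - sum(lo))
    bump <- utils::head(order(x * scale - lo, decreasing = TRUE), short)
    lo[bump] <- lo[bump] + 1L
    lo / scale
  }
  tables <- report[c("table2", "table3", "table4", "table5")]
  dist_cols <- grep("^cells_", names(tables$table4))
  for (i in seq_len(nrow(tables$table4)))
    tables$table4[i, dist_cols] <-
      round_to_sum(as.numeric(tables$table4[i, dist_cols]))
  for (nm in names(tables))
    utils::write.csv(round_df(tables[[nm]]),
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(tables = report[c("table2", "table3", "table4", "table5")],
         per_sim = report$per_sim,
         meta = list(n_sims = report$n_sims, n_sample = report$n_sample,
                     procedures = report$procedures, seed = report$seed)),
    file.path(out_dir, "report.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(n_sims = report$n_sims, n_sample = report$n_sample,
         procedures = report$procedures, seed = report$seed),
    file.path(out_dir, "config_echo.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
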