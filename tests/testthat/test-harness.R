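small_cfg <- function(...) {
  run_config(n_sims = 3L, seed = 61, ...)
}

test_that("run_simulation logs one decision per participant in arrival order", {
  set.seed(62)
  cohort <- bootstrap_sample(
    generate_source_population(generator_config()), 304L)
  cfg <- small_cfg(procedures = "sr")
  set.seed(63)
  res <- run_simulation(cohort, "sr", cfg)
  expect_equal(nrow(res$log), 304L)
  expect_equal(res$log$order, 1:304)
  expect_equal(res$log$participant_id, cohort$id)
  # simple randomization: every allocation is fully random
  expect_true(all(res$log$eligible_count == 16L))
  expect_false(any(res$log$deterministic))
  expect_equal(sum(res$state$cell_counts), 304L)
  expect_error(run_simulation(cohort, "bogus", cfg), "unknown procedure")
})

test_that("MTI runs respect the range bound along the whole trial", {
  set.seed(64)
  cohort <- bootstrap_sample(
    generate_source_population(generator_config()), 304L)
  set.seed(65)
  res <- run_simulation(cohort, "mti2", small_cfg())
  counts <- integer(16)
  for (cell in res$log$chosen_cell) {
    counts[cell + 1L] <- counts[cell + 1L] + 1L
    expect_lte(max(counts) - min(counts), 3L)
  }
})

test_that("the study shares bootstrap draws and isolates procedure streams", {
  cfg <- run_config(n_sims = 2L, procedures = c("sr", "min"), seed = 66,
                    full_logs = TRUE)
  rep <- run_study(cfg)
  # shared-draw design: identical participant sequence across procedures
  for (s in 1:2) {
    ids <- lapply(c("sr", "min"), function(p)
      rep$logs$participant_id[rep$logs$sim == s & rep$logs$procedure == p])
    expect_identical(ids[[1L]], ids[[2L]])
  }
  # dropping a procedure leaves the other's results untouched
  rep_min_only <- run_study(run_config(n_sims = 2L, procedures = "min",
                                       seed = 66))
  expect_equal(rep_min_only$per_sim,
               rep$per_sim[rep$per_sim$procedure == "min", ],
               ignore_attr = TRUE)
})

test_that("reports are structurally sound and reproducible on disk", {
  cfg <- run_config(n_sims = 2L, procedures = c("sr", "mti2"), seed = 67)
  rep <- run_study(cfg)
  expect_equal(nrow(rep$table2), 2L)
  cells_cols <- paste0("cells_", 1:16)
  for (i in 1:2)
    expect_equal(sum(unlist(rep$table4[i, cells_cols])), 100)
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  write_report(rep, out1)
  expect_true(all(file.exists(file.path(
    out1, c("table2.csv", "table3.csv", "table4.csv", "table5.csv",
            "report.json", "config_echo.json")))))
  t4 <- utils::read.csv(file.path(out1, "table4.csv"))
  expect_true(all(abs(rowSums(t4[, cells_cols]) - 100) <= 0.1))
  # same seed, fresh run: byte-identical report.json
  write_report(run_study(cfg), out2)
  expect_identical(readBin(file.path(out1, "report.json"), "raw", 10^7),
                   readBin(file.path(out2, "report.json"), "raw", 10^7))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("simple-randomization balance matches the multinomial expectation", {
  # independent oracle: the final cell counts under simple randomization are
  # multinomial(304, 1/16), so the expected range is a pure sampling quantity
  set.seed(68)
  oracle <- replicate(400, {
    x <- stats::rmultinom(1L, 304L, rep(1 / 16, 16L))
    max(x) - min(x)
  })
  cfg <- run_config(n_sims = 40L, procedures = "sr", seed = 69)
  rep <- run_study(cfg)
  se <- sqrt(stats::var(oracle) / 400 + stats::var(
    rep$per_sim$range) / 40)
  expect_lt(abs(rep$table2$range - mean(oracle)), 4 * se)
})

test_that("run configurations round-trip through JSON config files", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(sims = 5L, seed = 99L, procedures = c("sr", "mti:4"),
         generator = list(n_source = 100L, n_sample = 64L,
                          ethnicity_probs = c(0.5, 0.25, 0.25)),
         alphas = list(msb_trigger = 0.2, equivalence = 0.01)),
    path, auto_unbox = TRUE)
  cfg <- read_run_config(path)
  expect_equal(cfg$n_sims, 5L)
  expect_equal(cfg$procedures, c("sr", "mti:4"))
  expect_equal(cfg$generator$n_source, 100L)
  expect_equal(cfg$msb_alpha, 0.2)
  expect_equal(cfg$equivalence_alpha, 0.01)
  expect_equal(allocsim:::parse_procedure("mti:4")$limit, 4L)
  unlink(path)
})
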