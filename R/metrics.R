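#' Pearson chi-square test of a binary covariate across cells
#'
#' Tests homogeneity of a binary covariate's positive proportion across the
#' design cells using the Pearson statistic on the 2 x K contingency table
#' restricted to non-empty cells (K = number of non-empty cells), with K - 1
#' degrees of freedom and no continuity correction. The table is degenerate —
#' and the covariate not testable — when fewer than two cells are non-empty
#' or when the covariate is all-positive or all-negative overall; callers
#' treat "not testable" as non-significant.
#'
#' @param positives Integer vector of covariate-positive counts per cell.
#' @param totals Integer vector of cell sizes (same length).
#' @return A list with `testable` (logical), and when testable `statistic`,
#'   `df`, `p_value` (otherwise `NA`).
#' @examples
#' chi_square_binary_across_cells(c(20, 10), c(30, 30))$statistic  # 20/3
#' @export
chi_square_binary_across_cells <- function(positives, totals) {
  if (length(positives) != length(totals))
    stop("`positives` and `totals` must have the same length", call. = FALSE)
  if (any(positives < 0L) || any(positives > totals))
    stop("counts must satisfy 0 <= positives <= totals", call. = FALSE)
  keep <- totals > 0L
  K <- sum(keep)
  pos <- positives[keep]
  tot <- totals[keep]
  gp <- sum(pos)
  gt <- sum(tot)
  if (K < 2L || gp == 0L || gp == gt)
    return(list(testable = FALSE, statistic = NA_real_, df = NA_integer_,
                p_value = NA_real_))
  e_pos <- tot * gp / gt
  e_neg <- tot * (gt - gp) / gt
  stat <- sum((pos - e_pos)^2 / e_pos) + sum(((tot - pos) - e_neg)^2 / e_neg)
  df <- K - 1L
  list(testable = TRUE, statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Summarize cell-size balance
#'
#' @param cell_counts Integer vector of cell sizes.
#' @return A `balance_summary` list with `min_cell`, `max_cell` and `range`
#'   (max − min).
#' @export
balance_summary <- function(cell_counts) {
  structure(
    list(min_cell = min(cell_counts), max_cell = max(cell_counts),
         range = max(cell_counts) - min(cell_counts)),
    class = "balance_summary"
  )
}

#' End-of-trial covariate equivalence summary
#'
#' Applies [chi_square_binary_across_cells()] to every covariate at the end
#' of an allocation sequence, flags significance at `alpha`, and tallies the
#' stratification covariates (SC) and minimization covariates (MC)
#' separately. No multiple-testing adjustment is applied; covariates are
#' counted individually. Non-testable covariates count as non-significant.
#'
#' @param state Final [new_allocation_state()].
#' @param schema The [covariate_schema()] (defaults to the state's).
#' @param alpha End-of-trial significance threshold (default 0.05).
#' @return An `equivalence_summary` list: `significant` (named logical),
#'   `n_sc_significant`, `n_mc_significant`, `pct_sc`, `pct_mc`.
#' @export
equivalence_summary <- function(state, schema = state$schema, alpha = 0.05) {
  sig <- vapply(seq_len(nrow(schema)), function(k) {
    test <- chi_square_binary_across_cells(state$cov_positive[, schema$name[k]],
                                           state$cell_counts)
    isTRUE(test$testable) && test$p_value < alpha
  }, logical(1))
  names(sig) <- schema$name
  is_sc <- schema$role == "SC"
  n_sc <- sum(sig[is_sc])
  n_mc <- sum(sig[!is_sc])
  structure(
    list(significant = sig,
         n_sc_significant = n_sc,
         n_mc_significant = n_mc,
         pct_sc = if (any(is_sc)) 100 * n_sc / sum(is_sc) else NA_real_,
         pct_mc = if (any(!is_sc)) 100 * n_mc / sum(!is_sc) else NA_real_),
    class = "equivalence_summary"
  )
}
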