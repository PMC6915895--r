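#' Define a fully crossed two-level factorial design
#'
#' A design with `F` two-level factors yields `2^F` cells. Cells are indexed
#' 0-based internally; bit `i` of the cell index is the level of factor `i`,
#' so cell 0 is the all-low condition and cell `2^F - 1` the all-high one.
#' Reports label cells 1 through `2^F`.
#'
#' @param n_factors Number of two-level factors (default 4, giving 16 cells).
#' @param factor_names Optional character vector of factor names.
#' @return An object of class `factorial_design` with elements `factors`,
#'   `levels_per_factor` (always 2) and `n_cells`.
#' @examples
#' d <- factorial_design(4)
#' d$n_cells  # 16
#' @export
factorial_design <- function(n_factors = 4L, factor_names = NULL) {
  n_factors <- as.integer(n_factors)
  if (is.na(n_factors) || n_factors < 1L)
    stop("`n_factors` must be a positive integer", call. = FALSE)
  if (is.null(factor_names))
    factor_names <- paste0("F", seq_len(n_factors))
  if (length(factor_names) != n_factors)
    stop("`factor_names` must have length `n_factors`", call. = FALSE)
  structure(
    list(
      factors = as.character(factor_names),
      levels_per_factor = 2L,
      n_cells = as.integer(2L^n_factors)
    ),
    class = "factorial_design"
  )
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("<factorial_design> %s (%d cells)\n",
              paste(rep("2", length(x$factors)), collapse = "x"), x$n_cells))
  invisible(x)
}

#' Map a cell index to its tuple of factor levels
#'
#' The mapping is fixed and bijective: bit `i` of the 0-based cell index is
#' the binary level of factor `i`.
#'
#' @param design A [factorial_design()].
#' @param cell 0-based cell index in `[0, n_cells)`.
#' @return Integer vector of binary levels, one per factor.
#' @seealso [levels_to_cell()]
#' @examples
#' d <- factorial_design(4)
#' cell_to_levels(d, 5L)  # c(1, 0, 1, 0)
#' @export
cell_to_levels <- function(design, cell) {
  stopifnot(inherits(design, "factorial_design"))
  cell <- as.integer(cell)
  if (length(cell) != 1L || is.na(cell) || cell < 0L || cell >= design$n_cells)
    stop(sprintf("cell index must be in [0, %d)", design$n_cells), call. = FALSE)
  vapply(seq_along(design$factors) - 1L,
         function(i) bitwAnd(bitwShiftR(cell, i), 1L), integer(1))
}

#' Map a tuple of factor levels to its cell index
#'
#' @inheritParams cell_to_levels
#' @param levels Integer vector of binary levels, one per factor.
#' @return 0-based cell index.
#' @export
levels_to_cell <- function(design, levels) {
  stopifnot(inherits(design, "factorial_design"))
  levels <- as.integer(levels)
  if (length(levels) != length(design$factors) || anyNA(levels) ||
      any(levels < 0L | levels > 1L))
    stop("`levels` must be a binary vector with one entry per factor",
         call. = FALSE)
  as.integer(sum(levels * 2L^(seq_along(levels) - 1L)))
}

# level of factor `factor` (1-based) for each 0-based cell index in `cells`
factor_level_of_cells <- function(cells, factor = 1L) {
  bitwAnd(bitwShiftR(as.integer(cells), as.integer(factor) - 1L), 1L)
}

#' Describe the binary covariate schema
#'
#' A schema lists the binary covariates carried by every participant. Each
#' covariate has a role: `"SC"` for the stratification-related covariates
#' (Hispanic and Black, which define the race/ethnicity strata used by
#' stratified permuted blocks) or `"MC"` for the remaining minimization
#' covariates. The `prevalence` column is used only by the synthetic-cohort
#' generator.
#'
#' @param name Character vector of covariate names.
#' @param role Character vector, each `"SC"` or `"MC"`.
#' @param prevalence Numeric vector of generator prevalences in (0, 1); may be
#'   `NA` for the SC covariates, whose marginals come from the ethnicity
#'   category probabilities instead.
#' @return A `covariate_schema` data frame with columns `name`, `role`,
#'   `prevalence`.
#' @export
covariate_schema <- function(name, role, prevalence = NA_real_) {
  name <- as.character(name)
  role <- as.character(role)
  prevalence <- rep_len(as.numeric(prevalence), length(name))
  if (length(role) != length(name))
    stop("`role` must have one entry per covariate", call. = FALSE)
  if (!all(role %in% c("SC", "MC")))
    stop("covariate roles must be 'SC' or 'MC'", call. = FALSE)
  if (anyDuplicated(name))
    stop("covariate names must be unique", call. = FALSE)
  bad <- !is.na(prevalence) & (prevalence <= 0 | prevalence >= 1)
  if (any(bad))
    stop("prevalences must lie strictly in (0, 1)", call. = FALSE)
  structure(
    data.frame(name = name, role = role, prevalence = prevalence,
               stringsAsFactors = FALSE),
    class = c("covariate_schema", "data.frame")
  )
}

#' Default eight-covariate schema
#'
#' Two stratification covariates (Hispanic, Black) plus six minimization
#' covariates (Medicaid status, works outside home, sex, child age, autism
#' diagnosis, high-school education), all binary. The SC marginals are set by
#' the generator's ethnicity probabilities; the MC prevalences default to 0.5.
#'
#' @return A [covariate_schema()] with 2 SC and 6 MC covariates.
#' @export
default_schema <- function() {
  covariate_schema(
    name = c("Hispanic", "Black", "Medicaid", "WorkOutsideHome", "Sex",
             "ChildAge", "Autism", "HighSchool"),
    role = c("SC", "SC", rep("MC", 6L)),
    prevalence = c(NA, NA, rep(0.5, 6L))
  )
}

#' Derive the race/ethnicity stratum from a participant's covariates
#'
#' Strata are coded 1 = Hispanic, 2 = non-Hispanic Black, 3 = other. A
#' participant positive on both Hispanic and Black resolves to stratum 1
#' (Hispanic takes precedence, following the coding order).
#'
#' @param covariates Named binary vector aligned to `schema`.
#' @param schema A [covariate_schema()] containing `Hispanic` and `Black`.
#' @return Integer stratum in `{1, 2, 3}`.
#' @examples
#' derive_stratum(c(Hispanic = 0, Black = 1), default_schema())  # 2
#' @export
derive_stratum <- function(covariates, schema) {
  if (!all(c("Hispanic", "Black") %in% schema$name))
    stop("schema must contain the stratification covariates 'Hispanic' and 'Black'",
         call. = FALSE)
  h <- covariates[["Hispanic"]]
  b <- covariates[["Black"]]
  if (h == 1L) 1L else if (b == 1L) 2L else 3L
}

# vectorized stratum derivation over a covariate matrix (rows = participants)
derive_strata <- function(cov_matrix, schema) {
  if (!all(c("Hispanic", "Black") %in% schema$name))
    stop("schema must contain the stratification covariates 'Hispanic' and 'Black'",
         call. = FALSE)
  h <- cov_matrix[, "Hispanic"]
  b <- cov_matrix[, "Black"]
  ifelse(h == 1L, 1L, ifelse(b == 1L, 2L, 3L))
}

#' Construct a cohort of participants in arrival order
#'
#' A cohort pairs an ordered participant table (one row per participant,
#' arrival order = row order) with its covariate schema. Row order is
#' significant and preserved by all readers and writers.
#'
#' @param data Data frame with an `id` column and one binary column per
#'   schema covariate.
#' @param schema A [covariate_schema()].
#' @return An object of class `cohort`: the data frame with a derived
#'   `stratum` column and the schema attached as an attribute.
#' @export
new_cohort <- function(data, schema) {
  stopifnot(is.data.frame(data))
  if (!"id" %in% names(data))
    stop("cohort data must have an `id` column", call. = FALSE)
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols))
    stop("cohort data is missing covariate columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cm <- as.matrix(data[, schema$name, drop = FALSE])
  storage.mode(cm) <- "integer"
  if (anyNA(cm) || any(cm != 0L & cm != 1L))
    stop("covariate values must be 0 or 1", call. = FALSE)
  out <- data.frame(id = as.integer(data$id), cm,
                    stratum = as.integer(derive_strata(cm, schema)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, schema = schema, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d covariates (%d SC + %d MC)\n",
              nrow(x), nrow(attr(x, "schema")),
              sum(attr(x, "schema")$role == "SC"),
              sum(attr(x, "schema")$role == "MC")))
  NextMethod()
}

#' Cohort schema accessor
#' @param cohort A [new_cohort()] object.
#' @return The attached [covariate_schema()].
#' @export
cohort_schema <- function(cohort) attr(cohort, "schema")

# covariate matrix view of a cohort, rows in arrival order
cohort_matrix <- function(cohort) {
  schema <- attr(cohort, "schema")
  m <- as.matrix(as.data.frame(cohort)[, schema$name, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Read a cohort from CSV
#'
#' Expects a header `id,<covariate names...>` with 0/1 values; row order is
#' the arrival order.
#'
#' @param path CSV file path.
#' @param schema A [covariate_schema()] the file must conform to.
#' @return A [new_cohort()] object.
#' @export
read_cohort_csv <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_cohort(df, schema)
}

#' Write a cohort to CSV
#'
#' Emits the `id,<covariate names...>` dialect (comma-separated, UTF-8, LF)
#' in arrival order; the derived stratum column is not written.
#'
#' @param cohort A [new_cohort()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  schema <- attr(cohort, "schema")
  df <- as.data.frame(cohort)[, c("id", schema$name), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  body <- do.call(paste, c(unname(as.list(df)), sep = ","))
  if (length(body)) writeLines(body, con, sep = "\n")
  invisible(path)
}
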