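#' Read a run configuration from a JSON or YAML file
#'
#' Recognized top-level keys (all optional; defaults as in [run_config()]):
#' `sims`, `procedures`, `seed`, `design` (`n_factors`), `schema` (list of
#' `{name, role, prevalence}`), `generator` (`n_source`, `n_sample`,
#' `ethnicity_probs`, `hispanic_black_rate`), `alphas` (`msb_trigger`,
#' `equivalence`), `weights` (`size`, `covariates`), `block_sizes`,
#' `full_logs`. YAML files require the `yaml` package.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  schema <- if (!is.null(raw$schema)) {
    s <- as.data.frame(raw$schema, stringsAsFactors = FALSE)
    covariate_schema(s$name, s$role,
                     if ("prevalence" %in% names(s)) s$prevalence else NA_real_)
  } else default_schema()
  gen_args <- list(schema = schema)
  for (key in c("n_source", "n_sample", "ethnicity_probs",
                "hispanic_black_rate"))
    if (!is.null(raw$generator[[key]])) gen_args[[key]] <- raw$generator[[key]]
  generator <- do.call(generator_config, gen_args)
  design <- factorial_design(
    if (!is.null(raw$design$n_factors)) raw$design$n_factors else 4L)
  args <- list(generator = generator, design = design)
  if (!is.null(raw$sims)) args$n_sims <- raw$sims
  if (!is.null(raw$procedures)) args$procedures <- unlist(raw$procedures)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$alphas$msb_trigger)) args$msb_alpha <- raw$alphas$msb_trigger
  if (!is.null(raw$alphas$equivalence))
    args$equivalence_alpha <- raw$alphas$equivalence
  if (!is.null(raw$weights)) args$weights <- raw$weights
  if (!is.null(raw$block_sizes)) args$block_sizes <- unlist(raw$block_sizes)
  if (!is.null(raw$full_logs)) args$full_logs <- raw$full_logs
  do.call(run_config, args)
}
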