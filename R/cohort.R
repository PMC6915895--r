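#' Synthetic source-population generator configuration
#'
#' Configures the generator that emulates the kind of source dataset the
#' simulations resample: a few hundred participants with binary
#' socio-demographic covariates, including Hispanic and Black indicators
#' that define three race/ethnicity strata. The default marginals —
#' ethnicity probabilities (0.40, 0.30, 0.30) for (Hispanic, non-Hispanic
#' Black, other) and 0.5 for every minimization covariate — are invented,
#' configurable stand-ins, not values estimated from any real dataset.
#'
#' @param n_source Source-population size (default 332).
#' @param n_sample Bootstrap sample size per simulated trial (default 304).
#' @param ethnicity_probs Probabilities of the (Hispanic, non-Hispanic Black,
#'   other) categories; must sum to 1.
#' @param schema [covariate_schema()] giving the covariates and the MC
#'   generator prevalences.
#' @param hispanic_black_rate Probability that a Hispanic participant is also
#'   Black-positive (default 0, i.e. exclusive categories; raise for stress
#'   testing the stratum-precedence rule).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_source = 332L, n_sample = 304L,
                             ethnicity_probs = c(0.40, 0.30, 0.30),
                             schema = default_schema(),
                             hispanic_black_rate = 0) {
  if (length(ethnicity_probs) != 3L || any(ethnicity_probs < 0) ||
      abs(sum(ethnicity_probs) - 1) > 1e-8)
    stop("`ethnicity_probs` must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  mc <- schema$prevalence[schema$role == "MC"]
  if (anyNA(mc) || any(mc <= 0 | mc >= 1))
    stop("every MC covariate needs a generator prevalence in (0, 1)",
         call. = FALSE)
  if (hispanic_black_rate < 0 || hispanic_black_rate > 1)
    stop("`hispanic_black_rate` must be a probability", call. = FALSE)
  structure(
    list(n_source = as.integer(n_source), n_sample = as.integer(n_sample),
         ethnicity_probs = as.numeric(ethnicity_probs), schema = schema,
         hispanic_black_rate = as.numeric(hispanic_black_rate)),
    class = "generator_config"
  )
}

#' Generate a synthetic source population
#'
#' Draws each participant's ethnicity category from `ethnicity_probs`, sets
#' the Hispanic and Black indicators consistently with it (Hispanic = 1 iff
#' category 1; Black = 1 iff category 2, plus optional Hispanic-and-Black
#' co-occurrence), and draws every MC covariate as an independent Bernoulli
#' at its schema prevalence. Deterministic given the RNG state.
#'
#' @param config A [generator_config()].
#' @return A [new_cohort()] of `n_source` participants.
#' @export
generate_source_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_source
  schema <- config$schema
  category <- sample.int(3L, n, replace = TRUE, prob = config$ethnicity_probs)
  hispanic <- as.integer(category == 1L)
  black <- as.integer(category == 2L)
  if (config$hispanic_black_rate > 0) {
    co <- hispanic == 1L &
      stats::runif(n) < config$hispanic_black_rate
    black[co] <- 1L
  }
  df <- data.frame(id = seq_len(n))
  for (k in seq_len(nrow(schema))) {
    nm <- schema$name[k]
    if (nm == "Hispanic") df[[nm]] <- hispanic
    else if (nm == "Black") df[[nm]] <- black
    else df[[nm]] <- as.integer(stats::runif(n) < schema$prevalence[k])
  }
  new_cohort(df, schema)
}

#' Draw a bootstrap sample from a source cohort
#'
#' Samples `n_sample` participants uniformly with replacement; the output
#' order is the draw order (this is the arrival order of the simulated
#' trial) and participant ids reference the source ids.
#'
#' @param source A [new_cohort()] source population.
#' @param n_sample Number of draws (default 304).
#' @return A [new_cohort()] of `n_sample` participants.
#' @export
bootstrap_sample <- function(source, n_sample = 304L) {
  stopifnot(inherits(source, "cohort"), nrow(source) > 0L)
  idx <- sample.int(nrow(source), n_sample, replace = TRUE)
  schema <- attr(source, "schema")
  df <- as.data.frame(source)[idx, c("id", schema$name), drop = FALSE]
  new_cohort(df, schema)
}
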