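#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with arbitrary labels (simulation index,
#' procedure identifier, purpose tag) into an integer in `[0, 2^31 - 2]` via
#' a rolling polynomial hash. Used by the harness to give every procedure in
#' every simulation its own named random stream, so that adding or removing
#' a procedure from a run never perturbs another procedure's results.
#'
#' @param master Master integer seed.
#' @param ... Labels (coerced to character) identifying the stream.
#' @return An integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character,
                                              character(1))),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
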