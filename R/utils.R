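# Internal helpers shared across modules.

#' Derive a child RNG seed from a base seed and an index
#'
#' Deterministic seed streams are needed so that per-gene and per-permutation
#' work units can run in any order (or in parallel) and still reproduce the
#' serial result. Uses a Lehmer-style step on the Mersenne-prime modulus
#' 2^31 - 1; all intermediates stay below 2^53 so the arithmetic is exact in
#' doubles.
#'
#' @param seed integer base seed.
#' @param index non-negative integer stream index.
#' @return a single integer in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271 + as.numeric(index) * 16807 + 1) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

# Condition-indicator columns are named with this prefix so they can be
# told apart from markers in selection-frequency profiles.
indicator_prefix <- "ct_"

indicator_name <- function(condition) paste0(indicator_prefix, condition)

is_indicator <- function(predictor) startsWith(predictor, indicator_prefix)

#' Log a bookkeeping message with a reason code
#'
#' All drop/skip events in the pipeline go through this helper so that runs
#' leave an auditable trail on the message stream.
#'
#' @param code short reason code, e.g. "drop_gene".
#' @param ... text fragments pasted into the message.
#' @keywords internal
log_event <- function(code, ...) {
  message(sprintf("[dyneqtl:%s] %s", code, paste0(...)))
}
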