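#' Derive a reproducible child seed
#'
#' Counter-based scheme so any single subject or resampling iteration can be
#' re-run in isolation: `seed_i = (1 + (master mod 1000003) * 69069 +
#' i * 1013904223) mod 2147483629`. All intermediates stay exactly
#' representable in doubles and the result fits a 32-bit integer.
#'
#' @param seed Master seed (integer).
#' @param i Counter (integer >= 0).
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, i) {
  x <- (1 + as.numeric(seed %% 1000003L) * 69069 +
        as.numeric(i) * 1013904223) %% 2147483629
  as.integer(x) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
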