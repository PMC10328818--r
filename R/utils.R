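#' Derive a reproducible substream seed
#'
#' One global seed drives every stochastic component; each component draws
#' from its own named substream so parts of a simulation can be regenerated
#' without disturbing the others.
#'
#' @param seed integer base seed.
#' @param stream character substream name (e.g. "covariates", "composition").
#' @return an integer seed below 2^31, deterministic in (seed, stream).
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # cheap string hash (polynomial rolling, modular); avoids external digest deps
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) %% 1000003L) * 1009 + h) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message(sprintf(...))
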