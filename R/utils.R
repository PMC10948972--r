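#' Derive a named substream seed from a run seed
#'
#' The simulator and the pipeline use one integer seed per run, split into
#' named substreams (landscape, climate, species, records, ...) so that stages
#' can be re-run independently and still reproduce bit-identical output.
#'
#' @param seed integer run seed.
#' @param label character substream name.
#' @return an integer seed in `[1, 2^31 - 1)` suitable for [set.seed()].
#' @export
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483629
  h <- abs(as.double(seed)) %% m
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assert that a vector of probabilities lies in [0, 1]
#' @noRd
check_prob <- function(x, name = deparse(substitute(x))) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
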