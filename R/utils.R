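#' Derive a child seed for a named pipeline stage
#'
#' All stochastic stages draw from their own stream derived from a single
#' master seed, so each stage is independently reproducible: re-running
#' one stage with the same master seed gives bit-identical output no
#' matter what ran before it.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_aligned <- function(ids_a, ids_b, what = "inputs") {
  if (length(ids_a) != length(ids_b) || !all(ids_a == ids_b)) {
    stop("sample ids of ", what, " are not aligned", call. = FALSE)
  }
  invisible(TRUE)
}
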