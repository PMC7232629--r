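#' Derive a reproducible sub-seed from a master seed
#'
#' Pipeline stages and per-unit computations each get their own RNG
#' seed derived from the master seed and a stage index by a fixed
#' affine-modular scheme, so any stage (or any single bootstrap cell)
#' can be rerun in isolation and reproduce the full-run result.  The
#' result always fits in a 32-bit integer.
#'
#' @param seed Master seed (integer).
#' @param stage Non-negative integer stage index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  as.integer((abs(seed) %% 1000003) * 2011 + stage) %% 2147483647L
}

#' @importFrom rlang .data
#' @importFrom stats plogis qlogis
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

as_binary01 <- function(x, what = "value") {
  x <- as.integer(x)
  if (any(!x %in% c(0L, 1L, NA_integer_))) {
    stop(what, " must be coded 0/1", call. = FALSE)
  }
  x
}
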