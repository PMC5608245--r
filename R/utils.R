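# Internal helpers shared across modules.

sigmoid <- function(z) 1 / (1 + exp(-z))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Every random draw in the package flows from a single master seed through
#' named sub-streams, so that independent stages (phantom generation, Poisson
#' sampling, weight initialization, ...) are decoupled yet fully reproducible.
#' The derived value always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param label character stream name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629 + 1)
}

# Sum of squared matrix entries without forming intermediates twice.
frob_norm <- function(W) sqrt(sum(W * W))

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
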