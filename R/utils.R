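# Internal helpers: error classes, activations, seed derivation.

abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fpgait_validation_error")
}

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fpgait_config_error")
}

abort_parse <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fpgait_parse_error")
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    abort_validation("%s contains non-finite values", what)
  }
  invisible(x)
}

#' Leaky rectified linear activation
#'
#' Elementwise `x` for `x >= 0` and `slope * x` otherwise. This is the
#' activation used inside the graph aggregation and for the spectral masks.
#'
#' @param x Numeric vector or array.
#' @param slope Negative-side slope (default 0.01).
#' @return Object shaped like `x`.
#' @export
leaky_relu <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

leaky_relu_grad <- function(x, slope = 0.01) {
  out <- (x >= 0) + 0
  out[!out] <- slope
  out
}

relu <- function(x) {
  pmax(x, 0)
}

# Deterministic per-item seed derivation, kept below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 129749) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
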