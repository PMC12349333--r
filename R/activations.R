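#' Hardswish activation
#'
#' Piecewise activation used throughout the lightweight blocks:
#' 0 for `x <= -3`, `x` for `x >= 3`, and `x * (x + 3) / 6` in between.
#' It is continuous everywhere (including at the knots at -3 and +3) and
#' monotone non-decreasing on `[-3, Inf)`, and is substantially cheaper than
#' SiLU/Swish on embedded targets, which is why the improved blocks use it.
#'
#' @param x numeric vector or array.
#' @return object of the same shape as `x`.
#' @examples
#' hardswish(c(-4, -3, 0, 1, 3, 5))
#' @export
hardswish <- function(x) {
  stopifnot(is.numeric(x))
  y <- x * (x + 3) / 6
  y[x <= -3] <- 0
  idx <- x >= 3
  y[idx] <- x[idx]
  y
}

# derivative of hardswish, needed by the backward pass
hardswish_grad <- function(x) {
  g <- (2 * x + 3) / 6
  g[x <= -3] <- 0
  g[x >= 3] <- 1
  g
}

#' SiLU (swish) activation
#'
#' `x * sigmoid(x)`; the default activation of the YOLOv8 baseline blocks.
#'
#' @param x numeric vector or array.
#' @return object of the same shape as `x`.
#' @export
silu <- function(x) x * stats::plogis(x)

silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

apply_act <- function(x, act) {
  switch(act, silu = silu(x), hardswish = hardswish(x), none = x)
}

act_grad <- function(x, act) {
  switch(act, silu = silu_grad(x), hardswish = hardswish_grad(x),
         none = array(1, dim = dim(x) %||% length(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
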