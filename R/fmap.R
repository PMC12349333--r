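#' Feature maps
#'
#' Internally a feature map is a dense matrix with `batch * height * width`
#' rows and `channels` columns (rows ordered column-major over (height, width)
#' within each sample, samples stacked), plus the spatial metadata. The
#' user-facing conversion accepts 4-axis arrays in (batch, channel, height,
#' width) order.
#'
#' @param arr numeric 4-D array, dims (batch, channel, height, width).
#' @return an object of class `fmap`.
#' @export
as_fmap <- function(arr) {
  stopifnot(is.array(arr), length(dim(arr)) == 4L, all(is.finite(arr)))
  d <- dim(arr)                       # n, c, h, w
  n <- d[1]; C <- d[2]; h <- d[3]; w <- d[4]
  # row order: h fastest, then w, then sample; columns = channels
  x <- matrix(aperm(arr, c(3, 4, 1, 2)), nrow = h * w * n, ncol = C)
  new_fmap(x, h, w, n)
}

#' @export
fmap_array <- function(fm) {
  stopifnot(inherits(fm, "fmap"))
  a <- array(fm$x, c(fm$h, fm$w, fm$n, ncol(fm$x)))
  aperm(a, c(3, 4, 1, 2))
}

new_fmap <- function(x, h, w, n) {
  fm <- list(x = x, h = h, w = w, n = n)
  class(fm) <- "fmap"
  fm
}

#' @export
dim.fmap <- function(x) c(x$n, ncol(x$x), x$h, x$w)

#' @export
print.fmap <- function(x, ...) {
  cat(sprintf("<fmap %d x %d x %d x %d (batch,channel,height,width)>\n",
              x$n, ncol(x$x), x$h, x$w))
  invisible(x)
}

#' Channel shuffle
#'
#' Deterministic channel permutation used after grouped convolutions: the
#' channel axis is reshaped to (groups, C/groups), transposed and flattened,
#' restoring information flow between groups. Composing with the shuffle for
#' `C/groups` groups inverts it.
#'
#' @param x an `fmap` or a 4-D array (batch, channel, height, width).
#' @param groups integer divisor of the channel count.
#' @return same type as the input with channels permuted.
#' @export
channel_shuffle <- function(x, groups) {
  arr_in <- !inherits(x, "fmap")
  fm <- if (arr_in) as_fmap(x) else x
  C <- ncol(fm$x)
  if (groups < 1 || C %% groups != 0)
    stop("`groups` must divide the channel count", call. = FALSE)
  perm <- shuffle_perm(C, groups)
  fm$x <- fm$x[, perm, drop = FALSE]
  if (arr_in) fmap_array(fm) else fm
}

# permutation such that new channel i = old channel perm[i]
shuffle_perm <- function(C, groups) {
  as.vector(t(matrix(seq_len(C), ncol = groups)))
}
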