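#' Adaptive kernel size for efficient channel attention (ECA)
#'
#' ECA re-weights feature channels with a short 1-D convolution across the
#' channel axis. The kernel width adapts to the channel count C by the rule
#' `k = odd(floor((log2(C) + b) / gamma))` with `gamma = 2`, `b = 1`
#' (even values are rounded up to the next odd), floored at 3.
#'
#' @param channels positive integer, number of channels entering the ECA unit.
#' @param gamma,b parameters of the adaptive rule (defaults 2 and 1).
#' @return an odd integer >= 3.
#' @examples
#' eca_kernel_size(64)   # 3
#' eca_kernel_size(256)  # 5
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  if (length(channels) != 1L || !is.finite(channels) || channels < 1)
    stop("`channels` must be a single integer >= 1", call. = FALSE)
  t <- floor((log2(channels) + b) / gamma)
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(k, 3))
}

# ---- ECA unit on flattened feature maps -------------------------------------
# A feature map is stored as a matrix X of (n*h*w) rows by C columns; row order
# is column-major over (h, w) within each sample, samples stacked.

eca_new <- function(channels, k = eca_kernel_size(channels)) {
  list(channels = as.integer(channels), k = as.integer(k),
       params = list(w = numeric(k)))   # zero init: weights start at sigmoid(0) = 0.5
}

# 1-D convolution over the channel axis with zero padding, per sample row of G
conv1d_channels <- function(G, w) {
  k <- length(w)
  p <- (k - 1L) / 2L
  C <- ncol(G)
  Gp <- cbind(matrix(0, nrow(G), p), G, matrix(0, nrow(G), p))
  A <- matrix(0, nrow(G), C)
  for (j in seq_len(k)) A <- A + Gp[, (j - 1L) + seq_len(C), drop = FALSE] * w[j]
  A
}

eca_forward <- function(unit, X, h, w, n, cache = FALSE) {
  hw <- h * w
  grp <- rep(seq_len(n), each = hw)
  G <- rowsum(X, grp, reorder = TRUE) / hw          # n x C global average pool
  dimnames(G) <- NULL
  A <- conv1d_channels(G, unit$params$w)
  Wt <- stats::plogis(A)                            # n x C channel weights in (0,1)
  Y <- X * Wt[grp, , drop = FALSE]
  if (cache) list(Y = Y, cache = list(X = X, G = G, Wt = Wt, grp = grp, hw = hw))
  else list(Y = Y, cache = NULL)
}

eca_backward <- function(unit, cache, dY) {
  X <- cache$X; G <- cache$G; Wt <- cache$Wt; grp <- cache$grp; hw <- cache$hw
  k <- unit$k; p <- (k - 1L) / 2L; C <- ncol(X)
  dX <- dY * Wt[grp, , drop = FALSE]
  dWt <- rowsum(dY * X, grp, reorder = TRUE)        # n x C
  dimnames(dWt) <- NULL
  dA <- dWt * Wt * (1 - Wt)
  # gradient wrt the 1-D kernel and wrt G (transposed convolution)
  Gp <- cbind(matrix(0, nrow(G), p), G, matrix(0, nrow(G), p))
  dw <- numeric(k)
  dGp <- matrix(0, nrow(G), C + 2L * p)
  for (j in seq_len(k)) {
    cols <- (j - 1L) + seq_len(C)
    dw[j] <- sum(Gp[, cols, drop = FALSE] * dA)
    dGp[, cols] <- dGp[, cols] + dA * unit$params$w[j]
  }
  dG <- dGp[, p + seq_len(C), drop = FALSE]
  dX <- dX + dG[grp, , drop = FALSE] / hw
  list(dX = dX, grads = list(w = dw))
}
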