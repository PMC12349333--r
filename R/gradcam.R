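#' Grad-CAM heatmap for a detection model
#'
#' Gradient-weighted class activation mapping: the class score of the most
#' confident cell (or of a requested class) is backpropagated to a target
#' layer; channel weights are the spatial means of the gradients, the map is
#' the rectified weighted sum of that layer's activations, normalized to
#' 0-255 and resized to the input size.
#'
#' @param model a `pfl_model`.
#' @param x input array `(1, 3, H, W)`, values in `[0, 1]`, spatial size
#'   divisible by 32.
#' @param target_layer 0-based layer index whose activations are visualized.
#'   By default the feature layer feeding the head at the scale of the best
#'   detection (15, 18 or 21 for strides 8/16/32) -- a layer off the gradient
#'   path of the explained score would receive no gradient and yield an
#'   all-zero map.
#' @param class_id optional 0-based class to explain; defaults to the class
#'   of the most confident cell.
#' @return numeric H x W matrix with values in `[0, 255]`.
#' @export
gradcam_map <- function(model, x, target_layer = NULL, class_id = NULL) {
  nl <- length(model$layers)
  if (!is.null(target_layer) && (target_layer < 0 || target_layer >= nl - 1L))
    stop("target_layer must index a feature layer (0..", nl - 2L, ")",
         call. = FALSE)
  if (dim(x)[1] != 1L) stop("gradcam expects a single image", call. = FALSE)
  fw <- model_forward(model, x, train = FALSE, cache = TRUE)
  nc <- model$nc
  reg <- 4L * 16L
  # locate the highest class probability across scales (optionally per class)
  best <- list(score = -Inf)
  for (si in 1:3) {
    L <- fw$raw[[si]]$X[, reg + seq_len(nc), drop = FALSE]
    if (!is.null(class_id)) {
      r <- which.max(L[, class_id + 1L])
      sc <- L[r, class_id + 1L]
      cl <- class_id
    } else {
      r <- which.max(apply(L, 1L, max))
      cl <- which.max(L[r, ]) - 1L
      sc <- L[r, cl + 1L]
    }
    if (sc > best$score) best <- list(score = sc, si = si, row = r, cl = cl)
  }
  if (is.null(target_layer))
    target_layer <- vapply(model$graph$blocks[[nl]]$from, identity, 0L)[best$si]
  draw <- lapply(1:3, function(si) matrix(0, nrow(fw$raw[[si]]$X),
                                          ncol(fw$raw[[si]]$X)))
  draw[[best$si]][best$row, reg + best$cl + 1L] <- 1
  bw <- model_backward(model, fw, draw, stop_at = target_layer)
  dA <- bw$douts[[target_layer + 1L]]$dX
  if (is.null(dA)) stop("no gradient reaches the requested layer", call. = FALSE)
  A <- fw$outs[[target_layer + 1L]]
  alpha <- colMeans(dA)
  cam <- pmax(as.vector(A$X %*% alpha), 0)
  cam <- matrix(cam, A$h, A$w)
  if (max(cam) > 0) cam <- cam / max(cam)
  resize_nearest(cam, dim(x)[3], dim(x)[4]) * 255
}

resize_nearest <- function(m, h, w) {
  ri <- pmin(pmax(ceiling(seq_len(h) * nrow(m) / h), 1L), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(w) * ncol(m) / w), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}
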