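# Decoding raw head outputs into boxes, and non-maximum suppression.
#
# Box regression follows the distribution-focal convention of the baseline
# head: each box side is a discrete distribution over reg_max bins decoded by
# expectation, in units of grid cells, around the cell-center anchor.

softmax_rows <- function(M) {
  M <- exp(M - apply(M, 1L, max))
  M / rowSums(M)
}

decode_scale <- function(fm, nc, stride, reg_max = 16L, conf_thr = 0.25) {
  X <- fm$X; h <- fm$h; w <- fm$w; n <- fm$n
  S <- nrow(X)
  rr <- (seq_len(S) - 1L) %% (h * w)
  hi <- rr %% h + 1L
  wi <- rr %/% h + 1L
  img <- (seq_len(S) - 1L) %/% (h * w) + 1L
  ax <- wi - 0.5
  ay <- hi - 0.5
  e <- matrix(0, S, 4L)
  for (s in 1:4) {
    sm <- softmax_rows(X[, (s - 1L) * reg_max + seq_len(reg_max), drop = FALSE])
    e[, s] <- sm %*% (seq_len(reg_max) - 1L)
  }
  probs <- stats::plogis(X[, 4L * reg_max + seq_len(nc), drop = FALSE])
  conf <- apply(probs, 1L, max)
  cls <- max.col(probs, ties.method = "first") - 1L
  keep <- conf >= conf_thr
  data.frame(image = img[keep], class = cls[keep], conf = conf[keep],
             x1 = (ax - e[, 1L])[keep] * stride, y1 = (ay - e[, 2L])[keep] * stride,
             x2 = (ax + e[, 3L])[keep] * stride, y2 = (ay + e[, 4L])[keep] * stride)
}

nms <- function(det, iou_thr = 0.45) {
  if (nrow(det) == 0L) return(det)
  keep <- logical(nrow(det))
  for (im in unique(det$image)) for (cl in unique(det$class)) {
    idx <- which(det$image == im & det$class == cl)
    idx <- idx[order(-det$conf[idx])]
    chosen <- integer()
    for (i in idx) {
      if (length(chosen) == 0L ||
          all(box_iou(det[i, c("x1", "y1", "x2", "y2")],
                      det[chosen, c("x1", "y1", "x2", "y2")]) < iou_thr))
        chosen <- c(chosen, i)
    }
    keep[chosen] <- TRUE
  }
  det[keep, , drop = FALSE]
}

#' Run detection on a batch of images
#'
#' Forward pass, distribution-focal decoding at every scale, confidence
#' filtering and per-class non-maximum suppression.
#'
#' @param model a `pfl_model`.
#' @param x 4-D array (batch, channel, height, width), values in `[0, 1]`.
#' @param conf_thr confidence threshold (default 0.25).
#' @param iou_thr NMS IoU threshold (default 0.45).
#' @return data frame: `image`, `class` (0-based), `conf`, `x1`, `y1`, `x2`,
#'   `y2` in input pixels.
#' @export
predict_boxes <- function(model, x, conf_thr = 0.25, iou_thr = 0.45) {
  fw <- model_forward(model, x, train = FALSE, cache = FALSE)
  nc <- model$nc
  dets <- do.call(rbind, lapply(1:3, function(i)
    decode_scale(fw$raw[[i]], nc, model$strides[i], conf_thr = conf_thr)))
  nms(dets[order(-dets$conf), , drop = FALSE], iou_thr)
}
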