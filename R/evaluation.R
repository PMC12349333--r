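# Detection metrics: IoU, confusion counts, precision/recall/F1, average
# precision with the monotone-envelope interpolation, mAP@50 and mAP@50:95,
# timing statistics, and the heatmap area-of-interest measurement.

#' Intersection over union of axis-aligned boxes
#'
#' @param a length-4 vector `(x1, y1, x2, y2)` or an n x 4 matrix.
#' @param b same shape as `a` (or one box recycled against a matrix).
#' @return numeric vector of IoU values in `[0, 1]`; degenerate unions give 0.
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(unlist(a)), ncol = 4L)
  b <- matrix(as.numeric(unlist(b)), ncol = 4L)
  if (nrow(a) == 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  ix <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  iy <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- ix * iy
  ua <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
        (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  ifelse(ua > 0, inter / ua, 0)
}

# greedy one-to-one matching in descending confidence; returns the per-
# prediction TP flag (ordered by descending confidence) plus per-class counts
match_predictions <- function(preds, gts, iou_thr = 0.5) {
  ord <- order(-preds$conf)
  preds <- preds[ord, , drop = FALSE]
  tp <- logical(nrow(preds))
  used <- logical(nrow(gts))
  for (i in seq_len(nrow(preds))) {
    cand <- which(!used & gts$image == preds$image[i] &
                    gts$class == preds$class[i])
    if (length(cand) == 0L) next
    ious <- box_iou(preds[i, c("x1", "y1", "x2", "y2")],
                    gts[cand, c("x1", "y1", "x2", "y2")])
    j <- which.max(ious)
    if (ious[j] >= iou_thr) { tp[i] <- TRUE; used[cand[j]] <- TRUE }
  }
  list(preds = preds, tp = tp, used = used)
}

#' Confusion counts from matched detections
#'
#' Greedy one-to-one matching in descending confidence: a prediction is a TP
#' when its class matches and it overlaps an unmatched ground-truth box at
#' IoU >= `iou_thr`, otherwise an FP; unmatched ground truths are FNs.
#'
#' @param preds data frame `image`, `class`, `conf`, `x1`, `y1`, `x2`, `y2`.
#' @param gts data frame `image`, `class`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_thr IoU threshold (default 0.5).
#' @param conf_thr confidence threshold applied before counting (default 0.25).
#' @return data frame per class: `class`, `tp`, `fp`, `fn`.
#' @export
match_and_count <- function(preds, gts, iou_thr = 0.5, conf_thr = 0.25) {
  preds <- preds[preds$conf >= conf_thr, , drop = FALSE]
  m <- match_predictions(preds, gts, iou_thr)
  classes <- sort(unique(c(m$preds$class, gts$class)))
  do.call(rbind, lapply(classes, function(cl) {
    pi <- m$preds$class == cl
    data.frame(class = cl,
               tp = sum(m$tp[pi]),
               fp = sum(!m$tp[pi]),
               fn = sum(gts$class == cl) - sum(m$tp[pi]))
  }))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with the 0/0
#' convention mapped to 0.
#'
#' @param tp,fp,fn counts (vectors are handled elementwise). `tp` may also be
#'   a data frame as returned by [match_and_count()].
#' @return data frame with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  data.frame(precision = p, recall = r, f1 = f1_score(p, r))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)` (0 when both are 0). Accepts either fractions
#' or percentages -- the result is on the same scale as the inputs.
#'
#' @param precision,recall numeric vectors.
#' @return numeric vector.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Average precision of one ranked prediction list
#'
#' Area under the precision-recall curve using the monotone precision
#' envelope (precision at each recall replaced by the maximum precision at
#' any higher recall) integrated exactly as a rectangle sum; `method =
#' "interp101"` instead samples the envelope at 101 evenly spaced recalls.
#'
#' @param tp logical vector of per-prediction TP flags, ordered by
#'   descending confidence.
#' @param n_gt number of ground-truth objects.
#' @param method `"envelope"` (default) or `"interp101"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp, n_gt, method = c("envelope", "interp101")) {
  method <- match.arg(method)
  if (n_gt == 0L) return(NA_real_)
  if (length(tp) == 0L || !any(tp)) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / n_gt
  # monotone envelope from the right
  env <- rev(cummax(rev(prec)))
  if (method == "interp101") {
    rs <- seq(0, 1, length.out = 101L)
    pe <- vapply(rs, function(r) {
      i <- which(rec >= r)
      if (length(i)) env[i[1L]] else 0
    }, 0)
    return(mean(pe))
  }
  dr <- diff(c(0, rec))
  sum(dr * env)
}

#' Evaluate detections: AP per class and threshold, mAP@50, mAP@50:95
#'
#' @inheritParams match_and_count
#' @param thresholds IoU thresholds; default `seq(0.5, 0.95, 0.05)`.
#' @param n_classes number of classes N for the class mean; defaults to the
#'   classes present in the ground truth.
#' @param method AP integration method, see [average_precision()].
#' @return list (`pfl_eval`): `ap` matrix (class x threshold), `map50`,
#'   `map5095`, per-class and mean `precision`/`recall`/`f1` at
#'   `conf_thr`/IoU 0.5, and `n_classes`.
#' @export
map_at <- function(preds, gts, thresholds = seq(0.5, 0.95, by = 0.05),
                   n_classes = NULL, conf_thr = 0.25,
                   method = "envelope") {
  classes <- sort(unique(gts$class))
  if (is.null(n_classes)) n_classes <- length(classes)
  ap <- matrix(NA_real_, length(classes), length(thresholds),
               dimnames = list(classes, thresholds))
  for (k in seq_along(thresholds)) {
    m <- match_predictions(preds, gts, thresholds[k])
    for (ci in seq_along(classes)) {
      sel <- m$preds$class == classes[ci]
      ap[ci, k] <- average_precision(m$tp[sel],
                                     sum(gts$class == classes[ci]),
                                     method = method)
    }
  }
  counts <- match_and_count(preds, gts, iou_thr = 0.5, conf_thr = conf_thr)
  prf <- precision_recall_f1(counts)
  res <- list(ap = ap,
              map50 = mean(ap[, 1L], na.rm = TRUE),
              map5095 = mean(ap, na.rm = TRUE),
              per_class = cbind(counts, prf),
              precision = mean(prf$precision),
              recall = mean(prf$recall),
              f1 = f1_score(mean(prf$precision), mean(prf$recall)),
              n_classes = n_classes)
  class(res) <- "pfl_eval"
  res
}

#' @export
print.pfl_eval <- function(x, ...) {
  cat(sprintf("<eval over %d classes: P %.3f R %.3f F1 %.2f mAP@50 %.3f mAP@50:95 %.3f>\n",
              x$n_classes, x$precision, x$recall, 100 * x$f1, x$map50, x$map5095))
  invisible(x)
}

#' Detection timing statistics
#'
#' Mean per-image detection time (`Dt`, the sum of pre-process, inference
#' and post-process per image) and the frame rate `FPS = 1000 / Dt` for
#' times in milliseconds.
#'
#' @param t_ms numeric vector of per-image times in milliseconds.
#' @return list with `M`, `dt_ms`, `fps`.
#' @export
timing_stats <- function(t_ms) {
  if (length(t_ms) < 1L) stop("need at least one timing", call. = FALSE)
  dt <- mean(t_ms)
  list(M = length(t_ms), dt_ms = dt, fps = 1000 / dt)
}

#' Heatmap area of interest
#'
#' Grayscale conversion, binarization, contour extraction and area
#' computation of the contour-enclosed regions. With `method = "contour"`
#' the area is the Green's-theorem (shoelace) area of each traced external
#' contour, which yields half-pixel values and, for a filled w x h
#' rectangle, `(w-1)*(h-1)`; `method = "pixel"` counts the filled pixels
#' (exactly `w*h` for that rectangle). Interior holes are filled before
#' measuring, so the area is the region enclosed by the outer contour.
#'
#' @param heatmap numeric matrix or H x W x 3 array, any non-negative scale.
#' @param threshold binarization threshold on the `[0, 1]` normalized map;
#'   `"otsu"` (default) or a number.
#' @param method `"contour"` (default) or `"pixel"`.
#' @return total area in pixels (possibly fractional for `"contour"`).
#' @export
aoi_area <- function(heatmap, threshold = "otsu", method = c("contour", "pixel")) {
  method <- match.arg(method)
  g <- to_gray(heatmap)
  if (max(g) <= 0) return(0)
  g <- g / max(g)
  thr <- if (identical(threshold, "otsu")) EBImage::otsu(EBImage::Image(g))
         else as.numeric(threshold)
  bin <- EBImage::fillHull(EBImage::bwlabel(g > thr))
  if (method == "pixel") return(sum(bin > 0))
  ct <- EBImage::ocontour(bin)
  sum(vapply(ct, shoelace_area, 0))
}

shoelace_area <- function(p) {
  if (nrow(p) < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
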