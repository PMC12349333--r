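# Synthetic fixture data: procedural "faces" with per-class color/stripe
# signatures so that every pipeline stage (dedup, validation, augmentation,
# splitting, smoke training, evaluation, Grad-CAM) is testable without any
# external download. The faces are deliberately schematic stand-ins (ellipse
# + eye dots + class-specific hue/stripes), not renderings of real animals.

#' Generate a synthetic labeled face dataset
#'
#' Each identity class gets a distinctive signature (hue from a golden-angle
#' palette, stripe frequency and orientation). Every image contains exactly
#' one face -- an ellipse with two eye dots -- at a random position and scale
#' on a noisy background, with its axis-aligned bounding box as the single
#' YOLO-style label. A fraction of images are near-duplicate jittered copies
#' of the previous image of the same class (SSIM above the usual 0.75
#' threshold), to exercise the duplicate filter.
#'
#' @param n_classes number of identity classes (default 60).
#' @param per_class images per class.
#' @param image_size square image side in pixels.
#' @param near_duplicate_rate fraction of images per class generated as
#'   near-duplicates of their predecessor.
#' @param seed RNG seed; the dataset is fully reproducible from it.
#' @return list of items; each item is a list with `id`, `class_id`, `image`
#'   (H x W x 3, 0-255) and `label` (`class_id`, `cx`, `cy`, `w`, `h`).
#' @export
gen_face_dataset <- function(n_classes = 60L, per_class = 10L,
                             image_size = 96L, near_duplicate_rate = 0,
                             seed = 0L) {
  set.seed(seed)
  items <- list()
  for (cl in seq_len(n_classes) - 1L) {
    sig <- class_signature(cl)
    n_dup <- round(near_duplicate_rate * per_class)
    n_fresh <- max(1L, per_class - n_dup)
    fresh <- vector("list", n_fresh)
    for (j in seq_len(per_class)) {
      if (j <= n_fresh) {
        it <- draw_face(sig, image_size)
        fresh[[j]] <- it
      } else {
        # jittered copy of a fresh image: SSIM stays well above 0.75
        it <- fresh[[(j - n_fresh - 1L) %% n_fresh + 1L]]
        it$image <- pmin(pmax(it$image +
          array(stats::rnorm(length(it$image), sd = 2), dim(it$image)), 0), 255)
      }
      it$id <- sprintf("c%02d_%03d", cl, j)
      it$class_id <- cl
      it$label$class_id <- cl
      items[[length(items) + 1L]] <- it
    }
  }
  items
}

class_signature <- function(class_id) {
  hue <- (class_id * 0.381966) %% 1
  list(hue = hue,
       stripe_freq = 3 + (class_id %% 7),
       stripe_angle = (class_id %% 12) * pi / 12,
       stripe_strength = 0.35 + 0.05 * (class_id %% 4))
}

draw_face <- function(sig, sz) {
  bg <- array(stats::runif(sz * sz * 3, 90, 130), c(sz, sz, 3))
  cx <- stats::runif(1, 0.3, 0.7)
  cy <- stats::runif(1, 0.3, 0.7)
  rx <- stats::runif(1, 0.14, 0.2)
  ry <- rx * stats::runif(1, 1.1, 1.35)
  xs <- (col(matrix(0, sz, sz)) - 0.5) / sz
  ys <- (row(matrix(0, sz, sz)) - 0.5) / sz
  inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  base <- hsv_to_rgb_scalar(sig$hue, 0.65, 0.85)
  stripes <- sin(2 * pi * sig$stripe_freq *
                 (cos(sig$stripe_angle) * (xs - cx) / rx +
                  sin(sig$stripe_angle) * (ys - cy) / ry))
  shade <- 1 + sig$stripe_strength * stripes
  img <- bg
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- pmin(pmax(255 * base[ch] * shade[inside], 0), 255)
    img[, , ch] <- plane
  }
  for (ex in c(-0.45, 0.45)) {
    eye <- ((xs - (cx + ex * rx))^2 + (ys - (cy - 0.25 * ry))^2) <= (0.12 * rx)^2
    for (ch in 1:3) { plane <- img[, , ch]; plane[eye] <- 25; img[, , ch] <- plane }
  }
  x1 <- max(cx - rx, 0); x2 <- min(cx + rx, 1)
  y1 <- max(cy - ry, 0); y2 <- min(cy + ry, 1)
  list(image = img,
       label = list(class_id = NA_integer_, cx = (x1 + x2) / 2,
                    cy = (y1 + y2) / 2, w = x2 - x1, h = y2 - y1))
}

hsv_to_rgb_scalar <- function(h, s, v) {
  a <- hsv_to_rgb(array(c(h, s, v), c(1, 1, 3)))
  as.vector(a)
}

#' Generate a synthetic heatmap with known hot regions
#'
#' Grayscale map (0-255) with rectangular or elliptical hot regions on a cold
#' background -- ground truth fixtures for the heatmap area-of-interest
#' measurement.
#'
#' @param shape `c(height, width)` in pixels.
#' @param regions list of regions; each a list with `type` ("rect" or
#'   "ellipse"), `intensity` (0-255) and either `x`, `y`, `w`, `h` (rect,
#'   1-based top-left corner) or `cx`, `cy`, `rx`, `ry` (ellipse), in pixels.
#' @param background background intensity.
#' @return numeric matrix `shape[1]` x `shape[2]`.
#' @export
gen_heatmap <- function(shape, regions = list(), background = 0) {
  m <- matrix(background, shape[1], shape[2])
  for (rg in regions) {
    if (rg$type == "rect") {
      rows <- rg$y:(rg$y + rg$h - 1L)
      cols <- rg$x:(rg$x + rg$w - 1L)
      m[rows, cols] <- rg$intensity
    } else if (rg$type == "ellipse") {
      rr <- row(m); cc <- col(m)
      mask <- ((cc - rg$cx) / rg$rx)^2 + ((rr - rg$cy) / rg$ry)^2 <= 1
      m[mask] <- rg$intensity
    } else stop("unknown region type: ", rg$type, call. = FALSE)
  }
  m
}
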