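# Dataset-curation toolkit: frame extraction, SSIM near-duplicate filtering,
# YOLO-txt label validation, single-draw augmentation and the
# split-then-augment partition.

#' Structural similarity (global form)
#'
#' SSIM between two equally sized images from their global means, variances
#' and covariance:
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'                   {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}}
#' with \eqn{C_1 = (k_1 L)^2}, \eqn{C_2 = (k_2 L)^2}. Color images are
#' converted to luma (0.299 R + 0.587 G + 0.114 B) first. Values near 1
#' indicate near-duplicates. This is the single-window (global statistics)
#' form; `windowed = TRUE` averages the same statistic over non-overlapping
#' 8x8 tiles for robustness studies.
#'
#' @param x,y numeric matrices (grayscale) or H x W x 3 arrays on the `[0, L]`
#'   scale.
#' @param k1,k2 stabilization constants (defaults 0.01, 0.03).
#' @param L dynamic range of pixel values (default 255).
#' @param windowed logical, see above.
#' @return a scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, k1 = 0.01, k2 = 0.03, L = 255, windowed = FALSE) {
  x <- to_gray(x); y <- to_gray(y)
  if (!identical(dim(x), dim(y)))
    stop("images must have identical dimensions", call. = FALSE)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  stat <- function(xv, yv) {
    n <- length(xv)
    mx <- mean(xv); my <- mean(yv)
    vx <- sum((xv - mx)^2) / n
    vy <- sum((yv - my)^2) / n
    cxy <- sum((xv - mx) * (yv - my)) / n
    ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
  if (!windowed) return(stat(as.vector(x), as.vector(y)))
  h <- nrow(x); w <- ncol(x)
  ti <- (seq_len(h) - 1L) %/% 8L
  tj <- (seq_len(w) - 1L) %/% 8L
  tiles <- split(seq_along(x), outer(ti, tj, function(a, b) a * 1e6 + b))
  mean(vapply(tiles, function(ix) stat(x[ix], y[ix]), 0))
}

to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] == 3L)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) return(img[, , 1])
  stop("expected a matrix or an H x W x 3 array", call. = FALSE)
}

#' Greedy SSIM near-duplicate filter
#'
#' Sequential scan (in input order, optionally within identity classes): an
#' image is rejected when its SSIM against any already-retained image of the
#' same class exceeds `threshold`. Deterministic and idempotent.
#'
#' @param images list of images (matrices or H x W x 3 arrays).
#' @param threshold SSIM rejection threshold (default 0.75).
#' @param class_id optional vector of class labels, one per image; filtering
#'   is then performed independently within each class.
#' @param ... passed to [ssim()].
#' @return integer vector of retained indices (in input order).
#' @export
dedup_filter <- function(images, threshold = 0.75, class_id = NULL, ...) {
  n <- length(images)
  if (is.null(class_id)) class_id <- rep(1L, n)
  stopifnot(length(class_id) == n)
  keep <- logical(n)
  for (cl in unique(class_id)) {
    retained <- integer()
    for (i in which(class_id == cl)) {
      dup <- FALSE
      for (j in retained)
        if (ssim(images[[i]], images[[j]], ...) > threshold) { dup <- TRUE; break }
      if (!dup) { retained <- c(retained, i); keep[i] <- TRUE }
    }
  }
  which(keep)
}

#' Extract frames at a fixed stride
#'
#' Takes frames 0, `stride`, `2 * stride`, ... (0-based) from a frame
#' sequence, mirroring interval-based frame extraction from video.
#'
#' @param video a list of frames, or an array whose last dimension indexes
#'   frames.
#' @param stride frame interval (default 30).
#' @return list of frames.
#' @export
extract_frames <- function(video, stride = 30L) {
  stopifnot(stride >= 1)
  frames <- if (is.list(video)) video
  else {
    nd <- length(dim(video))
    lapply(seq_len(dim(video)[nd]), function(i)
      if (nd == 3L) video[, , i] else video[, , , i])
  }
  if (length(frames) == 0L) return(list())
  frames[seq(1L, length(frames), by = stride)]
}

#' Validate YOLO-style labels
#'
#' Checks, per image: exactly one label; class id within `0..nc-1`; every
#' box edge (`cx +/- w/2`, `cy +/- h/2`) inside `[0, 1]`.
#'
#' @param manifest data frame with columns `image`, `class_id`, `cx`, `cy`,
#'   `w`, `h` (normalized).
#' @param nc number of classes.
#' @param images optional character vector of all image ids (to catch images
#'   with no label at all); defaults to the ids present in `manifest`.
#' @return data frame, one row per image, with logical flag columns
#'   `bad_count`, `bad_class`, `out_of_bounds` and the summary `ok`.
#' @export
validate_labels <- function(manifest, nc = 60L, images = NULL) {
  if (is.null(images)) images <- unique(manifest$image)
  out <- do.call(rbind, lapply(images, function(im) {
    rows <- manifest[manifest$image == im, , drop = FALSE]
    bad_count <- nrow(rows) != 1L
    bad_class <- any(rows$class_id < 0 | rows$class_id > nc - 1 |
                       rows$class_id != floor(rows$class_id))
    oob <- any(rows$cx - rows$w / 2 < 0 | rows$cx + rows$w / 2 > 1 |
                 rows$cy - rows$h / 2 < 0 | rows$cy + rows$h / 2 > 1 |
                 rows$w <= 0 | rows$h <= 0)
    data.frame(image = im, bad_count = bad_count,
               bad_class = isTRUE(bad_class), out_of_bounds = isTRUE(oob))
  }))
  out$ok <- !(out$bad_count | out$bad_class | out$out_of_bounds)
  out
}

#' Apply one randomly drawn augmentation
#'
#' Draws exactly one transform uniformly from: horizontal flip, vertical
#' flip, random 90-degree rotation (k in 1..3), shift-scale-rotate
#' (shift +/-6.25%, scale +/-10%, rotation +/-15 degrees), random
#' brightness/contrast, hue-saturation-value jitter. Geometric transforms
#' update the bounding box by transforming its four corners and refitting the
#' axis-aligned box (clipped to the image); photometric transforms leave the
#' label untouched. A draw whose clipped box degenerates to zero area is
#' rejected and redrawn.
#'
#' @param item list with `image` (H x W x 3 array, 0-255) and `label`
#'   (list `class_id`, `cx`, `cy`, `w`, `h`).
#' @param transform optional transform name to force (mainly for tests):
#'   one of `"hflip"`, `"vflip"`, `"rot90"`, `"ssr"`, `"brightness"`, `"hsv"`.
#' @return the augmented item; the applied transform name is attached as
#'   attribute `"transform"`.
#' @export
augment_once <- function(item, transform = NULL) {
  choices <- c("hflip", "vflip", "rot90", "ssr", "brightness", "hsv")
  repeat {
    tr <- if (is.null(transform)) sample(choices, 1L) else transform
    res <- switch(tr,
      hflip = aug_hflip(item), vflip = aug_vflip(item),
      rot90 = aug_rot90(item, sample(1:3, 1L)),
      ssr = aug_ssr(item, stats::runif(1, -0.0625, 0.0625),
                    stats::runif(1, -0.0625, 0.0625),
                    stats::runif(1, 0.9, 1.1),
                    stats::runif(1, -15, 15)),
      brightness = aug_brightness(item, stats::runif(1, -0.2, 0.2),
                                  stats::runif(1, -0.2, 0.2)),
      hsv = aug_hsv(item, stats::runif(1, -20, 20), stats::runif(1, -0.2, 0.2),
                    stats::runif(1, -0.2, 0.2)))
    if (!is.null(res)) { attr(res, "transform") <- tr; return(res) }
    if (!is.null(transform))
      stop("requested transform degenerates the box", call. = FALSE)
  }
}

aug_hflip <- function(item) {
  item$image <- item$image[, rev(seq_len(dim(item$image)[2])), , drop = FALSE]
  item$label$cx <- 1 - item$label$cx
  item
}

aug_vflip <- function(item) {
  item$image <- item$image[rev(seq_len(dim(item$image)[1])), , , drop = FALSE]
  item$label$cy <- 1 - item$label$cy
  item
}

# k counter-clockwise quarter turns
aug_rot90 <- function(item, k = 1L) {
  rot1 <- function(img) {  # counter-clockwise: (r, c) <- (c, W + 1 - r)
    aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , , drop = FALSE]
  }
  for (i in seq_len(k %% 4L)) {
    item$image <- rot1(item$image)
    l <- item$label
    item$label$cx <- l$cy
    item$label$cy <- 1 - l$cx
    item$label$w <- l$h
    item$label$h <- l$w
  }
  item
}

# shift-scale-rotate around the image center; returns NULL when the clipped
# box degenerates
aug_ssr <- function(item, shift_x, shift_y, scale, angle_deg) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  l <- item$label
  corners <- rbind(c(l$cx - l$w / 2, l$cy - l$h / 2),
                   c(l$cx + l$w / 2, l$cy - l$h / 2),
                   c(l$cx + l$w / 2, l$cy + l$h / 2),
                   c(l$cx - l$w / 2, l$cy + l$h / 2))
  tc <- t(scale * R %*% (t(corners) - 0.5) + 0.5 + c(shift_x, shift_y))
  x1 <- max(min(tc[, 1]), 0); x2 <- min(max(tc[, 1]), 1)
  y1 <- max(min(tc[, 2]), 0); y2 <- min(max(tc[, 2]), 1)
  if (x2 - x1 <= 1e-6 || y2 - y1 <= 1e-6) return(NULL)
  item$label <- list(class_id = l$class_id, cx = (x1 + x2) / 2,
                     cy = (y1 + y2) / 2, w = x2 - x1, h = y2 - y1)
  item$image <- warp_image(item$image, shift_x, shift_y, scale, th)
  item
}

# bilinear warp through EBImage; the affine map acts on normalized
# coordinates about the image center
warp_image <- function(img, shift_x, shift_y, scale, th) {
  h <- dim(img)[1]; w <- dim(img)[2]
  # EBImage uses (x, y) = (column, row) pixel coordinates
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  cx <- w / 2; cy <- h / 2
  off <- c(cx + shift_x * w, cy + shift_y * h) - R %*% c(cx, cy)
  m <- rbind(t(R), as.vector(off))          # 3 x 2, as EBImage expects
  out <- array(0, dim(img))
  for (ch in seq_len(dim(img)[3])) {
    ximg <- EBImage::Image(t(img[, , ch]) / 255)
    wimg <- EBImage::affine(ximg, m, filter = "bilinear",
                            output.dim = c(w, h), bg.col = 0)
    out[, , ch] <- t(as.array(wimg)) * 255
  }
  out
}

aug_brightness <- function(item, alpha, beta) {
  img <- item$image * (1 + alpha) + beta * 255
  item$image <- pmin(pmax(img, 0), 255)
  item
}

aug_hsv <- function(item, hue_shift_deg, sat_shift, val_shift) {
  img <- item$image / 255
  hsv <- rgb_to_hsv(img)
  hsv[, , 1] <- (hsv[, , 1] + hue_shift_deg / 360) %% 1
  hsv[, , 2] <- pmin(pmax(hsv[, , 2] + sat_shift, 0), 1)
  hsv[, , 3] <- pmin(pmax(hsv[, , 3] + val_shift, 0), 1)
  item$image <- hsv_to_rgb(hsv) * 255
  item
}

rgb_to_hsv <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  i <- d > 0 & mx == r; h[i] <- ((g - b) / d)[i] %% 6
  i <- d > 0 & mx == g & mx != r; h[i] <- ((b - r) / d)[i] + 2
  i <- d > 0 & mx == b & mx != r & mx != g; h[i] <- ((r - g) / d)[i] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  out <- array(0, dim(img)); out[, , 1] <- h; out[, , 2] <- s; out[, , 3] <- mx
  out
}

hsv_to_rgb <- function(hsv) {
  h <- hsv[, , 1] * 6; s <- hsv[, , 2]; v <- hsv[, , 3]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- v; g <- v; b <- v
  r[i == 1] <- q[i == 1]; r[i == 2] <- p[i == 2]; r[i == 3] <- p[i == 3]
  r[i == 4] <- t[i == 4]
  g[i == 0] <- t[i == 0]; g[i == 3] <- q[i == 3]; g[i == 4] <- p[i == 4]
  g[i == 5] <- p[i == 5]
  b[i == 0] <- p[i == 0]; b[i == 1] <- p[i == 1]; b[i == 2] <- t[i == 2]
  b[i == 5] <- q[i == 5]
  out <- array(0, dim(hsv)); out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Split a dataset 8:1:1, then double each split by augmentation
#'
#' Global random split with `val = test = floor(N / 10)` and
#' `train = N - 2 * floor(N / 10)` (the only rule consistent with a
#' 6418 -> 5136/641/641 partition), followed by exactly one augmented copy of
#' every item within its own split, so each split and each per-class count
#' doubles.
#'
#' @param ids vector of item identifiers.
#' @param seed RNG seed for the split.
#' @param class_id optional per-item class labels carried into the counts.
#' @return list with `filtered` (lists `train`, `val`, `test` of ids),
#'   `augmented` (same splits with the `_aug` copies appended) and `counts`
#'   (data frame of split sizes at both stages).
#' @export
split_then_augment <- function(ids, seed = 0L, class_id = NULL) {
  n <- length(ids)
  k <- floor(n / 10)
  set.seed(seed)
  perm <- sample(n)
  val_i <- perm[seq_len(k)]
  test_i <- perm[k + seq_len(k)]
  train_i <- sort(perm[setdiff(seq_len(n), seq_len(2 * k))])
  filtered <- list(train = ids[train_i], val = ids[sort(val_i)],
                   test = ids[sort(test_i)])
  augmented <- lapply(filtered, function(s) c(s, paste0(s, "_aug")))
  counts <- data.frame(
    split = c("train", "val", "test", "total"),
    filtered = c(lengths(filtered), n),
    augmented = c(lengths(augmented), 2L * n))
  res <- list(filtered = filtered, augmented = augmented, counts = counts)
  if (!is.null(class_id)) {
    names(class_id) <- ids
    res$class_counts <- data.frame(
      class_id = sort(unique(class_id)),
      filtered = as.vector(table(class_id)[as.character(sort(unique(class_id)))]))
    res$class_counts$augmented <- 2L * res$class_counts$filtered
  }
  res
}

#' Read and write YOLO-txt label files
#'
#' One file per image, one line per object: `class cx cy w h`, normalized,
#' space-separated.
#'
#' @param manifest data frame with `image`, `class_id`, `cx`, `cy`, `w`, `h`.
#' @param dir directory for the `.txt` files.
#' @export
write_yolo_labels <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (im in unique(manifest$image)) {
    rows <- manifest[manifest$image == im, , drop = FALSE]
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f", rows$class_id, rows$cx,
                       rows$cy, rows$w, rows$h),
               file.path(dir, paste0(im, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_yolo_labels
#' @param files specific files to read (defaults to every `.txt` in `dir`).
#' @export
read_yolo_labels <- function(dir, files = NULL) {
  if (is.null(files)) files <- list.files(dir, pattern = "\\.txt$")
  do.call(rbind, lapply(files, function(f) {
    lines <- readLines(file.path(dir, f))
    if (length(lines) == 0L) return(NULL)
    m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
    data.frame(image = sub("\\.txt$", "", f), class_id = as.integer(m[, 1]),
               cx = m[, 2], cy = m[, 3], w = m[, 4], h = m[, 5])
  }))
}
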