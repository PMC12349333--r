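# Dataset curation: SSIM, duplicate filtering, frame extraction, label
# validation, augmentation and the split-then-augment partition.

test_that("ssim: identity, constant-image closed form, symmetry, errors", {
  set.seed(101)
  a <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(ssim(a, a), 1.0)
  z0 <- matrix(0, 10, 10)
  z255 <- matrix(255, 10, 10)
  C1 <- (0.01 * 255)^2
  expect_equal(ssim(z0, z255), C1 / (255^2 + C1), tolerance = 1e-9)
  b <- matrix(runif(400, 0, 255), 20, 20)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_error(ssim(a, matrix(0, 5, 5)), "dimensions")
  # color images go through luma weighting
  rgb <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  expect_equal(ssim(rgb, rgb), 1.0)
})

test_that("dedup_filter keeps dissimilar images, drops constructed near-dups", {
  set.seed(102)
  A <- matrix(runif(900, 0, 255), 30, 30)
  A2 <- pmin(pmax(A + matrix(rnorm(900, sd = 2), 30, 30), 0), 255)
  B <- matrix(runif(900, 0, 255), 30, 30)
  expect_gt(ssim(A, A2), 0.75)
  expect_lt(ssim(A, B), 0.75)
  expect_identical(dedup_filter(list(A, A2, B)), c(1L, 3L))
  expect_identical(dedup_filter(list(A, A)), 1L)
  expect_identical(dedup_filter(list(A, B)), c(1L, 2L))
  # idempotent: filtering a filtered set removes nothing
  kept <- dedup_filter(list(A, A2, B))
  expect_identical(dedup_filter(list(A, B)[]), seq_along(list(A, B)))
  # per-class grouping: near-dups in different classes are both kept
  expect_identical(dedup_filter(list(A, A2), class_id = c(1, 2)), c(1L, 2L))
})

test_that("extract_frames picks every stride-th frame from index 0", {
  frames <- lapply(1:90, function(i) matrix(i, 2, 2))
  got <- extract_frames(frames, 30)
  expect_length(got, 3)
  expect_equal(sapply(got, function(f) f[1, 1]), c(1, 31, 61))
  expect_length(extract_frames(frames, 1), 90)
  expect_length(extract_frames(list()), 0)
  arr <- array(0, c(2, 2, 5))
  expect_length(extract_frames(arr, 2), 3)
})

test_that("validate_labels flags bad class ids, OOB boxes and label counts", {
  man <- data.frame(image = c("a", "b", "c", "d", "d"),
                    class_id = c(0, 61, 3, 1, 2),
                    cx = c(0.5, 0.5, 0.5, 0.5, 0.5),
                    cy = c(0.5, 0.5, 0.5, 0.5, 0.5),
                    w = c(0.4, 0.2, 1.2, 0.1, 0.1),
                    h = c(0.4, 0.2, 0.2, 0.1, 0.1))
  v <- validate_labels(man, nc = 60, images = c("a", "b", "c", "d", "e"))
  expect_true(v$ok[v$image == "a"])
  expect_true(v$bad_class[v$image == "b"])
  expect_true(v$out_of_bounds[v$image == "c"])   # cx + w/2 = 1.1
  expect_true(v$bad_count[v$image == "d"])       # two labels
  expect_true(v$bad_count[v$image == "e"])       # no label at all
})

test_that("flip and rot90 label updates match the corner-point oracle", {
  set.seed(103)
  corner_oracle <- function(l, f) {
    cs <- rbind(c(l$cx - l$w / 2, l$cy - l$h / 2),
                c(l$cx + l$w / 2, l$cy - l$h / 2),
                c(l$cx + l$w / 2, l$cy + l$h / 2),
                c(l$cx - l$w / 2, l$cy + l$h / 2))
    tc <- t(apply(cs, 1, f))
    list(cx = mean(range(tc[, 1])), cy = mean(range(tc[, 2])),
         w = diff(range(tc[, 1])), h = diff(range(tc[, 2])))
  }
  it <- fixture_item(cx = 0.3, cy = 0.2, bw = 0.2, bh = 0.1)
  hf <- augment_once(it, "hflip")
  want <- corner_oracle(it$label, function(p) c(1 - p[1], p[2]))
  expect_equal(hf$label[c("cx", "cy", "w", "h")], want)
  expect_equal(hf$label$cx, 0.7)
  vf <- augment_once(it, "vflip")
  expect_equal(vf$label[c("cx", "cy", "w", "h")],
               corner_oracle(it$label, function(p) c(p[1], 1 - p[2])))
  # one counter-clockwise quarter turn: (0.3, 0.2) -> (0.2, 0.7), w/h swap
  r1 <- pflyolo:::aug_rot90(it, 1)
  expect_equal(r1$label[c("cx", "cy", "w", "h")],
               corner_oracle(it$label, function(p) c(p[2], 1 - p[1])))
  expect_equal(unlist(r1$label[c("cx", "cy")]), c(cx = 0.2, cy = 0.7))
  expect_equal(r1$label$w, it$label$h)
  # image content moves with the label: the bright box follows
  box_mean <- function(item) {
    d <- dim(item$image)
    l <- item$label
    rows <- max(1, ceiling((l$cy - l$h / 2) * d[1])):floor((l$cy + l$h / 2) * d[1])
    cols <- max(1, ceiling((l$cx - l$w / 2) * d[2])):floor((l$cx + l$w / 2) * d[2])
    mean(item$image[rows, cols, ])
  }
  expect_gt(box_mean(r1), 180)
  expect_gt(box_mean(hf), 180)
})

test_that("shift-scale-rotate matches an independent rotation oracle", {
  it <- fixture_item(cx = 0.45, cy = 0.55, bw = 0.3, bh = 0.2)
  got <- pflyolo:::aug_ssr(it, shift_x = 0.05, shift_y = -0.03, scale = 1.08,
                           angle_deg = 12)
  th <- 12 * pi / 180
  rot <- function(p) {
    q <- 1.08 * c(cos(th) * (p[1] - 0.5) - sin(th) * (p[2] - 0.5),
                  sin(th) * (p[1] - 0.5) + cos(th) * (p[2] - 0.5))
    q + 0.5 + c(0.05, -0.03)
  }
  cs <- rbind(c(0.3, 0.45), c(0.6, 0.45), c(0.6, 0.65), c(0.3, 0.65))
  tc <- t(apply(cs, 1, rot))
  expect_equal(got$label$cx, mean(range(tc[, 1])), tolerance = 1e-10)
  expect_equal(got$label$cy, mean(range(tc[, 2])), tolerance = 1e-10)
  expect_equal(got$label$w, diff(range(tc[, 1])), tolerance = 1e-10)
  expect_equal(got$label$h, diff(range(tc[, 2])), tolerance = 1e-10)
  # warped image content follows the transformed label
  d <- dim(got$image)
  l <- got$label
  rows <- max(1, ceiling((l$cy - l$h / 2) * d[1])):floor((l$cy + l$h / 2) * d[1])
  cols <- max(1, ceiling((l$cx - l$w / 2) * d[2])):floor((l$cx + l$w / 2) * d[2])
  expect_gt(mean(got$image[rows, cols, ]), mean(got$image))
})

test_that("photometric transforms keep the label and stay in range", {
  set.seed(104)
  it <- fixture_item()
  for (tr in c("brightness", "hsv")) {
    out <- augment_once(it, tr)
    expect_identical(out$label, it$label)
    expect_true(all(out$image >= 0 & out$image <= 255))
    expect_false(identical(out$image, it$image))
  }
  # every augmented item still validates
  set.seed(105)
  for (i in 1:20) {
    out <- augment_once(it)
    man <- data.frame(image = "x", class_id = out$label$class_id,
                      cx = out$label$cx, cy = out$label$cy,
                      w = out$label$w, h = out$label$h)
    expect_true(validate_labels(man, nc = 60)$ok)
  }
})

test_that("split_then_augment reproduces the published dataset arithmetic", {
  sp <- split_then_augment(seq_len(6418), seed = 4)
  expect_equal(sp$counts$filtered, c(5136, 641, 641, 6418))
  expect_equal(sp$counts$augmented, c(10272, 1282, 1282, 12836))
  expect_equal(split_then_augment(1:10, seed = 1)$counts$filtered[1:3],
               c(8, 1, 1))
  expect_equal(split_then_augment(1:12, seed = 1)$counts$filtered[1:3],
               c(10, 1, 1))
  # partition property over assorted sizes and seeds
  for (n in c(3, 10, 57, 640)) for (sd in 1:2) {
    sp <- split_then_augment(seq_len(n), seed = sd)
    all_ids <- unlist(sp$filtered)
    expect_length(all_ids, n)
    expect_length(unique(all_ids), n)
    k <- floor(n / 10)
    expect_length(sp$filtered$val, k)
    expect_length(sp$filtered$test, k)
  }
  # same seed, same partition
  expect_identical(split_then_augment(1:100, seed = 9),
                   split_then_augment(1:100, seed = 9))
})

test_that("YOLO-txt label files round-trip", {
  dir <- withr::local_tempdir()
  man <- data.frame(image = c("im1", "im2"), class_id = c(3L, 59L),
                    cx = c(0.25, 0.5), cy = c(0.5, 0.75),
                    w = c(0.1, 0.3), h = c(0.2, 0.4))
  write_yolo_labels(man, dir)
  back <- read_yolo_labels(dir)
  back <- back[order(back$image), ]
  expect_equal(back$class_id, man$class_id)
  expect_equal(back$cx, man$cx, tolerance = 1e-6)
  expect_equal(back$h, man$h, tolerance = 1e-6)
})
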