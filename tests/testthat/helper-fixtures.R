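# Shared fixtures. The smoke-trained model is expensive (a few minutes of
# CPU), so it is trained once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

smoke_fixture <- function() {
  if (!is.null(.fixture_env$smoke)) return(.fixture_env$smoke)
  items <- gen_face_dataset(n_classes = 2, per_class = 20, image_size = 96,
                            seed = 5)
  model <- instantiate(build_variant("all", nc = 2), seed = 0)
  tr <- smoke_train(model, items, imgsz = 64, epochs = 150, batch_size = 8,
                    lr = 0.01, seed = 0)
  x <- pflyolo:::abind4(lapply(items, function(it)
    pflyolo:::item_to_input(it, 64)))
  gt <- pflyolo:::items_ground_truth(items, 64)
  .fixture_env$smoke <- list(items = items, model = tr$model, x = x, gt = gt)
  .fixture_env$smoke
}

# a tiny hand-built labeled item with a solid box, for augmentation tests
fixture_item <- function(h = 40, w = 60, cx = 0.3, cy = 0.2, bw = 0.2,
                         bh = 0.25) {
  img <- array(runif(h * w * 3, 0, 60), c(h, w, 3))
  rows <- max(1, round((cy - bh / 2) * h)):min(h, round((cy + bh / 2) * h))
  cols <- max(1, round((cx - bw / 2) * w)):min(w, round((cx + bw / 2) * w))
  img[rows, cols, ] <- 220
  list(image = img,
       label = list(class_id = 0L, cx = cx, cy = cy, w = bw, h = bh))
}

# brute-force average precision: enumerate confidence thresholds, take the
# monotone precision envelope, sum recall-step rectangles
ap_bruteforce <- function(conf, tp, n_gt) {
  if (n_gt == 0 || !any(tp)) return(0)
  ths <- sort(unique(conf), decreasing = TRUE)
  pr <- t(vapply(ths, function(th) {
    sel <- conf >= th
    c(p = sum(tp[sel]) / sum(sel), r = sum(tp[sel]) / n_gt)
  }, c(p = 0, r = 0)))
  env <- vapply(seq_len(nrow(pr)), function(i) max(pr[i:nrow(pr), "p"]), 0)
  # integrate P dR over the recall steps
  r_prev <- 0
  ap <- 0
  for (i in seq_len(nrow(pr))) {
    ap <- ap + (pr[i, "r"] - r_prev) * env[i]
    r_prev <- pr[i, "r"]
  }
  unname(ap)
}

# direct (quadruple-loop) 2-D convolution oracle on a (n, c, h, w) array
conv_oracle <- function(x, w_arr, bias, stride, pad, groups) {
  d <- dim(x)
  k <- dim(w_arr)[1]; cing <- dim(w_arr)[3]; cout <- dim(w_arr)[4]
  coutg <- cout / groups
  ho <- (d[3] + 2 * pad - k) %/% stride + 1
  wo <- (d[4] + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(d[1], d[2], d[3] + 2 * pad, d[4] + 2 * pad))
  xp[, , pad + seq_len(d[3]), pad + seq_len(d[4])] <- x
  y <- array(0, c(d[1], cout, ho, wo))
  for (n in seq_len(d[1])) for (co in seq_len(cout)) {
    g <- ceiling(co / coutg)
    cis <- (g - 1) * cing + seq_len(cing)
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      patch <- xp[n, cis, (i - 1) * stride + seq_len(k),
                  (j - 1) * stride + seq_len(k), drop = FALSE]
      acc <- 0
      for (ci in seq_len(cing)) for (kh in seq_len(k)) for (kw in seq_len(k))
        acc <- acc + patch[1, ci, kh, kw] * w_arr[kh, kw, ci, co]
      y[n, co, i, j] <- acc + (if (is.null(bias)) 0 else bias[co])
    }
  }
  y
}
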