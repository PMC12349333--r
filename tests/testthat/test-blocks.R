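# Building-block semantics: activations, ECA, channel shuffle, convolution
# units and the composite blocks.

test_that("eca_kernel_size follows the adaptive odd-kernel rule", {
  expect_identical(eca_kernel_size(64), 3L)
  expect_identical(eca_kernel_size(256), 5L)
  expect_identical(eca_kernel_size(16), 3L)
  expect_identical(eca_kernel_size(96), 3L)
  expect_true(all(vapply(2^(0:10), eca_kernel_size, 0L) %% 2 == 1))
  expect_true(all(vapply(2^(0:10), eca_kernel_size, 0L) >= 3))
  expect_error(eca_kernel_size(0), "channels")
})

test_that("hardswish matches its three branches and is continuous/monotone", {
  expect_equal(hardswish(-3), 0)
  expect_equal(hardswish(3), 3)
  expect_equal(hardswish(1), 1 * (1 + 3) / 6)
  expect_equal(hardswish(0), 0)
  expect_equal(hardswish(-5), 0)
  expect_equal(hardswish(7), 7)
  # continuity at the knots
  eps <- 1e-9
  expect_lt(abs(hardswish(-3 + eps) - hardswish(-3 - eps)), 1e-8)
  expect_lt(abs(hardswish(3 + eps) - hardswish(3 - eps)), 1e-8)
  # x * (x + 3) / 6 dips to -0.375 at x = -1.5; monotone from there on
  xs <- seq(-1.5, 8, by = 0.01)
  expect_true(all(diff(hardswish(xs)) >= 0))
  expect_equal(hardswish(-1.5), -0.375)
  expect_true(all(hardswish(seq(-10, 10, 0.01)) >= -0.375))
})

test_that("channel_shuffle permutes by reshape-transpose and round-trips", {
  # channels tagged by constant value so the permutation is readable
  arr <- array(0, c(1, 4, 2, 3))
  for (c in 1:4) arr[1, c, , ] <- c
  out <- channel_shuffle(arr, 2)
  expect_equal(out[1, , 1, 1], c(1, 3, 2, 4))  # [0,1,2,3] -> [0,2,1,3]
  expect_equal(channel_shuffle(arr, 1), arr)
  expect_equal(channel_shuffle(arr, 4), arr)
  # composing with the complementary group count inverts the shuffle
  arr2 <- array(rnorm(2 * 12 * 3 * 3), c(2, 12, 3, 3))
  expect_equal(channel_shuffle(channel_shuffle(arr2, 3), 4), arr2)
  # spatial content of each channel is untouched (multiset preserved)
  o2 <- channel_shuffle(arr2, 4)
  for (c in 1:12) {
    match_found <- any(vapply(1:12, function(c2)
      isTRUE(all.equal(o2[, c2, , ], arr2[, c, , ])), TRUE))
    expect_true(match_found)
  }
  expect_error(channel_shuffle(arr, 3), "divide")
})

test_that("ECA attention: shape, symmetry, bounded weights, arithmetic oracle", {
  set.seed(11)
  unit <- pflyolo:::eca_new(8)
  X <- matrix(rnorm(4 * 4 * 1 * 8), 16, 8)
  out <- pflyolo:::eca_forward(unit, X, 4, 4, 1)
  expect_identical(dim(out$Y), dim(X))
  # zero-initialized kernel: every weight is sigmoid(0) = 0.5 exactly
  expect_equal(out$Y, X * 0.5)
  # identical channels receive identical weights (away from the zero-padded
  # ends of the 1-D kernel, whose support is truncated)
  Xe <- matrix(rep(rnorm(16), 8), 16, 8)
  unit$params$w <- rnorm(unit$k)
  oute <- pflyolo:::eca_forward(unit, Xe, 4, 4, 1)
  ratios <- oute$Y / Xe
  inner <- 2:7
  expect_lt(max(ratios[, inner]) - min(ratios[, inner]), 1e-12)
  expect_true(all(ratios > 0 & ratios < 1))
  # brute-force oracle on a (1, 4, 2, 2) input with a fixed 1-D kernel
  u4 <- pflyolo:::eca_new(4)
  u4$params$w <- c(0.2, -0.4, 0.7)
  x4 <- array(rnorm(16), c(1, 4, 2, 2))
  fm <- as_fmap(x4)
  got <- pflyolo:::eca_forward(u4, fm$x, 2, 2, 1)$Y
  gap <- apply(x4[1, , , , drop = FALSE], 2, mean)
  gpad <- c(0, gap, 0)
  a <- vapply(1:4, function(c) sum(gpad[c:(c + 2)] * u4$params$w), 0)
  wgt <- 1 / (1 + exp(-a))
  want <- x4
  for (c in 1:4) want[1, c, , ] <- x4[1, c, , ] * wgt[c]
  expect_equal(fmap_array(pflyolo:::new_fmap(got, 2, 2, 1)), want,
               tolerance = 1e-12)
})

test_that("conv unit: stride arithmetic, grouped-conv oracle, parameter counts", {
  set.seed(21)
  # shape contract: k3 s2 halves the spatial size
  cu <- pflyolo:::cu_new(pflyolo:::cu_spec(3, 16, 3, 2))
  x <- array(rnorm(1 * 3 * 16 * 16), c(1, 3, 16, 16))
  fm <- as_fmap(x)
  r <- pflyolo:::cu_forward(cu, fm$x, 16, 16, 1)
  expect_equal(c(r$ho, r$wo, ncol(r$Y)), c(8, 8, 16))
  # forward equals the direct-convolution oracle (plain and grouped, s1/s2)
  for (cfg in list(list(g = 1, s = 1), list(g = 2, s = 1), list(g = 2, s = 2))) {
    sp <- pflyolo:::cu_spec(4, 6, 3, cfg$s, groups = cfg$g, act = "none",
                            bn = FALSE, bias = TRUE)
    u <- pflyolo:::cu_new(sp)
    u$params$b <- rnorm(6)
    xa <- array(rnorm(2 * 4 * 6 * 5), c(2, 4, 6, 5))
    fmx <- as_fmap(xa)
    got <- pflyolo:::cu_forward(u, fmx$x, 6, 5, 2)
    want <- conv_oracle(xa, u$params$w, u$params$b, cfg$s, 1, cfg$g)
    expect_equal(fmap_array(pflyolo:::new_fmap(got$Y, got$ho, got$wo, 2)),
                 want, tolerance = 1e-10)
  }
  # closed-form parameter counts (affine batch norm counted)
  n_params <- function(u) length(u$params$w) + length(u$params$b) +
    length(u$bn$gamma) + length(u$bn$beta) +
    (if (is.null(u$eca)) 0 else length(u$eca$params$w))
  u1 <- pflyolo:::cu_new(pflyolo:::cu_spec(32, 64, 3))
  expect_equal(n_params(u1), 18560)           # 9*32*64 + 2*64
  u2 <- pflyolo:::cu_new(pflyolo:::cu_spec(32, 64, 3, groups = 4))
  expect_equal(n_params(u2), 4736)            # 9*32*64/4 + 2*64
  u3 <- pflyolo:::cu_new(pflyolo:::cu_spec(32, 64, 3, groups = 4, eca = TRUE))
  expect_equal(n_params(u3), 4739)            # + ECA kernel of width 3
})

test_that("EHConv keeps the conv shape contract and every parameter learns", {
  set.seed(31)
  blk <- pflyolo:::block_ehconv(8, 16, groups = 4)
  X <- matrix(rnorm(10 * 10 * 2 * 8), 200, 8)
  ins <- list(pflyolo:::fm_of(X, 10, 10, 2))
  r <- pflyolo:::block_forward(blk, ins, train = TRUE, cache = TRUE)
  expect_equal(c(r$out$h, r$out$w, ncol(r$out$X)), c(5, 5, 16))
  dY <- matrix(rnorm(length(r$out$X)), nrow(r$out$X))
  bb <- pflyolo:::block_backward(r$block, r$cache, list(dX = dY))
  g <- bb$grads$cv
  for (nm in c("w", "gamma", "beta", "eca_w")) {
    expect_gt(min(abs(g[[nm]])), 0)
  }
})

test_that("SPPF/ESPPF: spatial preservation, pooling oracle, param ordering", {
  set.seed(41)
  blk <- pflyolo:::block_sppf(8, 8)
  X <- matrix(rnorm(7 * 6 * 1 * 8), 42, 8)
  r <- pflyolo:::block_forward(blk, list(pflyolo:::fm_of(X, 7, 6, 1)))
  expect_equal(c(r$out$h, r$out$w, ncol(r$out$X)), c(7, 6, 8))
  be <- pflyolo:::block_esppf(8, 8, groups = 4)
  re <- pflyolo:::block_forward(be, list(pflyolo:::fm_of(X, 7, 6, 1)))
  expect_equal(c(re$out$h, re$out$w, ncol(re$out$X)), c(7, 6, 8))
  # max-pool matches a window-max oracle
  mp <- pflyolo:::maxpool_forward(X, 7, 6, 1, k = 5)
  xa <- fmap_array(pflyolo:::new_fmap(X, 7, 6, 1))
  for (c in sample(8, 3)) for (i in sample(7, 3)) for (j in sample(6, 3)) {
    win <- xa[1, c, max(1, i - 2):min(7, i + 2), max(1, j - 2):min(6, j + 2)]
    got <- fmap_array(pflyolo:::new_fmap(mp$Y, 7, 6, 1))[1, c, i, j]
    expect_equal(got, max(win))
  }
  # grouping strictly reduces parameters at identical geometry
  np <- function(b) sum(unlist(lapply(b[c("cv1", "cv2")], function(u)
    length(u$params$w) + length(u$bn$gamma) + length(u$bn$beta))))
  expect_lt(np(pflyolo:::block_esppf(64, 64, groups = 4)),
            np(pflyolo:::block_sppf(64, 64)))
})

test_that("RC2f: contract, ladder wiring, zeroed transforms drop groups 2-4", {
  set.seed(51)
  blk <- pflyolo:::block_rc2f(16, 16, 2, 2, 1, 1)
  X <- matrix(rnorm(6 * 6 * 2 * 16), 72, 16)
  ins <- list(pflyolo:::fm_of(X, 6, 6, 2))
  r <- pflyolo:::block_forward(blk, ins)
  expect_equal(c(r$out$h, r$out$w, ncol(r$out$X)), c(6, 6, 16))
  # wiring oracle: zero the ladder transforms; the output must equal
  # eca(fuse(cbind(x1, 0, 0, 0))) computed from the stems directly
  for (nm in c("t2", "t3", "t4")) {
    blk[[nm]]$params$w[] <- 0
    blk[[nm]]$bn$gamma[] <- 0
    blk[[nm]]$bn$beta[] <- 0
  }
  rz <- pflyolo:::block_forward(blk, ins)
  s1 <- pflyolo:::cu_forward(blk$cv1, X, 6, 6, 2)
  s2 <- pflyolo:::cu_forward(blk$cv2, s1$Y, 6, 6, 2)
  x1 <- s2$Y[, 1:4, drop = FALSE]
  cat4 <- cbind(x1, matrix(0, nrow(x1), 12))
  fz <- pflyolo:::cu_forward(blk$fuse, cat4, 6, 6, 2)
  ez <- pflyolo:::eca_forward(blk$eca, fz$Y, 6, 6, 2)
  expect_equal(rz$out$X, ez$Y, tolerance = 1e-12)
})

test_that("detection heads emit 4*reg_max + nc channels per scale", {
  set.seed(61)
  ins <- lapply(c(8, 12, 16), function(ci)
    pflyolo:::fm_of(matrix(rnorm(4 * 4 * ci), 16, ci), 4, 4, 1))
  bd <- pflyolo:::block_detect(60, chs = c(8, 12, 16))
  rd <- pflyolo:::block_forward(bd, ins)
  expect_equal(vapply(rd$out, function(o) ncol(o$X), 0), rep(124, 3))
  bp <- pflyolo:::block_pfdetect(60, chs = c(8, 12, 16), width = 8,
                                 entry_groups = c(2, 2, 2), mid_groups = 4,
                                 shuffle_groups = 4)
  rp <- pflyolo:::block_forward(bp, ins)
  expect_equal(vapply(rp$out, function(o) ncol(o$X), 0), rep(124, 3))
})

test_that("backward passes agree with central finite differences", {
  set.seed(71)
  h <- 5; w <- 4; n <- 2
  for (mk in list(function() pflyolo:::block_ehconv(6, 8, groups = 2),
                  function() pflyolo:::block_rc2f(6, 8, 2, 2, 1, 1))) {
    blk <- mk()
    X <- matrix(rnorm(h * w * n * 6), h * w * n, 6)
    ins <- list(pflyolo:::fm_of(X, h, w, n))
    r <- pflyolo:::block_forward(blk, ins, train = TRUE, cache = TRUE)
    R <- matrix(rnorm(length(r$out$X)), nrow(r$out$X))
    bb <- pflyolo:::block_backward(r$block, r$cache, list(dX = R))
    eps <- 1e-5
    for (ii in sample(length(X), 6)) {
      Xp <- X; Xp[ii] <- Xp[ii] + eps
      Xm <- X; Xm[ii] <- Xm[ii] - eps
      lp <- sum(pflyolo:::block_forward(blk, list(pflyolo:::fm_of(Xp, h, w, n)),
                                        train = TRUE)$out$X * R)
      lm <- sum(pflyolo:::block_forward(blk, list(pflyolo:::fm_of(Xm, h, w, n)),
                                        train = TRUE)$out$X * R)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - bb$dins[[1]][ii]) /
                  max(1e-6, abs(num) + abs(bb$dins[[1]][ii])), 1e-5)
    }
  }
})
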