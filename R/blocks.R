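# Building blocks: plain Conv / C2f / SPPF / Detect (YOLOv8n baseline) and the
# lightweight EHConv / RC2f / ESPPF / PFDetect variants.
#
# Each block holds its trainable parameters in nested named lists; forward
# functions take the flattened feature-map matrix plus spatial metadata and
# return the output together with a cache for the backward pass.

# ---- conv unit: conv2d [+ ECA] [+ BN] + activation --------------------------

cu_spec <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                    act = "silu", bn = TRUE, bias = !bn, eca = FALSE) {
  if (cin %% groups != 0 || cout %% groups != 0)
    stop(sprintf("groups=%d must divide in (%d) and out (%d) channels",
                 groups, cin, cout), call. = FALSE)
  if (k %% 2 != 1) stop("kernel size must be odd for same padding", call. = FALSE)
  list(cin = as.integer(cin), cout = as.integer(cout), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(k %/% 2),
       groups = as.integer(groups), act = act, bn = bn, bias = bias, eca = eca)
}

cu_new <- function(spec) {
  cing <- spec$cin %/% spec$groups
  fan_in <- spec$k^2 * cing
  w <- array(stats::rnorm(spec$k^2 * cing * spec$cout, sd = sqrt(2 / fan_in)),
             dim = c(spec$k, spec$k, cing, spec$cout))
  unit <- list(spec = spec, params = list(w = w))
  if (spec$bias) unit$params$b <- rep(0, spec$cout)
  if (spec$bn) unit$bn <- bn_new(spec$cout)
  if (spec$eca) unit$eca <- eca_new(spec$cout)
  unit
}

cu_forward <- function(unit, X, h, w, n, train = FALSE, cache = FALSE) {
  sp <- unit$spec
  cv <- conv2d_forward(X, h, w, n, unit$params$w, unit$params$b,
                       sp$stride, sp$pad, sp$groups, cache = cache)
  Y <- cv$Y; ho <- cv$ho; wo <- cv$wo
  ec <- NULL
  if (sp$eca) {
    e <- eca_forward(unit$eca, Y, ho, wo, n, cache = cache)
    Y <- e$Y; ec <- e$cache
  }
  bnc <- NULL
  if (sp$bn) {
    b <- bn_forward(unit$bn, Y, train = train, cache = cache)
    Y <- b$Y
    unit$bn <- b$bn
    bnc <- b$cache
  }
  Z <- Y
  Y <- apply_act(Y, sp$act)
  res <- list(Y = Y, ho = ho, wo = wo, unit = unit)
  if (cache) res$cache <- list(conv = cv$cache, eca = ec, bn = bnc, Z = Z, n = n)
  res
}

cu_backward <- function(unit, cache, dY) {
  sp <- unit$spec
  dZ <- dY * act_grad(cache$Z, sp$act)
  grads <- list()
  if (sp$bn) {
    bb <- bn_backward(unit$bn, cache$bn, dZ)
    dZ <- bb$dX
    grads$gamma <- bb$dgamma; grads$beta <- bb$dbeta
  }
  if (sp$eca) {
    eb <- eca_backward(unit$eca, cache$eca, dZ)
    dZ <- eb$dX
    grads$eca_w <- eb$grads$w
  }
  cb <- conv2d_backward(cache$conv, unit$params$w, dZ)
  grads$w <- cb$dw
  if (sp$bias) grads$b <- cb$db
  list(dX = cb$dX, grads = grads)
}

# apply an SGD-style update to a conv unit given its grads
cu_update <- function(unit, grads, vel, lr, momentum, wd) {
  upd <- function(p, g, v) {
    v <- momentum * v + g + wd * p
    list(p = p - lr * v, v = v)
  }
  if (is.null(vel)) vel <- list()
  for (nm in names(grads)) {
    tgt <- switch(nm,
      w = unit$params$w, b = unit$params$b,
      gamma = unit$bn$gamma, beta = unit$bn$beta, eca_w = unit$eca$params$w)
    u <- upd(tgt, grads[[nm]], vel[[nm]] %||% 0)
    switch(nm,
      w = { unit$params$w <- u$p }, b = { unit$params$b <- u$p },
      gamma = { unit$bn$gamma <- u$p }, beta = { unit$bn$beta <- u$p },
      eca_w = { unit$eca$params$w <- u$p })
    vel[[nm]] <- u$v
  }
  list(unit = unit, vel = vel)
}

# ---- blocks -----------------------------------------------------------------

new_block <- function(kind, ...) {
  b <- list(kind = kind, ...)
  class(b) <- c(paste0("pfl_", kind), "pfl_block")
  b
}

# plain YOLOv8 Conv (conv + BN + SiLU); EHConv adds grouping, ECA and Hardswish
block_conv <- function(cin, cout, k = 3L, stride = 2L) {
  new_block("conv", cv = cu_new(cu_spec(cin, cout, k, stride)))
}

block_ehconv <- function(cin, cout, k = 3L, stride = 2L, groups = 4L) {
  g <- min(groups, gcd_int(cin, cout))
  new_block("ehconv",
            cv = cu_new(cu_spec(cin, cout, k, stride, groups = g,
                                act = "hardswish", eca = TRUE)))
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- a %% b; a <- b; b <- t }
  a
}

block_c2f <- function(cin, cout, n = 1L, shortcut = FALSE) {
  c <- cout %/% 2L
  bott <- lapply(seq_len(n), function(i)
    list(cv1 = cu_new(cu_spec(c, c, 3L)), cv2 = cu_new(cu_spec(c, c, 3L))))
  new_block("c2f",
            cv1 = cu_new(cu_spec(cin, 2L * c, 1L)),
            cv2 = cu_new(cu_spec((2L + n) * c, cout, 1L)),
            bott = bott, n = as.integer(n), shortcut = shortcut, c = c)
}

# RC2f: 1x1 + 3x3 grouped stems, 4-way split, residual ladder T2..T4 on the
# quarter width, 1x1 fuse, ECA. Group counts come from the calibrated config.
block_rc2f <- function(cin, cout, g_stem1 = 4L, g_stem2 = 1L, g_t = 1L,
                       g_fuse = 1L) {
  h <- as.integer(cout)
  if (h %% 4L != 0L) stop("RC2f width must be divisible by 4", call. = FALSE)
  s <- h %/% 4L
  new_block("rc2f",
            cv1 = cu_new(cu_spec(cin, h, 1L, groups = cap_groups(g_stem1, cin, h))),
            cv2 = cu_new(cu_spec(h, h, 3L, groups = cap_groups(g_stem2, h, h))),
            t2 = cu_new(cu_spec(s, s, 3L, groups = cap_groups(g_t, s, s))),
            t3 = cu_new(cu_spec(s, s, 3L, groups = cap_groups(g_t, s, s))),
            t4 = cu_new(cu_spec(s, s, 3L, groups = cap_groups(g_t, s, s))),
            fuse = cu_new(cu_spec(h, cout, 1L, groups = cap_groups(g_fuse, h, cout))),
            eca = eca_new(cout), s = s, h = h)
}

cap_groups <- function(g, cin, cout) {
  g <- min(g, gcd_int(cin, cout))
  max(1L, as.integer(g))
}

block_sppf <- function(cin, cout, pool_k = 5L) {
  c <- cin %/% 2L
  new_block("sppf",
            cv1 = cu_new(cu_spec(cin, c, 1L)),
            cv2 = cu_new(cu_spec(4L * c, cout, 1L)),
            pool_k = as.integer(pool_k), c = c)
}

block_esppf <- function(cin, cout, groups = 16L, pool_k = 5L) {
  c <- cin %/% 2L
  new_block("esppf",
            cv1 = cu_new(cu_spec(cin, c, 1L, groups = cap_groups(groups, cin, c))),
            cv2 = cu_new(cu_spec(4L * c, cout, 1L,
                                 groups = cap_groups(groups, 4L * c, cout))),
            eca = eca_new(cout), pool_k = as.integer(pool_k), c = c)
}

block_upsample <- function() new_block("upsample")
block_concat <- function() new_block("concat")

# baseline YOLOv8 decoupled head
block_detect <- function(nc, chs = c(64L, 128L, 256L), reg_max = 16L) {
  c2 <- max(16L, chs[1] %/% 4L, 4L * reg_max)
  c3 <- max(chs[1], min(nc, 100L))
  scales <- lapply(chs, function(ci) list(
    box1 = cu_new(cu_spec(ci, c2, 3L)),
    box2 = cu_new(cu_spec(c2, c2, 3L)),
    box3 = cu_new(cu_spec(c2, 4L * reg_max, 1L, bn = FALSE, bias = TRUE, act = "none")),
    cls1 = cu_new(cu_spec(ci, c3, 3L)),
    cls2 = cu_new(cu_spec(c3, c3, 3L)),
    cls3 = cu_new(cu_spec(c3, nc, 1L, bn = FALSE, bias = TRUE, act = "none"))))
  new_block("detect", scales = scales, nc = as.integer(nc),
            reg_max = as.integer(reg_max), dfl = seq(0L, reg_max - 1L))
}

# PFDetect: per-scale grouped 1x1 entry, ECA, per-scale grouped 3x3 with
# channel shuffle, then box/cls 1x1 projections SHARED across the three scales
block_pfdetect <- function(nc, chs = c(64L, 128L, 256L), width = 96L,
                           entry_groups = c(8L, 4L, 2L), mid_groups = 8L,
                           shuffle_groups = 8L, reg_max = 16L) {
  scales <- lapply(seq_along(chs), function(i) list(
    entry = cu_new(cu_spec(chs[i], width, 1L,
                           groups = cap_groups(entry_groups[i], chs[i], width))),
    eca = eca_new(width),
    mid = cu_new(cu_spec(width, width, 3L,
                         groups = cap_groups(mid_groups, width, width)))))
  new_block("pfdetect", scales = scales,
            proj_box = cu_new(cu_spec(width, 4L * reg_max, 1L, bn = FALSE,
                                      bias = TRUE, act = "none")),
            proj_cls = cu_new(cu_spec(width, nc, 1L, bn = FALSE,
                                      bias = TRUE, act = "none")),
            nc = as.integer(nc), width = as.integer(width),
            shuffle_groups = as.integer(shuffle_groups),
            reg_max = as.integer(reg_max), dfl = seq(0L, reg_max - 1L))
}
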