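# Forward and backward passes through blocks. A block input/output is a list
# (X = matrix rows x channels, h, w, n); detection heads return one such list
# per scale. Backward functions return gradients in a tree mirroring the
# block's parameter-bearing components.

block_forward <- function(block, ins, train = FALSE, cache = FALSE) {
  UseMethod("block_forward")
}

fm_of <- function(X, h, w, n) list(X = X, h = h, w = w, n = n)

#' @export
block_forward.pfl_conv <- function(block, ins, train = FALSE, cache = FALSE) {
  a <- ins[[1]]
  r <- cu_forward(block$cv, a$X, a$h, a$w, a$n, train, cache)
  block$cv <- r$unit
  list(out = fm_of(r$Y, r$ho, r$wo, a$n), block = block, cache = r$cache)
}

#' @export
block_forward.pfl_ehconv <- block_forward.pfl_conv

#' @export
block_forward.pfl_c2f <- function(block, ins, train = FALSE, cache = FALSE) {
  a <- ins[[1]]
  r1 <- cu_forward(block$cv1, a$X, a$h, a$w, a$n, train, cache)
  block$cv1 <- r1$unit
  c <- block$c
  ys <- list(r1$Y[, seq_len(c), drop = FALSE],
             r1$Y[, c + seq_len(c), drop = FALSE])
  bcaches <- vector("list", block$n)
  for (i in seq_len(block$n)) {
    cur <- ys[[i + 1L]]
    z1 <- cu_forward(block$bott[[i]]$cv1, cur, r1$ho, r1$wo, a$n, train, cache)
    block$bott[[i]]$cv1 <- z1$unit
    z2 <- cu_forward(block$bott[[i]]$cv2, z1$Y, r1$ho, r1$wo, a$n, train, cache)
    block$bott[[i]]$cv2 <- z2$unit
    out <- if (block$shortcut) cur + z2$Y else z2$Y
    ys[[i + 2L]] <- out
    bcaches[[i]] <- list(c1 = z1$cache, c2 = z2$cache)
  }
  r2 <- cu_forward(block$cv2, do.call(cbind, ys), r1$ho, r1$wo, a$n, train, cache)
  block$cv2 <- r2$unit
  ch <- if (cache) list(c1 = r1$cache, c2 = r2$cache, bott = bcaches) else NULL
  list(out = fm_of(r2$Y, r2$ho, r2$wo, a$n), block = block, cache = ch)
}

block_backward <- function(block, cache, dout) UseMethod("block_backward")

#' @export
block_backward.pfl_conv <- function(block, cache, dout) {
  b <- cu_backward(block$cv, cache, dout$dX)
  list(dins = list(b$dX), grads = list(cv = b$grads))
}

#' @export
block_backward.pfl_ehconv <- block_backward.pfl_conv

#' @export
block_backward.pfl_c2f <- function(block, cache, dout) {
  b2 <- cu_backward(block$cv2, cache$c2, dout$dX)
  c <- block$c
  nb <- block$n
  dys <- lapply(seq_len(nb + 2L), function(i)
    b2$dX[, (i - 1L) * c + seq_len(c), drop = FALSE])
  gb <- vector("list", nb)
  for (i in rev(seq_len(nb))) {
    dcur <- dys[[i + 2L]]
    z2b <- cu_backward(block$bott[[i]]$cv2, cache$bott[[i]]$c2, dcur)
    z1b <- cu_backward(block$bott[[i]]$cv1, cache$bott[[i]]$c1, z2b$dX)
    din <- z1b$dX
    if (block$shortcut) din <- din + dcur
    dys[[i + 1L]] <- dys[[i + 1L]] + din
    gb[[i]] <- list(cv1 = z1b$grads, cv2 = z2b$grads)
  }
  b1 <- cu_backward(block$cv1, cache$c1, cbind(dys[[1L]], dys[[2L]]))
  list(dins = list(b1$dX),
       grads = list(cv1 = b1$grads, cv2 = b2$grads, bott = gb))
}

#' @export
block_forward.pfl_rc2f <- function(block, ins, train = FALSE, cache = FALSE) {
  a <- ins[[1]]
  r1 <- cu_forward(block$cv1, a$X, a$h, a$w, a$n, train, cache)
  block$cv1 <- r1$unit
  r2 <- cu_forward(block$cv2, r1$Y, r1$ho, r1$wo, a$n, train, cache)
  block$cv2 <- r2$unit
  s <- block$s
  xs <- lapply(1:4, function(i) r2$Y[, (i - 1L) * s + seq_len(s), drop = FALSE])
  ys <- vector("list", 4L)
  tc <- vector("list", 4L)
  ys[[1L]] <- xs[[1L]]
  for (i in 2:4) {
    u <- block[[paste0("t", i)]]
    r <- cu_forward(u, xs[[i]] + ys[[i - 1L]], r2$ho, r2$wo, a$n, train, cache)
    block[[paste0("t", i)]] <- r$unit
    ys[[i]] <- r$Y
    tc[[i]] <- r$cache
  }
  rf <- cu_forward(block$fuse, do.call(cbind, ys), r2$ho, r2$wo, a$n, train, cache)
  block$fuse <- rf$unit
  re <- eca_forward(block$eca, rf$Y, rf$ho, rf$wo, a$n, cache)
  ch <- if (cache) list(c1 = r1$cache, c2 = r2$cache, t = tc, f = rf$cache,
                        e = re$cache) else NULL
  list(out = fm_of(re$Y, rf$ho, rf$wo, a$n), block = block, cache = ch)
}

#' @export
block_backward.pfl_rc2f <- function(block, cache, dout) {
  eb <- eca_backward(block$eca, cache$e, dout$dX)
  fb <- cu_backward(block$fuse, cache$f, eb$dX)
  s <- block$s
  dys <- lapply(1:4, function(i) fb$dX[, (i - 1L) * s + seq_len(s), drop = FALSE])
  dxs <- vector("list", 4L)
  gt <- vector("list", 4L)
  for (i in 4:2) {
    tb <- cu_backward(block[[paste0("t", i)]], cache$t[[i]], dys[[i]])
    dxs[[i]] <- tb$dX
    dys[[i - 1L]] <- dys[[i - 1L]] + tb$dX
    gt[[i]] <- tb$grads
  }
  dxs[[1L]] <- dys[[1L]]
  b2 <- cu_backward(block$cv2, cache$c2, do.call(cbind, dxs))
  b1 <- cu_backward(block$cv1, cache$c1, b2$dX)
  list(dins = list(b1$dX),
       grads = list(cv1 = b1$grads, cv2 = b2$grads,
                    t2 = gt[[2L]], t3 = gt[[3L]], t4 = gt[[4L]],
                    fuse = fb$grads, eca = list(w = eb$grads$w)))
}

sppf_chain_forward <- function(block, a, train, cache) {
  r1 <- cu_forward(block$cv1, a$X, a$h, a$w, a$n, train, cache)
  block$cv1 <- r1$unit
  p1 <- maxpool_forward(r1$Y, r1$ho, r1$wo, a$n, block$pool_k, cache)
  p2 <- maxpool_forward(p1$Y, r1$ho, r1$wo, a$n, block$pool_k, cache)
  p3 <- maxpool_forward(p2$Y, r1$ho, r1$wo, a$n, block$pool_k, cache)
  cat4 <- cbind(r1$Y, p1$Y, p2$Y, p3$Y)
  r2 <- cu_forward(block$cv2, cat4, r1$ho, r1$wo, a$n, train, cache)
  block$cv2 <- r2$unit
  list(block = block, Y = r2$Y, ho = r2$ho, wo = r2$wo,
       cache = if (cache) list(c1 = r1$cache, p = list(p1$cache, p2$cache,
                                                       p3$cache), c2 = r2$cache))
}

sppf_chain_backward <- function(block, cache, dY) {
  b2 <- cu_backward(block$cv2, cache$c2, dY)
  c <- block$c
  dparts <- lapply(1:4, function(i) b2$dX[, (i - 1L) * c + seq_len(c), drop = FALSE])
  d3 <- maxpool_backward(cache$p[[3L]], dparts[[4L]])$dX
  d2 <- maxpool_backward(cache$p[[2L]], dparts[[3L]] + d3)$dX
  d1 <- maxpool_backward(cache$p[[1L]], dparts[[2L]] + d2)$dX
  b1 <- cu_backward(block$cv1, cache$c1, dparts[[1L]] + d1)
  list(dX = b1$dX, g1 = b1$grads, g2 = b2$grads)
}

#' @export
block_forward.pfl_sppf <- function(block, ins, train = FALSE, cache = FALSE) {
  a <- ins[[1]]
  r <- sppf_chain_forward(block, a, train, cache)
  list(out = fm_of(r$Y, r$ho, r$wo, a$n), block = r$block, cache = r$cache)
}

#' @export
block_backward.pfl_sppf <- function(block, cache, dout) {
  b <- sppf_chain_backward(block, cache, dout$dX)
  list(dins = list(b$dX), grads = list(cv1 = b$g1, cv2 = b$g2))
}

#' @export
block_forward.pfl_esppf <- function(block, ins, train = FALSE, cache = FALSE) {
  a <- ins[[1]]
  r <- sppf_chain_forward(block, a, train, cache)
  re <- eca_forward(r$block$eca, r$Y, r$ho, r$wo, a$n, cache)
  ch <- if (cache) c(r$cache, list(e = re$cache)) else NULL
  list(out = fm_of(re$Y, r$ho, r$wo, a$n), block = r$block, cache = ch)
}

#' @export
block_backward.pfl_esppf <- function(block, cache, dout) {
  eb <- eca_backward(block$eca, cache$e, dout$dX)
  b <- sppf_chain_backward(block, cache, eb$dX)
  list(dins = list(b$dX),
       grads = list(cv1 = b$g1, cv2 = b$g2, eca = list(w = eb$grads$w)))
}

#' @export
block_forward.pfl_upsample <- function(block, ins, train = FALSE, cache = FALSE) {
  a <- ins[[1]]
  u <- upsample2_forward(a$X, a$h, a$w, a$n)
  list(out = fm_of(u$Y, u$ho, u$wo, a$n), block = block,
       cache = if (cache) list(rowmap = u$rowmap, nrow_in = nrow(a$X)))
}

#' @export
block_backward.pfl_upsample <- function(block, cache, dout) {
  list(dins = list(upsample2_backward(cache$rowmap, dout$dX, cache$nrow_in)$dX),
       grads = NULL)
}

#' @export
block_forward.pfl_concat <- function(block, ins, train = FALSE, cache = FALSE) {
  hs <- vapply(ins, `[[`, 1L, "h")
  if (length(unique(hs)) != 1L)
    stop("concat inputs must share spatial size", call. = FALSE)
  X <- do.call(cbind, lapply(ins, `[[`, "X"))
  a <- ins[[1]]
  list(out = fm_of(X, a$h, a$w, a$n), block = block,
       cache = if (cache) list(widths = vapply(ins, function(i) ncol(i$X), 1L)))
}

#' @export
block_backward.pfl_concat <- function(block, cache, dout) {
  w <- cache$widths
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1L) + 1L)
  dins <- lapply(seq_along(w), function(i)
    dout$dX[, starts[i]:ends[i], drop = FALSE])
  list(dins = dins, grads = NULL)
}

# ---- detection heads --------------------------------------------------------

#' @export
block_forward.pfl_detect <- function(block, ins, train = FALSE, cache = FALSE) {
  outs <- vector("list", 3L)
  caches <- vector("list", 3L)
  for (i in 1:3) {
    a <- ins[[i]]
    sc <- block$scales[[i]]
    b1 <- cu_forward(sc$box1, a$X, a$h, a$w, a$n, train, cache); sc$box1 <- b1$unit
    b2 <- cu_forward(sc$box2, b1$Y, a$h, a$w, a$n, train, cache); sc$box2 <- b2$unit
    b3 <- cu_forward(sc$box3, b2$Y, a$h, a$w, a$n, train, cache); sc$box3 <- b3$unit
    c1 <- cu_forward(sc$cls1, a$X, a$h, a$w, a$n, train, cache); sc$cls1 <- c1$unit
    c2 <- cu_forward(sc$cls2, c1$Y, a$h, a$w, a$n, train, cache); sc$cls2 <- c2$unit
    c3 <- cu_forward(sc$cls3, c2$Y, a$h, a$w, a$n, train, cache); sc$cls3 <- c3$unit
    block$scales[[i]] <- sc
    outs[[i]] <- fm_of(cbind(b3$Y, c3$Y), a$h, a$w, a$n)
    caches[[i]] <- if (cache) list(b1 = b1$cache, b2 = b2$cache, b3 = b3$cache,
                                   c1 = c1$cache, c2 = c2$cache, c3 = c3$cache)
  }
  list(out = outs, block = block, cache = caches)
}

#' @export
block_backward.pfl_detect <- function(block, cache, dout) {
  dins <- vector("list", 3L)
  gs <- vector("list", 3L)
  rb <- 4L * block$reg_max
  for (i in 1:3) {
    dX <- dout[[i]]$dX
    sc <- block$scales[[i]]
    db <- dX[, seq_len(rb), drop = FALSE]
    dc <- dX[, rb + seq_len(block$nc), drop = FALSE]
    b3 <- cu_backward(sc$box3, cache[[i]]$b3, db)
    b2 <- cu_backward(sc$box2, cache[[i]]$b2, b3$dX)
    b1 <- cu_backward(sc$box1, cache[[i]]$b1, b2$dX)
    c3 <- cu_backward(sc$cls3, cache[[i]]$c3, dc)
    c2 <- cu_backward(sc$cls2, cache[[i]]$c2, c3$dX)
    c1 <- cu_backward(sc$cls1, cache[[i]]$c1, c2$dX)
    dins[[i]] <- b1$dX + c1$dX
    gs[[i]] <- list(box1 = b1$grads, box2 = b2$grads, box3 = b3$grads,
                    cls1 = c1$grads, cls2 = c2$grads, cls3 = c3$grads)
  }
  list(dins = dins, grads = list(scales = gs))
}

#' @export
block_forward.pfl_pfdetect <- function(block, ins, train = FALSE, cache = FALSE) {
  outs <- vector("list", 3L)
  caches <- vector("list", 3L)
  perm <- shuffle_perm(block$width, block$shuffle_groups)
  for (i in 1:3) {
    a <- ins[[i]]
    sc <- block$scales[[i]]
    e <- cu_forward(sc$entry, a$X, a$h, a$w, a$n, train, cache); sc$entry <- e$unit
    at <- eca_forward(sc$eca, e$Y, a$h, a$w, a$n, cache)
    m <- cu_forward(sc$mid, at$Y, a$h, a$w, a$n, train, cache); sc$mid <- m$unit
    Z <- m$Y[, perm, drop = FALSE]
    pb <- cu_forward(block$proj_box, Z, a$h, a$w, a$n, train, cache)
    block$proj_box <- pb$unit
    pc <- cu_forward(block$proj_cls, Z, a$h, a$w, a$n, train, cache)
    block$proj_cls <- pc$unit
    block$scales[[i]] <- sc
    outs[[i]] <- fm_of(cbind(pb$Y, pc$Y), a$h, a$w, a$n)
    caches[[i]] <- if (cache) list(e = e$cache, at = at$cache, m = m$cache,
                                   pb = pb$cache, pc = pc$cache)
  }
  list(out = outs, block = block, cache = caches)
}

#' @export
block_backward.pfl_pfdetect <- function(block, cache, dout) {
  dins <- vector("list", 3L)
  gs <- vector("list", 3L)
  rb <- 4L * block$reg_max
  perm <- shuffle_perm(block$width, block$shuffle_groups)
  inv <- order(perm)
  gbox <- NULL; gcls <- NULL
  for (i in 1:3) {
    dX <- dout[[i]]$dX
    sc <- block$scales[[i]]
    db <- dX[, seq_len(rb), drop = FALSE]
    dc <- dX[, rb + seq_len(block$nc), drop = FALSE]
    pbb <- cu_backward(block$proj_box, cache[[i]]$pb, db)
    pcb <- cu_backward(block$proj_cls, cache[[i]]$pc, dc)
    gbox <- add_grads(gbox, pbb$grads)
    gcls <- add_grads(gcls, pcb$grads)
    dZ <- pbb$dX + pcb$dX
    dM <- dZ[, inv, drop = FALSE]
    mb <- cu_backward(sc$mid, cache[[i]]$m, dM)
    ab <- eca_backward(sc$eca, cache[[i]]$at, mb$dX)
    eb <- cu_backward(sc$entry, cache[[i]]$e, ab$dX)
    dins[[i]] <- eb$dX
    gs[[i]] <- list(entry = eb$grads, eca = list(w = ab$grads$w), mid = mb$grads)
  }
  list(dins = dins,
       grads = list(scales = gs, proj_box = gbox, proj_cls = gcls))
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
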