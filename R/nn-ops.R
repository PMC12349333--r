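# Low-level tensor operations on flattened feature maps.
#
# All ops work on the matrix form (rows = batch*height*width, cols = channels)
# and return both the output and, when `cache = TRUE`, whatever the backward
# pass needs. Convolution uses im2col gathers + BLAS matrix products; grouped
# convolution loops over groups.

# padded-row bookkeeping: maps each row of the padded plane to a source row
pad_rows <- function(h, w, n, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  # inner rows (1-based) inside the padded (hp, wp) plane for sample 1
  hi <- rep(pad + seq_len(h), times = w)
  wi <- rep(pad + seq_len(w), each = h)
  inner1 <- (wi - 1L) * hp + hi
  off <- rep((seq_len(n) - 1L) * hp * wp, each = h * w)
  list(inner = rep(inner1, n) + off, hp = hp, wp = wp)
}

# im2col padded-row indices: (k*k) x (ho*wo*n)
im2col_rows <- function(h, w, n, k, stride, pad) {
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  kh <- rep(seq_len(k), times = k)
  kw <- rep(seq_len(k), each = k)
  offk <- (kw - 1L) * hp + kh                                  # k^2
  oh <- rep(seq_len(ho), times = wo)
  ow <- rep(seq_len(wo), each = ho)
  offo1 <- (ow - 1L) * stride * hp + (oh - 1L) * stride        # ho*wo
  offn <- rep((seq_len(n) - 1L) * hp * wp, each = ho * wo)
  R <- matrix(offk, nrow = k * k, ncol = ho * wo * n) +
       matrix(rep(offo1, n) + offn, nrow = k * k, ncol = ho * wo * n, byrow = TRUE)
  list(R = R, ho = ho, wo = wo)
}

conv2d_forward <- function(X, h, w, n, wt, bias, stride, pad, groups,
                           cache = FALSE) {
  k <- dim(wt)[1]
  cing <- dim(wt)[3]
  cout <- dim(wt)[4]
  C <- ncol(X)
  stopifnot(C == cing * groups, cout %% groups == 0)
  coutg <- cout %/% groups
  pr <- pad_rows(h, w, n, pad)
  Xp <- matrix(0, pr$hp * pr$wp * n, C)
  Xp[pr$inner, ] <- X
  ic <- im2col_rows(h, w, n, k, stride, pad)
  S <- ic$ho * ic$wo * n
  Rv <- as.vector(ic$R)
  Y <- matrix(0, S, cout)
  Ms <- if (cache) vector("list", groups) else NULL
  for (g in seq_len(groups)) {
    cols <- (g - 1L) * cing + seq_len(cing)
    Xs <- Xp[Rv, cols, drop = FALSE]                 # (k2*S) x cing
    M <- matrix(aperm(array(Xs, c(k * k, S, cing)), c(1, 3, 2)),
                nrow = k * k * cing, ncol = S)
    Wg <- matrix(wt[, , , (g - 1L) * coutg + seq_len(coutg)], ncol = coutg)
    Y[, (g - 1L) * coutg + seq_len(coutg)] <- crossprod(M, Wg)
    if (cache) Ms[[g]] <- M
  }
  if (!is.null(bias)) Y <- sweep(Y, 2L, bias, "+")
  out <- list(Y = Y, ho = ic$ho, wo = ic$wo)
  if (cache)
    out$cache <- list(Ms = Ms, R = ic$R, pr = pr, h = h, w = w, n = n,
                      k = k, cing = cing, coutg = coutg, groups = groups,
                      stride = stride, pad = pad, C = C, S = S)
  out
}

conv2d_backward <- function(cache, wt, dY) {
  k <- cache$k; cing <- cache$cing; coutg <- cache$coutg
  groups <- cache$groups; S <- cache$S; C <- cache$C
  dwt <- array(0, dim(wt))
  dXp <- matrix(0, cache$pr$hp * cache$pr$wp * cache$n, C)
  R <- cache$R
  for (g in seq_len(groups)) {
    co <- (g - 1L) * coutg + seq_len(coutg)
    cols <- (g - 1L) * cing + seq_len(cing)
    dYg <- dY[, co, drop = FALSE]                    # S x coutg
    M <- cache$Ms[[g]]                               # (k2*cing) x S
    dwt[, , , co] <- array(M %*% dYg, c(k, k, cing, coutg))
    Wg <- matrix(wt[, , , co], ncol = coutg)
    dM <- Wg %*% t(dYg)                              # (k2*cing) x S
    dMa <- array(dM, c(k * k, cing, S))
    for (o in seq_len(k * k)) {
      rows_o <- R[o, ]
      # stride >= 1 makes rows_o collision-free within one kernel offset
      dXp[rows_o, cols] <- dXp[rows_o, cols] + t(dMa[o, , , drop = TRUE])
    }
  }
  dX <- dXp[cache$pr$inner, , drop = FALSE]
  db <- colSums(dY)
  list(dX = dX, dw = dwt, db = db)
}

# ---- batch normalization ----------------------------------------------------

bn_new <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       rmean = rep(0, C), rvar = rep(1, C))
}

bn_forward <- function(bn, X, train = FALSE, eps = 1e-5, momentum = 0.03,
                       cache = FALSE) {
  if (train) {
    m <- colMeans(X)
    v <- colMeans(X * X) - m * m
    v[v < 0] <- 0
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * m
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * v
  } else {
    m <- bn$rmean; v <- bn$rvar
  }
  istd <- 1 / sqrt(v + eps)
  Xh <- sweep(sweep(X, 2L, m, "-"), 2L, istd, "*")
  Y <- sweep(sweep(Xh, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  res <- list(Y = Y, bn = bn)
  if (cache) res$cache <- list(Xh = Xh, istd = istd, train = train)
  res
}

bn_backward <- function(bn, cache, dY) {
  Xh <- cache$Xh; istd <- cache$istd
  m <- nrow(dY)
  dgamma <- colSums(dY * Xh)
  dbeta <- colSums(dY)
  if (cache$train) {
    t1 <- sweep(dY, 2L, dbeta / m, "-")
    t2 <- sweep(Xh, 2L, dgamma / m, "*")
    dX <- sweep(t1 - t2, 2L, bn$gamma * istd, "*")
  } else {
    dX <- sweep(dY, 2L, bn$gamma * istd, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- max pooling (k x k, stride 1, same padding) ----------------------------

maxpool_forward <- function(X, h, w, n, k = 5L, cache = FALSE) {
  pad <- (k - 1L) %/% 2L
  pr <- pad_rows(h, w, n, pad)
  C <- ncol(X)
  Xp <- matrix(-Inf, pr$hp * pr$wp * n, C)
  Xp[pr$inner, ] <- X
  ic <- im2col_rows(h, w, n, k, 1L, pad)
  S <- ic$ho * ic$wo * n
  Y <- matrix(-Inf, S, C)
  IDX <- matrix(0L, S, C)
  for (o in seq_len(k * k)) {
    rows_o <- ic$R[o, ]
    cand <- Xp[rows_o, , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    IDX[upd] <- matrix(rows_o, S, C)[upd]
  }
  res <- list(Y = Y, ho = ic$ho, wo = ic$wo)
  if (cache) res$cache <- list(IDX = IDX, pr = pr, n = n, C = C)
  res
}

maxpool_backward <- function(cache, dY) {
  np <- cache$pr$hp * cache$pr$wp * cache$n
  dXp <- matrix(0, np, cache$C)
  for (cc in seq_len(cache$C)) {
    rs <- rowsum(dY[, cc], cache$IDX[, cc])
    dXp[as.integer(rownames(rs)), cc] <- dXp[as.integer(rownames(rs)), cc] + rs
  }
  list(dX = dXp[cache$pr$inner, , drop = FALSE])
}

# ---- nearest-neighbour 2x upsample ------------------------------------------

upsample2_rowmap <- function(h, w, n) {
  h2 <- 2L * h; w2 <- 2L * w
  hi <- rep(rep(seq_len(h), each = 2L), times = w2)
  wi <- rep(rep(seq_len(w), each = 2L), each = h2)
  base <- (wi - 1L) * h + hi
  off <- rep((seq_len(n) - 1L) * h * w, each = h2 * w2)
  rep(base, n) + off
}

upsample2_forward <- function(X, h, w, n) {
  rm <- upsample2_rowmap(h, w, n)
  list(Y = X[rm, , drop = FALSE], ho = 2L * h, wo = 2L * w, rowmap = rm)
}

upsample2_backward <- function(rowmap, dY, nrow_in) {
  rs <- rowsum(dY, rowmap)
  dX <- matrix(0, nrow_in, ncol(dY))
  dX[as.integer(rownames(rs)), ] <- rs
  list(dX = dX)
}
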