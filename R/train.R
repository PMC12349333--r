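# Smoke-scale training. The full production recipe of the YOLOv8 family
# (task-aligned assignment, CIoU + DFL losses, mosaic augmentation, EMA) is
# deliberately out of scope here; this trainer uses a minimal center-cell
# assignment with binary cross-entropy on the class map and a distribution-
# focal loss on the box sides -- enough to overfit small synthetic datasets
# and exercise every block's forward/backward path end to end.

# targets: data.frame(image [1..n], class [0-based], cx, cy, w, h) normalized.
# Each target is assigned to the single scale whose stride best matches the
# box size (about 3 cells across), at the cell containing the box center.
detect_loss <- function(raw, targets, nc, strides, reg_max = 16L,
                        lambda_cls = 1, lambda_box = 1, pos_weight = 4) {
  draw <- vector("list", 3L)
  loss_cls <- 0; loss_box <- 0
  imgsz <- raw[[1]]$h * strides[1]
  tscale <- vapply(seq_len(nrow(targets)), function(ti) {
    sz <- max(targets$w[ti], targets$h[ti]) * imgsz
    which.min(abs(log2(pmax(sz, 1) / strides) - log2(3)))
  }, 0L)
  for (si in 1:3) {
    fm <- raw[[si]]
    X <- fm$X; h <- fm$h; w <- fm$w; n <- fm$n
    S <- nrow(X)
    Tcls <- matrix(0, S, nc)
    dX <- matrix(0, S, ncol(X))
    sel <- which(tscale == si)
    for (ti in sel) {
      tg <- targets[ti, ]
      wi <- min(max(floor(tg$cx * w) + 1L, 1L), w)
      hi <- min(max(floor(tg$cy * h) + 1L, 1L), h)
      row <- (tg$image - 1L) * h * w + (wi - 1L) * h + hi
      Tcls[row, tg$class + 1L] <- 1
      # ltrb distances from the anchor point, in cell units
      ax <- wi - 0.5; ay <- hi - 0.5
      d <- c(ax - (tg$cx - tg$w / 2) * w, ay - (tg$cy - tg$h / 2) * h,
             (tg$cx + tg$w / 2) * w - ax, (tg$cy + tg$h / 2) * h - ay)
      d <- pmin(pmax(d, 0), reg_max - 1 - 1e-3)
      for (s in 1:4) {
        cols <- (s - 1L) * reg_max + seq_len(reg_max)
        logits <- X[row, cols]
        sm <- exp(logits - max(logits)); sm <- sm / sum(sm)
        lo <- floor(d[s]); hiw <- d[s] - lo
        tdist <- numeric(reg_max)
        tdist[lo + 1L] <- 1 - hiw
        if (lo + 2L <= reg_max) tdist[lo + 2L] <- hiw
        loss_box <- loss_box - sum(tdist * log(sm + 1e-12))
        dX[row, cols] <- dX[row, cols] +
          lambda_box * (sm - tdist) / (max(1, nrow(targets)) * 4)
      }
    }
    P <- stats::plogis(X[, 4L * reg_max + seq_len(nc), drop = FALSE])
    W <- 1 + (pos_weight - 1) * Tcls   # re-balance the rare positive cells
    loss_cls <- loss_cls - sum(W * (Tcls * log(P + 1e-12) +
                               (1 - Tcls) * log(1 - P + 1e-12))) / S
    dX[, 4L * reg_max + seq_len(nc)] <- lambda_cls * W * (P - Tcls) / S
    draw[[si]] <- dX
  }
  list(loss = lambda_cls * loss_cls + lambda_box * loss_box / max(1, nrow(targets)),
       draw = draw)
}

# SGD with momentum over the nested block/grad trees (weight decay on conv
# kernels only, as is conventional)
sgd_step <- function(layers, grads, vel, lr, momentum, wd) {
  step <- function(obj, g, v) {
    if (is.null(g)) return(list(o = obj, v = v))
    if (is_cu(obj)) {
      if (is.null(v)) v <- list()
      for (nm in names(g)) {
        cur <- switch(nm, w = obj$params$w, b = obj$params$b,
                      gamma = obj$bn$gamma, beta = obj$bn$beta,
                      eca_w = obj$eca$params$w)
        vv <- momentum * (v[[nm]] %||% 0) + g[[nm]] +
          (if (nm == "w") wd * cur else 0)
        cur <- cur - lr * vv
        switch(nm, w = { obj$params$w <- cur }, b = { obj$params$b <- cur },
               gamma = { obj$bn$gamma <- cur }, beta = { obj$bn$beta <- cur },
               eca_w = { obj$eca$params$w <- cur })
        v[[nm]] <- vv
      }
      return(list(o = obj, v = v))
    }
    if (is_eca(obj)) {
      vv <- momentum * (v$w %||% 0) + g$w
      obj$params$w <- obj$params$w - lr * vv
      return(list(o = obj, v = list(w = vv)))
    }
    if (is.list(obj) && is.list(g)) {
      if (is.null(v)) v <- vector("list", length(g))
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (k in keys) {
        if (is.null(obj[[k]]) || is.null(g[[k]])) next
        r <- step(obj[[k]], g[[k]], v[[k]])
        obj[[k]] <- r$o; v[[k]] <- r$v
      }
      return(list(o = obj, v = v))
    }
    list(o = obj, v = v)
  }
  for (li in seq_along(layers)) {
    if (is.null(grads[[li]])) next
    r <- step(layers[[li]], grads[[li]], vel[[li]])
    layers[[li]] <- r$o
    vel[[li]] <- r$v
  }
  list(layers = layers, vel = vel)
}

#' Smoke-train a detection model on an in-memory dataset
#'
#' Minimal SGD training loop intended for overfitting small synthetic
#' datasets (pipeline verification, not a reproduction of the full-scale
#' training recipe). Hyperparameter defaults mirror the published setup
#' (SGD, momentum 0.937, lr 0.01, weight decay 0.0005) at smoke scale.
#'
#' @param model a `pfl_model`.
#' @param items list of dataset items (as from [gen_face_dataset()]): each a
#'   list with `image` (H x W x 3 array, 0-255) and `label`
#'   (`class_id`, `cx`, `cy`, `w`, `h`).
#' @param imgsz training resolution (divisible by 32).
#' @param epochs passes over the data.
#' @param batch_size minibatch size.
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch loss.
#' @return list with the trained `model` and the per-step `losses`.
#' @export
smoke_train <- function(model, items, imgsz = 64L, epochs = 10L,
                        batch_size = 8L, lr = 0.01, momentum = 0.937,
                        weight_decay = 5e-4, seed = 0L, verbose = FALSE) {
  set.seed(seed)
  xs <- lapply(items, function(it) item_to_input(it, imgsz))
  labs <- do.call(rbind, lapply(seq_along(items), function(i) {
    l <- items[[i]]$label
    data.frame(item = i, class = l$class_id, cx = l$cx, cy = l$cy,
               w = l$w, h = l$h)
  }))
  vel <- vector("list", length(model$layers))
  losses <- numeric()
  for (ep in seq_len(epochs)) {
    # hold the base rate for the first 60% of epochs, then decay to 10%
    frac <- (ep - 1) / max(1, epochs - 1)
    lr_ep <- if (frac < 0.6) lr else lr * (1 - 0.9 * (frac - 0.6) / 0.4)
    ord <- sample(length(items))
    bs <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (b in bs) {
      x <- abind4(xs[b])
      tg <- labs[labs$item %in% b, , drop = FALSE]
      tg$image <- match(tg$item, b)
      fw <- model_forward(model, x, train = TRUE, cache = TRUE)
      model <- fw$model
      ls <- detect_loss(fw$raw, tg, model$nc, model$strides)
      bw <- model_backward(model, fw, ls$draw)
      up <- sgd_step(model$layers, bw$grads, vel, lr_ep, momentum, weight_decay)
      model$layers <- up$layers
      vel <- up$vel
      losses <- c(losses, ls$loss)
    }
    if (verbose)
      message(sprintf("epoch %d  loss %.4f", ep, mean(utils::tail(losses, length(bs)))))
  }
  list(model = model, losses = losses)
}

# resize an item image to the training resolution and normalize to [0, 1];
# returns (1, 3, imgsz, imgsz)
item_to_input <- function(item, imgsz) {
  img <- item$image / 255
  h <- dim(img)[1]; w <- dim(img)[2]
  ri <- pmin(pmax(round((seq_len(imgsz) - 0.5) * h / imgsz + 0.5), 1L), h)
  ci <- pmin(pmax(round((seq_len(imgsz) - 0.5) * w / imgsz + 0.5), 1L), w)
  out <- array(0, c(1, 3, imgsz, imgsz))
  for (ch in 1:3) out[1, ch, , ] <- img[ri, ci, ch]
  out
}

abind4 <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(length(lst), d[2], d[3], d[4]))
  for (i in seq_along(lst)) out[i, , , ] <- lst[[i]][1, , , ]
  out
}

# ground truth of a dataset at a given resolution, in evaluation format
items_ground_truth <- function(items, imgsz) {
  do.call(rbind, lapply(seq_along(items), function(i) {
    l <- items[[i]]$label
    data.frame(image = i, class = l$class_id,
               x1 = (l$cx - l$w / 2) * imgsz, y1 = (l$cy - l$h / 2) * imgsz,
               x2 = (l$cx + l$w / 2) * imgsz, y2 = (l$cy + l$h / 2) * imgsz)
  }))
}
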