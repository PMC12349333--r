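# Declarative 23-layer graphs (indices 0-22) for the YOLOv8n baseline, the
# PFL-YOLO network and every ablation variant, plus instantiation and the
# full-network forward/backward passes.

bspec <- function(index, kind, from, args = list()) {
  list(index = as.integer(index), kind = kind, from = as.integer(from),
       args = args)
}

#' Build the 23-layer YOLOv8n baseline graph
#'
#' Standard YOLOv8n wiring at depth multiple 0.33 / width multiple 0.25:
#' backbone layers 0-9 (channel plan 16/32/64/128/256, C2f repeats 1/2/2/1),
#' FPN/PAN neck layers 10-21, decoupled detection head at layer 22 fed at
#' strides 8/16/32.
#'
#' @param nc number of identity classes (60 for the sheep face task).
#' @return a `pfl_graph` object.
#' @export
build_baseline <- function(nc = 60L) {
  stopifnot(nc >= 1)
  blocks <- list(
    bspec(0, "conv", -1, list(cin = 3, cout = 16)),
    bspec(1, "conv", -1, list(cin = 16, cout = 32)),
    bspec(2, "c2f", -1, list(cin = 32, cout = 32, n = 1, shortcut = TRUE)),
    bspec(3, "conv", -1, list(cin = 32, cout = 64)),
    bspec(4, "c2f", -1, list(cin = 64, cout = 64, n = 2, shortcut = TRUE)),
    bspec(5, "conv", -1, list(cin = 64, cout = 128)),
    bspec(6, "c2f", -1, list(cin = 128, cout = 128, n = 2, shortcut = TRUE)),
    bspec(7, "conv", -1, list(cin = 128, cout = 256)),
    bspec(8, "c2f", -1, list(cin = 256, cout = 256, n = 1, shortcut = TRUE)),
    bspec(9, "sppf", -1, list(cin = 256, cout = 256)),
    bspec(10, "upsample", -1, list()),
    bspec(11, "concat", c(-1, 6), list()),
    bspec(12, "c2f", -1, list(cin = 384, cout = 128, n = 1, shortcut = FALSE)),
    bspec(13, "upsample", -1, list()),
    bspec(14, "concat", c(-1, 4), list()),
    bspec(15, "c2f", -1, list(cin = 192, cout = 64, n = 1, shortcut = FALSE)),
    bspec(16, "conv", -1, list(cin = 64, cout = 64)),
    bspec(17, "concat", c(-1, 12), list()),
    bspec(18, "c2f", -1, list(cin = 192, cout = 128, n = 1, shortcut = FALSE)),
    bspec(19, "conv", -1, list(cin = 128, cout = 128)),
    bspec(20, "concat", c(-1, 9), list()),
    bspec(21, "c2f", -1, list(cin = 384, cout = 256, n = 1, shortcut = FALSE)),
    bspec(22, "detect", c(15, 18, 21), list(nc = nc, chs = c(64, 128, 256)))
  )
  g <- list(blocks = blocks, nc = as.integer(nc), strides = c(8L, 16L, 32L),
            flags = c(esppf = FALSE, ehconv = FALSE, rc2f = FALSE,
                      pfdetect = FALSE))
  class(g) <- "pfl_graph"
  g
}

#' Build an ablation variant graph
#'
#' Substitutes the lightweight blocks into the baseline according to four
#' flags: `esppf` replaces layer 9, `ehconv` replaces the plain Conv layers
#' (0, 1, 3, 5, 7 in the backbone; 16, 19 in the neck), `rc2f` replaces every
#' C2f layer (2, 4, 6, 8, 12, 15, 18, 21), `pfdetect` replaces the head at
#' layer 22. All-false flags give the baseline; all-true gives PFL-YOLO.
#'
#' @param flags named logical vector (or list) with entries `esppf`,
#'   `ehconv`, `rc2f`, `pfdetect`; missing entries default to FALSE.
#' @param nc class count.
#' @param cfg block configuration, by default the calibrated
#'   [pfl_default_config()].
#' @return a `pfl_graph` object.
#' @export
build_variant <- function(flags = character(), nc = 60L,
                          cfg = pfl_default_config()) {
  fl <- c(esppf = FALSE, ehconv = FALSE, rc2f = FALSE, pfdetect = FALSE)
  if (is.character(flags)) {
    if (length(flags)) {
      if (identical(flags, "all")) flags <- names(fl)
      stopifnot(all(flags %in% names(fl)))
      fl[flags] <- TRUE
    }
  } else {
    flags <- vapply(as.list(flags), isTRUE, logical(1))
    fl[names(flags)] <- flags
  }
  g <- build_baseline(nc)
  if (fl[["ehconv"]]) {
    for (i in c(0, 1, 3, 5, 7, 16, 19)) {
      b <- g$blocks[[i + 1L]]
      b$kind <- "ehconv"
      b$args$groups <- unname(cfg$ehconv$groups[[as.character(i)]])
      g$blocks[[i + 1L]] <- b
    }
  }
  if (fl[["rc2f"]]) {
    for (i in c(2, 4, 6, 8, 12, 15, 18, 21)) {
      b <- g$blocks[[i + 1L]]
      b$kind <- "rc2f"
      co <- b$args$cout
      b$args <- list(cin = b$args$cin, cout = co,
                     g_stem1 = cfg$rc2f$g_stem1,
                     g_stem2 = cfg$rc2f$g_stem2(co),
                     g_t = cfg$rc2f$g_t(co),
                     g_fuse = cfg$rc2f$g_fuse)
      g$blocks[[i + 1L]] <- b
    }
  }
  if (fl[["esppf"]]) {
    b <- g$blocks[[10L]]
    b$kind <- "esppf"
    b$args$groups <- cfg$esppf$groups
    g$blocks[[10L]] <- b
  }
  if (fl[["pfdetect"]]) {
    b <- g$blocks[[23L]]
    b$kind <- "pfdetect"
    b$args <- c(list(nc = nc, chs = c(64, 128, 256)), cfg$pfdetect)
    g$blocks[[23L]] <- b
  }
  g$flags <- fl
  g
}

#' @export
print.pfl_graph <- function(x, ...) {
  kinds <- vapply(x$blocks, `[[`, "", "kind")
  cat(sprintf("<pfl_graph: %d layers, nc=%d, kinds: %s>\n",
              length(x$blocks), x$nc, paste(unique(kinds), collapse = ", ")))
  invisible(x)
}

# construct the block object (with weights) for one bspec
make_block <- function(b) {
  a <- b$args
  switch(b$kind,
    conv = block_conv(a$cin, a$cout),
    ehconv = block_ehconv(a$cin, a$cout, groups = a$groups),
    c2f = block_c2f(a$cin, a$cout, a$n, a$shortcut),
    rc2f = block_rc2f(a$cin, a$cout, a$g_stem1, a$g_stem2, a$g_t, a$g_fuse),
    sppf = block_sppf(a$cin, a$cout),
    esppf = block_esppf(a$cin, a$cout, groups = a$groups),
    upsample = block_upsample(),
    concat = block_concat(),
    detect = block_detect(a$nc, a$chs),
    pfdetect = block_pfdetect(a$nc, a$chs, width = a$width,
                              entry_groups = a$entry_groups,
                              mid_groups = a$mid_groups,
                              shuffle_groups = a$shuffle_groups),
    stop("unknown block kind: ", b$kind))
}

#' Instantiate a graph with weights
#'
#' Creates every block's weight arrays (Kaiming-style initialization for
#' convolutions, unit/zero batch-norm affine, zero-initialized ECA kernels)
#' reproducibly from `seed`.
#'
#' @param graph a `pfl_graph`.
#' @param seed integer RNG seed.
#' @return a `pfl_model`.
#' @export
instantiate <- function(graph, seed = 0L) {
  stopifnot(inherits(graph, "pfl_graph"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  layers <- lapply(graph$blocks, make_block)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  m <- list(graph = graph, layers = layers, nc = graph$nc,
            strides = graph$strides)
  class(m) <- "pfl_model"
  m
}

#' @export
print.pfl_model <- function(x, ...) {
  cat(sprintf("<pfl_model: %d layers, nc=%d, %s parameters>\n",
              length(x$layers), x$nc,
              format(introspect_params(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass through an assembled network
#'
#' @param model a `pfl_model`.
#' @param x input batch: 4-D array (batch, channel, height, width) with
#'   spatial size divisible by 32, or an `fmap`.
#' @param train logical; use batch statistics in batch norm and update the
#'   running estimates.
#' @param cache logical; retain everything needed for a backward pass.
#' @return list with `raw` (per-scale head outputs as internal feature maps),
#'   `outs` (per-layer outputs), `caches` (if requested) and the possibly
#'   updated `model` (batch-norm running statistics).
#' @export
model_forward <- function(model, x, train = FALSE, cache = FALSE) {
  fm <- if (inherits(x, "fmap")) x else as_fmap(x)
  if (fm$h %% 32 != 0 || fm$w %% 32 != 0)
    stop("input spatial size must be divisible by 32", call. = FALSE)
  nl <- length(model$layers)
  outs <- vector("list", nl)
  caches <- vector("list", nl)
  input <- fm_of(fm$x, fm$h, fm$w, fm$n)
  for (li in seq_len(nl)) {
    b <- model$graph$blocks[[li]]
    ins <- lapply(b$from, function(f)
      if (f < 0) { if (li == 1L) input else outs[[li - 1L]] } else outs[[f + 1L]])
    r <- block_forward(model$layers[[li]], ins, train = train, cache = cache)
    model$layers[[li]] <- r$block
    outs[[li]] <- r$out
    if (cache) caches[[li]] <- r$cache
  }
  list(raw = outs[[nl]], outs = outs, caches = if (cache) caches,
       model = model)
}

# Backward pass: `draw` is a list of three gradient matrices matching the
# per-scale raw head outputs. Accumulates gradients for every layer down to
# (and excluding) `stop_at` (0-based layer index; NULL = all the way down).
# Returns per-layer grads and the gradient wrt each layer's output.
model_backward <- function(model, fw, draw, stop_at = -1L) {
  nl <- length(model$layers)
  douts <- vector("list", nl)
  grads <- vector("list", nl)
  douts[[nl]] <- lapply(draw, function(d) list(dX = d))
  if (is.null(stop_at)) stop_at <- -1L
  for (li in nl:1) {
    bi <- li - 1L                       # 0-based layer index
    if (bi <= stop_at) next             # gradient wrt this output is the goal
    if (is.null(douts[[li]])) next
    b <- model$graph$blocks[[li]]
    bb <- block_backward(model$layers[[li]], fw$caches[[li]], douts[[li]])
    if (!is.null(bb$grads)) grads[[li]] <- bb$grads
    src <- ifelse(b$from < 0L, bi - 1L, b$from)
    for (k in seq_along(src)) {
      si <- src[k]
      if (si < 0L) next                 # gradient wrt the image: discarded
      sl <- si + 1L
      if (is.null(douts[[sl]])) douts[[sl]] <- list(dX = bb$dins[[k]])
      else douts[[sl]]$dX <- douts[[sl]]$dX + bb$dins[[k]]
    }
  }
  list(grads = grads, douts = douts)
}
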