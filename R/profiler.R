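# Parameter and FLOP accounting.
#
# Counting conventions (chosen to reproduce the published budgets exactly;
# see the methods vignette):
#   * fused counting (default): batch norm folded into the convolution bias,
#     i.e. each BN convolution contributes k^2*Cin*Cout/g + Cout; this is the
#     convention under which the published per-layer table was printed.
#     Unfused counting (fused = FALSE) counts the BN affine pair (2*Cout).
#     Running statistics are never counted.
#   * FLOPs = 2 x multiply-accumulates, convolutions (including the fixed DFL
#     projection and the 1-D ECA kernel) only; pooling, upsampling, concat
#     and activations count as zero.

# spatial divisor of every layer output relative to the input size
layer_divisors <- function(graph) {
  nl <- length(graph$blocks)
  div <- numeric(nl)
  for (li in seq_len(nl)) {
    b <- graph$blocks[[li]]
    src <- if (b$from[1] < 0) li - 1L else b$from[1] + 1L
    prev <- if (src < 1L) 1 else div[src]
    div[li] <- switch(b$kind,
      conv = , ehconv = prev * 2,
      upsample = prev / 2,
      detect = , pfdetect = NA,       # multi-scale, handled separately
      prev)
  }
  div
}

# one data frame row per counted unit
inv_row <- function(layer, unit, type, cin, cout, k, groups = 1L, bn = TRUE,
                    bias = FALSE, div = 1, fmult = 1, pmult = 1) {
  data.frame(layer = layer, unit = unit, type = type, cin = cin, cout = cout,
             k = k, groups = groups, bn = bn, bias = bias, div = div,
             fmult = fmult, pmult = pmult)
}

conv_inventory <- function(graph) {
  div <- layer_divisors(graph)
  rows <- list()
  emit <- function(...) rows[[length(rows) + 1L]] <<- inv_row(...)
  for (li in seq_along(graph$blocks)) {
    b <- graph$blocks[[li]]
    a <- b$args
    i <- b$index
    d <- div[li]
    switch(b$kind,
      conv = emit(i, "cv", "conv", a$cin, a$cout, 3, div = d),
      ehconv = {
        g <- cap_groups(a$groups, a$cin, a$cout)
        emit(i, "cv", "conv", a$cin, a$cout, 3, g, div = d)
        emit(i, "eca", "eca", a$cout, 1, eca_kernel_size(a$cout), div = d)
      },
      c2f = {
        cc <- a$cout %/% 2
        emit(i, "cv1", "conv", a$cin, 2 * cc, 1, div = d)
        for (j in seq_len(a$n)) {
          emit(i, paste0("b", j, ".cv1"), "conv", cc, cc, 3, div = d)
          emit(i, paste0("b", j, ".cv2"), "conv", cc, cc, 3, div = d)
        }
        emit(i, "cv2", "conv", (2 + a$n) * cc, a$cout, 1, div = d)
      },
      rc2f = {
        h <- a$cout; s <- h %/% 4
        emit(i, "cv1", "conv", a$cin, h, 1, cap_groups(a$g_stem1, a$cin, h), div = d)
        emit(i, "cv2", "conv", h, h, 3, cap_groups(a$g_stem2, h, h), div = d)
        for (j in 2:4)
          emit(i, paste0("t", j), "conv", s, s, 3, cap_groups(a$g_t, s, s), div = d)
        emit(i, "fuse", "conv", h, a$cout, 1, cap_groups(a$g_fuse, h, a$cout), div = d)
        emit(i, "eca", "eca", a$cout, 1, eca_kernel_size(a$cout), div = d)
      },
      sppf = {
        cc <- a$cin %/% 2
        emit(i, "cv1", "conv", a$cin, cc, 1, div = d)
        emit(i, "cv2", "conv", 4 * cc, a$cout, 1, div = d)
      },
      esppf = {
        cc <- a$cin %/% 2
        emit(i, "cv1", "conv", a$cin, cc, 1, cap_groups(a$groups, a$cin, cc), div = d)
        emit(i, "cv2", "conv", 4 * cc, a$cout, 1,
             cap_groups(a$groups, 4 * cc, a$cout), div = d)
        emit(i, "eca", "eca", a$cout, 1, eca_kernel_size(a$cout), div = d)
      },
      upsample = NULL,
      concat = NULL,
      detect = {
        reg <- 16L
        c2 <- max(16, a$chs[1] %/% 4, 4 * reg)
        c3 <- max(a$chs[1], min(a$nc, 100))
        for (si in 1:3) {
          ci <- a$chs[si]; ds <- graph$strides[si]
          pfx <- paste0("s", si, ".")
          emit(i, paste0(pfx, "box1"), "conv", ci, c2, 3, div = ds)
          emit(i, paste0(pfx, "box2"), "conv", c2, c2, 3, div = ds)
          emit(i, paste0(pfx, "box3"), "conv", c2, 4 * reg, 1, bn = FALSE,
               bias = TRUE, div = ds)
          emit(i, paste0(pfx, "cls1"), "conv", ci, c3, 3, div = ds)
          emit(i, paste0(pfx, "cls2"), "conv", c3, c3, 3, div = ds)
          emit(i, paste0(pfx, "cls3"), "conv", c3, a$nc, 1, bn = FALSE,
               bias = TRUE, div = ds)
          emit(i, paste0(pfx, "dfl"), "conv", reg, 1, 1, bn = FALSE,
               div = ds, fmult = 4, pmult = if (si == 1) 1 else 0)
        }
      },
      pfdetect = {
        reg <- 16L
        wdt <- a$width
        for (si in 1:3) {
          ci <- a$chs[si]; ds <- graph$strides[si]
          pfx <- paste0("s", si, ".")
          emit(i, paste0(pfx, "entry"), "conv", ci, wdt, 1,
               cap_groups(a$entry_groups[si], ci, wdt), div = ds)
          emit(i, paste0(pfx, "eca"), "eca", wdt, 1, eca_kernel_size(wdt), div = ds)
          emit(i, paste0(pfx, "mid"), "conv", wdt, wdt, 3,
               cap_groups(a$mid_groups, wdt, wdt), div = ds)
          # projections shared across scales: parameters counted once
          emit(i, paste0(pfx, "proj_box"), "conv", wdt, 4 * reg, 1, bn = FALSE,
               bias = TRUE, div = ds, pmult = if (si == 1) 1 else 0)
          emit(i, paste0(pfx, "proj_cls"), "conv", wdt, a$nc, 1, bn = FALSE,
               bias = TRUE, div = ds, pmult = if (si == 1) 1 else 0)
          emit(i, paste0(pfx, "dfl"), "conv", reg, 1, 1, bn = FALSE,
               div = ds, fmult = 4, pmult = if (si == 1) 1 else 0)
        }
      })
  }
  do.call(rbind, rows)
}

unit_params <- function(inv, fused = TRUE) {
  w <- ifelse(inv$type == "eca", inv$k,
              inv$k^2 * inv$cin * inv$cout / inv$groups)
  bnv <- if (fused) inv$cout else 2 * inv$cout
  extra <- ifelse(inv$type == "eca", 0,
                  ifelse(inv$bn, bnv, ifelse(inv$bias, inv$cout, 0)))
  (w + extra) * inv$pmult
}

unit_flops <- function(inv, input_size) {
  hw2 <- (input_size / inv$div)^2
  ifelse(inv$type == "eca", 2 * inv$k * inv$cin,
         2 * (inv$k^2 * inv$cin * inv$cout / inv$groups) * hw2 * inv$fmult)
}

#' Count trainable parameters per layer
#'
#' @param graph a `pfl_graph` (from [build_baseline()] or [build_variant()]).
#' @param fused logical; `TRUE` (default) folds batch norm into the conv bias
#'   (the convention of the published per-layer budgets), `FALSE` counts the
#'   affine pair.
#' @return data frame with one row per layer: `index`, `kind`, `params`,
#'   plus a `total` attribute.
#' @export
count_params <- function(graph, fused = TRUE) {
  if (length(graph$blocks) == 0L) {
    out <- data.frame(index = integer(), kind = character(), params = numeric())
    attr(out, "total") <- 0
    return(out)
  }
  inv <- conv_inventory(graph)
  p <- unit_params(inv, fused)
  agg <- rowsum(p, inv$layer)
  kinds <- vapply(graph$blocks, `[[`, "", "kind")
  idx <- vapply(graph$blocks, `[[`, 0L, "index")
  out <- data.frame(index = idx, kind = kinds,
                    params = as.vector(agg[match(idx, as.integer(rownames(agg)))]))
  out$params[is.na(out$params)] <- 0
  attr(out, "total") <- sum(out$params)
  out
}

#' Count FLOPs per layer at a given input size
#'
#' FLOPs are two per multiply-accumulate, convolutions only (including the
#' fixed distribution-focal projection and ECA's 1-D kernel); pooling,
#' upsampling, concatenation and activations are free under this convention.
#'
#' @param graph a `pfl_graph`.
#' @param input_size input resolution in pixels (square, divisible by 32).
#' @return data frame with `index`, `kind`, `flops`; `total` attribute.
#' @export
count_flops <- function(graph, input_size = 640) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32", call. = FALSE)
  inv <- conv_inventory(graph)
  f <- unit_flops(inv, input_size)
  agg <- rowsum(f, inv$layer)
  kinds <- vapply(graph$blocks, `[[`, "", "kind")
  idx <- vapply(graph$blocks, `[[`, 0L, "index")
  out <- data.frame(index = idx, kind = kinds,
                    flops = as.vector(agg[match(idx, as.integer(rownames(agg)))]))
  out$flops[is.na(out$flops)] <- 0
  attr(out, "total") <- sum(out$flops)
  out
}

#' Serialized model size estimate
#'
#' `params * bytes-per-value / 1e6` plus a fixed serialization overhead
#' (default 0.1 MB for checkpoint metadata).
#'
#' @param graph a `pfl_graph`, or a bare parameter count.
#' @param precision `"fp16"` or `"fp32"`.
#' @param overhead_mb fixed overhead constant in MB.
#' @return size in MB.
#' @export
size_estimate <- function(graph, precision = c("fp16", "fp32"),
                          overhead_mb = 0.1) {
  precision <- match.arg(precision)
  n <- if (inherits(graph, "pfl_graph")) attr(count_params(graph), "total")
       else as.numeric(graph)
  bytes <- if (precision == "fp16") 2 else 4
  n * bytes / 1e6 + overhead_mb
}

#' Full profile report
#'
#' @inheritParams count_flops
#' @param fused counting convention for parameters, see [count_params()].
#' @return a `pfl_profile`: per-layer rows and totals (params, flops,
#'   fp16/fp32 size estimates).
#' @export
profile_graph <- function(graph, input_size = 640, fused = TRUE) {
  p <- count_params(graph, fused)
  f <- count_flops(graph, input_size)
  rows <- data.frame(index = p$index, kind = p$kind, params = p$params,
                     flops = f$flops)
  rep <- list(rows = rows,
              totals = list(params = sum(rows$params),
                            flops = sum(rows$flops),
                            size_mb_fp16 = size_estimate(sum(rows$params), "fp16"),
                            size_mb_fp32 = size_estimate(sum(rows$params), "fp32")),
              input_size = input_size, fused = fused)
  class(rep) <- "pfl_profile"
  rep
}

#' @export
print.pfl_profile <- function(x, ...) {
  cat(sprintf("<profile at %dpx: %s params (%.2f M), %.3f GFLOPs, %.1f MB fp16>\n",
              x$input_size, format(x$totals$params, big.mark = ","),
              x$totals$params / 1e6, x$totals$flops / 1e9, x$totals$size_mb_fp16))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Compare a profile against a reference budget table
#'
#' @param report a `pfl_profile` or its `rows` data frame.
#' @param reference data frame with columns `index` and any of `params`,
#'   `flops`.
#' @param tol relative tolerance beyond which a layer is flagged.
#' @return data frame of per-layer absolute and relative deviations with a
#'   logical `flagged` column.
#' @export
diff_against_reference <- function(report, reference, tol = 0.005) {
  rows <- if (inherits(report, "pfl_profile")) report$rows else report
  if (!all(reference$index %in% rows$index))
    stop("reference indexes layers absent from the report", call. = FALSE)
  m <- merge(rows, reference, by = "index", suffixes = c("", ".ref"))
  out <- data.frame(index = m$index)
  for (col in intersect(c("params", "flops"), names(reference))) {
    ref <- m[[paste0(col, ".ref")]]
    dev <- m[[col]] - ref
    out[[paste0(col, "_abs_dev")]] <- dev
    out[[paste0(col, "_rel_dev")]] <- ifelse(ref == 0, ifelse(dev == 0, 0, Inf),
                                             dev / ref)
  }
  rel <- as.matrix(out[, grep("_rel_dev$", names(out)), drop = FALSE])
  out$flagged <- apply(abs(rel) > tol, 1, any)
  out
}

#' Published budget table
#'
#' The printed parameter/FLOP/model-size budgets for the baseline, every
#' ablation variant and the two detection heads, shipped as a plain-text
#' fixture and used by tests and the acceptance script.
#'
#' @return data frame with columns `id`, `metric`, `value`.
#' @export
reference_budgets <- function() {
  utils::read.csv(system.file("extdata", "reference_budgets.csv",
                              package = "pflyolo"), stringsAsFactors = FALSE)
}

# count parameters by walking the instantiated weight arrays -- used as the
# independent cross-check against the closed-form counter
introspect_params <- function(model, trainable_only = FALSE) {
  n <- 0
  walk_unit <- function(u) {
    cnt <- length(u$params$w) + length(u$params$b)
    if (!is.null(u$bn)) cnt <- cnt + length(u$bn$gamma) + length(u$bn$beta)
    if (!is.null(u$eca)) cnt <- cnt + length(u$eca$params$w)
    cnt
  }
  for (bl in model$layers) {
    for (nm in names(bl)) {
      el <- bl[[nm]]
      if (is_cu(el)) n <- n + walk_unit(el)
      else if (is_eca(el)) n <- n + length(el$params$w)
      else if (nm %in% c("bott", "scales"))
        for (sub in el) for (u in sub)
          n <- n + (if (is_cu(u)) walk_unit(u) else if (is_eca(u)) length(u$params$w) else 0)
    }
    if (!trainable_only && !is.null(bl$dfl)) n <- n + length(bl$dfl)
  }
  as.integer(n)
}

is_cu <- function(x) is.list(x) && !is.null(x$spec) && !is.null(x$params$w)
is_eca <- function(x) is.list(x) && is.null(x$spec) && !is.null(x$k) &&
  !is.null(x$params$w) && is.null(x$bn)
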