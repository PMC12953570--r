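# Enhanced multi-scale bidirectional feature pyramid (EM-BFPN): learnable
# nonnegative-weight fusion at every junction of a top-down + bottom-up pass,
# followed by cross-stage multi-kernel depthwise enhancement whose receptive
# fields grow with pyramid depth ({1,3,5} at P3, {3,5,7} at P4, {5,7,9} at P5).

# Weighted fusion op: out = sum(relu(w_i) F_i) / (sum(relu(w_j)) + eps).
op_affm <- function(features, wpar, ctx, eps = 1e-4) {
  n <- length(features)
  if (n < 1L) stop("adaptive fusion needs at least one input feature")
  d <- dim(features[[1L]]$v)
  for (f in features) if (!identical(dim(f$v), d)) stop("fused features must share one shape")
  a <- pmax(wpar$v, 0)
  D <- sum(a) + eps
  yv <- array(0, d)
  for (i in seq_len(n)) if (a[i] != 0) yv <- yv + a[i] * features[[i]]$v
  yv <- yv / D
  add_flops(ctx, 2 * n * prod(d))
  out <- tnode(yv)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dw <- numeric(n)
    for (i in seq_len(n)) {
      accum_grad(features[[i]], gy * (a[i] / D))
      if (wpar$v[i] > 0) dw[i] <- sum(gy * (features[[i]]$v - yv)) / D
    }
    accum_grad(wpar, dw)
  })
  out
}

#' Adaptive feature fusion (AFFM)
#'
#' Weighted sum of same-shape feature maps with learnable scalar weights
#' passed through ReLU (so no feature can contribute negatively) and
#' normalised with a small epsilon guard:
#' \deqn{F = \frac{\sum_i \max(w_i, 0)\, F_i}{\sum_j \max(w_j, 0) + 10^{-4}}}
#'
#' @param features list of arrays `(B, C, H, W)`, all the same shape
#' @param weights raw numeric weights, one per feature
#' @param eps normalisation guard, default `1e-4`
#' @return fused array
#' @export
affm_fuse <- function(features, weights, eps = 1e-4) {
  if (length(features) != length(weights)) stop("one raw weight per input feature")
  if (length(features) < 1L) stop("adaptive fusion needs at least one input feature")
  lapply(features, check_feature_map)
  nodes <- lapply(features, tnode)
  op_affm(nodes, param_tensor(as.numeric(weights)), new_ctx(), eps = eps)$v
}

affm_module <- function(n) {
  m <- new_module("affm")
  m$pars <- list(w = param_tensor(rep(1, n)))   # uniform, eps-discounted start
  m$fwd <- function(self, xs, ctx) op_affm(xs, self$pars$w, ctx)
  m
}

#' Parallel receptive-field fusion unit (PRFFM)
#'
#' One depthwise convolution per (odd) kernel size, each followed by batch
#' normalisation and ReLU; all branches preserve the input shape (stride 1)
#' or halve it together (stride 2). Depthwise means output channel `c`
#' depends only on input channel `c`.
#'
#' @param channels feature channels
#' @param kernel_set odd positive kernel sizes, e.g. `c(1, 3, 5)`
#' @param stride 1 or 2
#' @return a module; its forward pass returns a *list* of branch outputs
#' @export
prffm_unit <- function(channels, kernel_set = c(1L, 3L, 5L), stride = 1L) {
  if (any(kernel_set %% 2L != 1L)) stop("kernel sizes must be odd")
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  m <- new_module("prffm")
  m$ks <- as.integer(kernel_set); m$stride <- as.integer(stride)
  for (i in seq_along(kernel_set)) {
    u <- new_module("dw_bn_relu")
    k <- as.integer(kernel_set[i])
    u$k <- k; u$stride <- m$stride
    u$pars <- list(w = param_tensor(init_uniform(c(channels, k, k), k * k)))
    u$sub <- list(bn = bn_module(channels))
    u$fwd <- function(self, x, ctx)
      op_relu(op_bn(op_dwconv(x, self$pars$w, NULL, self$stride, self$k %/% 2L, ctx),
                    self$sub$bn, ctx), ctx)
    m$sub[[paste0("b", i)]] <- u
  }
  m$fwd <- function(self, x, ctx)
    lapply(seq_along(self$ks), function(i) forward_sub(self$sub[[paste0("b", i)]], x, ctx))
  m
}

#' Dynamic scale-adaptive residual block (DSARB)
#'
#' Pointwise channel expansion, parallel multi-kernel depthwise branches
#' (summed), channel shuffle, pointwise projection; a residual connection is
#' added when `stride = 1` (identity when widths match, a 1x1 projection
#' otherwise). `stride = 2` halves the spatial dimensions.
#'
#' @param in_channels,out_channels block widths
#' @param kernel_set odd kernel sizes for the parallel branches
#' @param expansion pointwise expansion factor
#' @param stride 1 or 2
#' @param shuffle_groups channel-shuffle group count
#' @return a module
#' @export
dsarb_block <- function(in_channels, out_channels, kernel_set = c(1L, 3L, 5L),
                        expansion = 2L, stride = 1L, shuffle_groups = 4L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  ce <- as.integer(in_channels * expansion)
  if (ce %% shuffle_groups != 0L) stop("expanded width must divide by shuffle groups")
  m <- new_module("dsarb")
  m$stride <- as.integer(stride); m$g <- as.integer(shuffle_groups)
  m$identity_res <- stride == 1L && in_channels == out_channels
  m$sub <- list(
    expand = conv_unit(in_channels, ce, 1L),
    branches = prffm_unit(ce, kernel_set, stride),
    proj = conv_unit(ce, out_channels, 1L, act = FALSE)
  )
  if (stride == 1L && !m$identity_res)
    m$sub$res <- conv_unit(in_channels, out_channels, 1L, act = FALSE)
  m$fwd <- function(self, x, ctx) {
    y <- forward_sub(self$sub$expand, x, ctx)
    bs <- forward_sub(self$sub$branches, y, ctx)
    agg <- bs[[1L]]
    for (i in seq_along(bs)[-1L]) agg <- op_add(agg, bs[[i]], ctx)
    agg <- op_permute_ch(agg, shuffle_perm(dim(agg$v)[2L], self$g), ctx)
    out <- forward_sub(self$sub$proj, agg, ctx)
    if (self$stride == 1L) {
      res <- if (self$identity_res) x else forward_sub(self$sub$res, x, ctx)
      out <- op_add(out, res, ctx)
    }
    out
  }
  m
}

#' Multi-scale convolution module (MSCM)
#'
#' Cross-stage-partial wrapper around cascaded [dsarb_block()]s: two 1x1
#' entry paths each carrying `in_channels * e / 2` channels, `n_blocks`
#' DSARBs plus a 1x1 transform on the second path, concatenation, and a 1x1
#' exit convolution to the output width.
#'
#' @param in_channels,out_channels block widths
#' @param kernel_set odd kernel sizes
#' @param e cross-stage expansion coefficient (`in_channels * e / 2` must be
#'   a positive integer)
#' @param n_blocks cascaded DSARB count (0 = plain two-path bottleneck)
#' @param expansion DSARB inner expansion
#' @return a module
#' @export
mscm_block <- function(in_channels, out_channels, kernel_set = c(1L, 3L, 5L),
                       e = 0.5, n_blocks = 1L, expansion = 2L) {
  ch <- in_channels * e / 2
  if (ch != round(ch) || ch < 1) stop("in_channels * e / 2 must be a positive integer")
  ch <- as.integer(ch)
  m <- new_module("mscm")
  m$n <- as.integer(n_blocks)
  m$sub <- list(
    path1 = conv_unit(in_channels, ch, 1L),
    path2 = conv_unit(in_channels, ch, 1L),
    phi2 = conv_unit(ch, ch, 1L),
    exit = conv_unit(2L * ch, out_channels, 1L)
  )
  for (i in seq_len(n_blocks))
    m$sub[[paste0("d", i)]] <- dsarb_block(ch, ch, kernel_set, expansion, 1L,
                                           shuffle_groups = gcd_pow2(ch * expansion))
  m$fwd <- function(self, x, ctx) {
    a <- forward_sub(self$sub$path1, x, ctx)
    b <- forward_sub(self$sub$path2, x, ctx)
    for (i in seq_len(self$n)) b <- forward_sub(self$sub[[paste0("d", i)]], b, ctx)
    b <- forward_sub(self$sub$phi2, b, ctx)
    forward_sub(self$sub$exit, op_concat_ch(list(a, b), ctx), ctx)
  }
  m
}

# largest power-of-two group count (<= 4) dividing C
gcd_pow2 <- function(C) {
  g <- 4L
  while (g > 1L && C %% g != 0L) g <- g %/% 2L
  g
}

#' Bidirectional multi-scale fusion neck (EM-BFPN)
#'
#' Unifies P3/P4/P5 channels with 1x1 convolutions, runs a top-down pass
#' (upsample, two-input adaptive fusion, MSCM) and a bottom-up pass
#' (stride-2 3x3 downsample, three-input fusion at P4, MSCM), returning
#' enhanced P3/P4/P5. Kernel sets grow with depth: `{1,3,5}` at P3, `{3,5,7}`
#' at P4, `{5,7,9}` at P5. Upsampling uses nearest-neighbour interpolation,
#' or [scau_block()]s when `use_scau` is set.
#'
#' @param in_channels integer vector: incoming P3/P4/P5 widths
#' @param width unified neck width
#' @param e,n_blocks,expansion MSCM settings
#' @param use_scau replace interpolation upsamplers with SCAU blocks?
#' @param scau_shift,scau_groups SCAU settings
#' @return a module; forward takes and returns a list `(p3, p4, p5)`
#' @export
embfpn_neck <- function(in_channels, width = 128L, e = 0.5, n_blocks = 1L,
                        expansion = 2L, use_scau = FALSE,
                        scau_shift = 1L, scau_groups = 4L) {
  m <- new_module("embfpn")
  m$width <- as.integer(width)
  m$use_scau <- use_scau
  ksets <- list(p3 = c(1L, 3L, 5L), p4 = c(3L, 5L, 7L), p5 = c(5L, 7L, 9L))
  m$sub <- list(
    in3 = conv_unit(in_channels[1L], width, 1L),
    in4 = conv_unit(in_channels[2L], width, 1L),
    in5 = conv_unit(in_channels[3L], width, 1L),
    fuse_td4 = affm_module(2L), fuse_td3 = affm_module(2L),
    fuse_bu4 = affm_module(3L), fuse_bu5 = affm_module(2L),
    mscm_td4 = mscm_block(width, width, ksets$p4, e, n_blocks, expansion),
    mscm_p3 = mscm_block(width, width, ksets$p3, e, n_blocks, expansion),
    mscm_bu4 = mscm_block(width, width, ksets$p4, e, n_blocks, expansion),
    mscm_p5 = mscm_block(width, width, ksets$p5, e, n_blocks, expansion),
    down34 = conv_unit(width, width, 3L, s = 2L),
    down45 = conv_unit(width, width, 3L, s = 2L)
  )
  if (use_scau) {
    m$sub$up54 <- scau_block(width, width, shift = scau_shift, groups = scau_groups)
    m$sub$up43 <- scau_block(width, width, shift = scau_shift, groups = scau_groups)
  }
  m$fwd <- function(self, xs, ctx) {
    d3 <- dim(xs$p3$v); d4 <- dim(xs$p4$v); d5 <- dim(xs$p5$v)
    if (!(d4[3L] * 2L == d3[3L] && d5[3L] * 4L == d3[3L] &&
          d4[4L] * 2L == d3[4L] && d5[4L] * 4L == d3[4L]))
      stop("pyramid levels must halve: P4 = P3/2, P5 = P3/4")
    p3 <- forward_sub(self$sub$in3, xs$p3, ctx)
    p4 <- forward_sub(self$sub$in4, xs$p4, ctx)
    p5 <- forward_sub(self$sub$in5, xs$p5, ctx)
    up <- function(x, Ho, Wo, which) {
      if (self$use_scau) forward_sub(self$sub[[which]], x, ctx)
      else op_upsample_nearest(x, Ho, Wo, ctx)
    }
    td4 <- forward_sub(self$sub$mscm_td4,
      forward_sub(self$sub$fuse_td4, list(p4, up(p5, d4[3L], d4[4L], "up54")), ctx), ctx)
    out3 <- forward_sub(self$sub$mscm_p3,
      forward_sub(self$sub$fuse_td3, list(p3, up(td4, d3[3L], d3[4L], "up43")), ctx), ctx)
    out4 <- forward_sub(self$sub$mscm_bu4,
      forward_sub(self$sub$fuse_bu4,
                  list(p4, td4, forward_sub(self$sub$down34, out3, ctx)), ctx), ctx)
    out5 <- forward_sub(self$sub$mscm_p5,
      forward_sub(self$sub$fuse_bu5,
                  list(p5, forward_sub(self$sub$down45, out4, ctx)), ctx), ctx)
    list(p3 = out3, p4 = out4, p5 = out5)
  }
  m
}

#' Run a neck over a feature pyramid
#'
#' @param neck module from [embfpn_neck()]
#' @param levels named list of arrays `p3`, `p4`, `p5` with halving geometry
#' @return named list of enhanced `p3`, `p4`, `p5` arrays
#' @export
build_neck_features <- function(neck, levels) {
  lapply(levels, check_feature_map)
  nodes <- lapply(levels, tnode)
  out <- neck$fwd(neck, nodes, new_ctx())
  lapply(out, function(n) n$v)
}
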