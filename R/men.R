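# Multi-scale morphological edge network (MEN): backbone blocks that replace
# the baseline's CSP stages with units combining multi-scale adaptive pooling
# and explicit edge-attention enhancement.

#' Edge enhancer
#'
#' Strengthens local edge responses: the difference between a feature map and
#' its 3x3 local average (replicate-padded, stride 1) is passed through a
#' learned 1x1 convolution + batch normalisation and a logistic gate, and the
#' gated input is added back:
#' \deqn{E(x) = x + x \odot \sigma(H(x - P_{avg}(x)))}
#' For nonnegative input the output therefore lies elementwise in
#' \eqn{[x, 2x)}. Spatially constant inputs carry zero edge signal and stay
#' spatially constant.
#'
#' @param channels number of feature channels
#' @return a module; apply with [forward()] or [edge_enhance()]
#' @export
edge_enhancer <- function(channels) {
  m <- new_module("edge_enhancer")
  m$sub <- list(h = conv_unit(channels, channels, 1L, act = FALSE))
  m$fwd <- function(self, x, ctx) {
    check_feature_map(x$v)
    edge <- op_sub(x, op_avgpool3_rep(x, ctx), ctx)
    gate <- op_sigmoid(forward_sub(self$sub$h, edge, ctx), ctx)
    op_add(x, op_mul(x, gate, ctx), ctx)
  }
  m
}

#' Apply an edge enhancer to a feature map
#'
#' @param x feature map array `(B, C, H, W)` or node
#' @param enhancer module from [edge_enhancer()]
#' @param ctx optional context
#' @return enhanced feature map, same shape as `x`
#' @export
edge_enhance <- function(x, enhancer, ctx = NULL) forward(enhancer, x, ctx)

#' Multi-scale fusion unit (MSF)
#'
#' Multi-branch unit: a local 3x3 convolution branch plus, per pooling scale
#' `s`, adaptive average pooling to an `s` x `s` grid, a 1x1 transform,
#' bilinear upsampling back to the input size and edge enhancement. All
#' branches are concatenated and fused by a 1x1 convolution. Default scale
#' set is `{3, 6, 9, 12}`.
#'
#' @param channels feature channels (preserved)
#' @param scales strictly increasing positive integers; every scale must be
#'   at most `min(H, W)` of the maps the unit will see
#' @return a module
#' @export
msf_unit <- function(channels, scales = c(3L, 6L, 9L, 12L)) {
  check_scale_set(scales)
  m <- new_module("msf")
  m$scales <- as.integer(scales)
  m$sub <- list(local = conv_unit(channels, channels, 3L))
  for (i in seq_along(scales)) {
    m$sub[[paste0("tr", i)]] <- conv_unit(channels, channels, 1L)
    m$sub[[paste0("ee", i)]] <- edge_enhancer(channels)
  }
  m$sub$fuse <- conv_unit((length(scales) + 1L) * channels, channels, 1L)
  m$fwd <- function(self, x, ctx) {
    sh <- fm_shape(x)
    if (max(self$scales) > min(sh$H, sh$W))
      stop(sprintf("pooling scale %d exceeds spatial extent %d",
                   max(self$scales), min(sh$H, sh$W)))
    branches <- list(forward_sub(self$sub$local, x, ctx))
    for (i in seq_along(self$scales)) {
      s <- self$scales[i]
      b <- op_adaptive_avgpool(x, s, ctx)
      b <- forward_sub(self$sub[[paste0("tr", i)]], b, ctx)
      b <- op_upsample_bilinear(b, sh$H, sh$W, ctx)
      b <- forward_sub(self$sub[[paste0("ee", i)]], b, ctx)
      branches[[length(branches) + 1L]] <- b
    }
    forward_sub(self$sub$fuse, op_concat_ch(branches, ctx), ctx)
  }
  m
}

#' @keywords internal
check_scale_set <- function(scales) {
  if (length(scales) < 1L || any(scales < 1L) || any(diff(scales) <= 0))
    stop("scales must be strictly increasing positive integers")
  invisible(scales)
}

#' Dual-path module (DPM)
#'
#' Two parallel 1x1 projections; one path runs a serial chain of [msf_unit()]s
#' before the two are concatenated and fused:
#' \deqn{Z = G(\mathrm{Concat}[E(P(x)), Q(x)])}
#'
#' @param channels input (= output) channels; must be even
#' @param n_msf number of MSF units in the serial chain `E` (0 = identity)
#' @param scales scale set forwarded to the MSF units
#' @return a module
#' @export
dpm_unit <- function(channels, n_msf = 1L, scales = c(3L, 6L, 9L, 12L)) {
  if (channels %% 2L != 0L) stop("dual-path unit needs an even channel count")
  ch <- channels %/% 2L
  m <- new_module("dpm")
  m$n_msf <- as.integer(n_msf)
  m$sub <- list(p = conv_unit(channels, ch, 1L), q = conv_unit(channels, ch, 1L),
                g = conv_unit(channels, channels, 1L))
  for (i in seq_len(n_msf)) m$sub[[paste0("e", i)]] <- msf_unit(ch, scales)
  m$fwd <- function(self, x, ctx) {
    a <- forward_sub(self$sub$p, x, ctx)
    for (i in seq_len(self$n_msf)) a <- forward_sub(self$sub[[paste0("e", i)]], a, ctx)
    b <- forward_sub(self$sub$q, x, ctx)
    forward_sub(self$sub$g, op_concat_ch(list(a, b), ctx), ctx)
  }
  m
}

#' Morphological edge network block (MEN)
#'
#' Cross-stage-partial block: a 1x1 entry convolution produces a hidden map
#' split channelwise into `X1`, `X2`; `n_units` dual-path units are applied in
#' series to `X2`, and `X1`, `X2` and every unit output are concatenated and
#' fused to the output width:
#' \deqn{Y = F_{fusion}(\mathrm{Concat}[X_1, X_2, M_{\theta_1}(X_2), \dots, M_{\theta_n}(X_2)])}
#'
#' @param in_channels,out_channels block widths
#' @param n_units number of serial dual-path enhancement units (>= 0)
#' @param split_channels width of each half after the entry split (hidden
#'   width is twice this); defaults to `out_channels / 2`
#' @param n_msf MSF units per dual-path unit
#' @param scales pooling scale set
#' @return a module
#' @export
men_block <- function(in_channels, out_channels, n_units = 1L,
                      split_channels = NULL, n_msf = 1L,
                      scales = c(3L, 6L, 9L, 12L)) {
  if (is.null(split_channels)) {
    if (out_channels %% 2L != 0L) stop("hidden width must split evenly; give split_channels")
    split_channels <- out_channels %/% 2L
  }
  ch <- as.integer(split_channels)
  if (ch %% 2L != 0L && n_units > 0L)
    stop("split width must be even (dual-path units halve it internally)")
  m <- new_module("men")
  m$ch <- ch
  m$n_units <- as.integer(n_units)
  m$in_channels <- as.integer(in_channels)
  m$sub <- list(entry = conv_unit(in_channels, 2L * ch, 1L),
                fuse = conv_unit((2L + n_units) * ch, out_channels, 1L))
  for (i in seq_len(n_units))
    m$sub[[paste0("u", i)]] <- dpm_unit(ch, n_msf, scales)
  m$fwd <- function(self, x, ctx) {
    if (dim(x$v)[2L] != self$in_channels)
      stop(sprintf("expected %d input channels, got %d", self$in_channels, dim(x$v)[2L]))
    h <- forward_sub(self$sub$entry, x, ctx)
    parts <- op_split_ch(h, c(self$ch, self$ch), ctx)
    cur <- parts[[2L]]
    for (i in seq_len(self$n_units)) {
      cur <- forward_sub(self$sub[[paste0("u", i)]], cur, ctx)
      parts[[length(parts) + 1L]] <- cur
    }
    forward_sub(self$sub$fuse, op_concat_ch(parts, ctx), ctx)
  }
  m
}

#' Adaptive average pooling to a square grid
#'
#' Near-uniform window partition: output cell `(i, j)` averages input rows
#' `floor((i-1)H/s)+1 .. ceil(iH/s)` and the analogous columns, so a 6x6 map
#' pooled to 3x3 averages disjoint 2x2 windows.
#'
#' @param x feature map array `(B, C, H, W)`
#' @param s output grid size
#' @return `(B, C, s, s)` array
#' @export
adaptive_avg_pool <- function(x, s) {
  check_feature_map(x)
  op_adaptive_avgpool(tnode(x), as.integer(s), new_ctx())$v
}
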