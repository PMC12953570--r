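# Bifurcated attention feature enhancement (BAFE): frozen Haar wavelet
# decomposition separates low-frequency (background-like) structure from
# high-frequency (edge/texture) detail; two cascaded windowed attention
# stages, guided by the two frequency bands, re-weight the feature map.

#' Haar wavelet decomposition
#'
#' Per-channel 2D convolution with the four fixed, orthonormal 2x2 Haar
#' filters (approximation, horizontal, vertical, diagonal), each scaled by
#' 1/2, stride 2, no padding. Halves both spatial dimensions; on even-sized
#' inputs the transform conserves energy exactly and is exactly invertible
#' (see [haar_reconstruct()]). The filter bank is frozen: it has no trainable
#' coefficients.
#'
#' @param x feature map array `(B, C, H, W)` with `H, W >= 2`
#' @return named list of four arrays `approx`, `horiz`, `vert`, `diag`, each
#'   `(B, C, floor(H/2), floor(W/2))`
#' @export
haar_decompose <- function(x) {
  check_feature_map(x)
  lapply(op_haar(tnode(x), new_ctx()), function(n) n$v)
}

#' Inverse Haar reconstruction
#'
#' Exact inverse of [haar_decompose()] for even-dimension inputs: since the
#' four flattened filters form an orthonormal basis of 2x2 blocks, each block
#' is recovered as the transpose transform of its four subband coefficients.
#'
#' @param subbands named list as returned by [haar_decompose()]
#' @return reconstructed array `(B, C, 2h, 2w)`
#' @export
haar_reconstruct <- function(subbands) {
  need <- c("approx", "horiz", "vert", "diag")
  if (!all(need %in% names(subbands))) stop("need subbands approx/horiz/vert/diag")
  ds <- lapply(subbands[need], dim)
  if (length(unique(lapply(ds, identity))) != 1L)
    stop("subbands must share an identical shape")
  d <- ds[[1L]]
  cf <- haar_coefs()
  y <- array(0, c(d[1L], d[2L], 2L * d[3L], 2L * d[4L]))
  oh <- seq_len(d[3L]) * 2L; ow <- seq_len(d[4L]) * 2L
  s <- subbands[need]
  # taps: 1=(top,left) 2=(bottom,left) 3=(top,right) 4=(bottom,right)
  slots <- list(list(oh - 1L, ow - 1L), list(oh, ow - 1L),
                list(oh - 1L, ow), list(oh, ow))
  for (t in 1:4) {
    acc <- cf[1L, t] * s[[1L]] + cf[2L, t] * s[[2L]] +
           cf[3L, t] * s[[3L]] + cf[4L, t] * s[[4L]]
    y[, , slots[[t]][[1L]], slots[[t]][[2L]]] <- acc
  }
  y
}

#' Fuse wavelet subbands into high- and low-frequency maps
#'
#' The three high-pass subbands are summed elementwise into a single
#' high-frequency representation; the approximation subband passes through as
#' the low-frequency map:
#' \deqn{F_{high} = W_h + W_v + W_d,\qquad F_{low} = W_a}
#'
#' @param subbands named list from [haar_decompose()]
#' @return list with elements `f_high` and `f_low`
#' @export
subband_fuse <- function(subbands) {
  list(f_high = subbands$horiz + subbands$vert + subbands$diag,
       f_low = subbands$approx)
}

#' Windowed self-attention over sliding k x k windows
#'
#' Functional form with identity query/key projections: `guide` supplies the
#' queries and keys, `v` the values. Both are unfolded into overlapping
#' `window` x `window` neighbourhoods (stride 1, zero padding); per head, the
#' attention matrix `softmax(Q K' / sqrt(d_h) + B)` re-weights the window
#' slots of `v`, and overlapping outputs are folded back by count-averaging.
#' Every attention row is a probability vector. With `window = 1` the output
#' equals `v` exactly.
#'
#' @param guide feature map array guiding attention (queries and keys)
#' @param v value feature map, same shape as `guide`
#' @param heads number of attention heads (must divide the channel count)
#' @param window odd window size, at most `min(H, W)`
#' @param bias optional `(window^2, window^2, heads)` positional bias array
#' @return array of the same shape as `v`
#' @export
windowed_attention <- function(guide, v, heads = 4L, window = 3L, bias = NULL) {
  check_feature_map(guide); check_feature_map(v)
  bpar <- if (!is.null(bias)) param_tensor(bias, trainable = FALSE)
  op_window_attention(tnode(guide), tnode(guide), tnode(v), bpar,
                      as.integer(heads), as.integer(window), new_ctx())$v
}

#' Bifurcated attention feature enhancement block (BAFE)
#'
#' Pipeline: 1x1 preprocessing convolution; frozen Haar decomposition;
#' subband fusion into high-/low-frequency maps; average-pool downsampling of
#' both guides (skipped when the subband is already a single pixel) and
#' nearest-neighbour re-expansion to the block resolution; a foreground
#' windowed-attention stage whose queries/keys come from 3x3 convolutions of
#' the high-frequency guide and whose values are a 1x1 projection of the
#' preprocessed input; a cascaded background stage guided by the low-frequency
#' map acting on the foreground output; and a 1x1 output projection. Input and
#' output shapes are equal.
#'
#' @param channels block width (input = output); must be divisible by `heads`
#' @param heads attention heads
#' @param window odd attention window size
#' @param pool guide pooling factor
#' @return a module
#' @export
bafe_block <- function(channels, heads = 4L, window = 3L, pool = 2L) {
  if (channels %% heads != 0L) stop("channels must be divisible by heads")
  if (window %% 2L != 1L) stop("window must be odd")
  m <- new_module("bafe")
  m$heads <- as.integer(heads); m$window <- as.integer(window)
  m$pool <- as.integer(pool)
  k2 <- window * window
  m$pars <- list(
    haar = param_tensor(haar_coefs(), trainable = FALSE),
    bias_fg = param_tensor(array(0, c(k2, k2, heads))),
    bias_bg = param_tensor(array(0, c(k2, k2, heads)))
  )
  m$sub <- list(
    phi_in = conv_unit(channels, channels, 1L),
    q_fg = conv_unit(channels, channels, 3L, act = FALSE),
    k_fg = conv_unit(channels, channels, 3L, act = FALSE),
    v_proj = conv_unit(channels, channels, 1L, act = FALSE),
    f_proj1 = conv_unit(channels, channels, 1L),
    q_bg = conv_unit(channels, channels, 3L, act = FALSE),
    k_bg = conv_unit(channels, channels, 3L, act = FALSE),
    f_proj2 = conv_unit(channels, channels, 1L),
    phi_out = conv_unit(channels, channels, 1L)
  )
  m$fwd <- function(self, x, ctx) {
    sh <- fm_shape(x)
    if (sh$H < 2L || sh$W < 2L) stop("Haar decomposition needs H >= 2 and W >= 2")
    z <- forward_sub(self$sub$phi_in, x, ctx)
    sb <- op_haar(z, ctx)
    fh <- op_add(op_add(sb$horiz, sb$vert, ctx), sb$diag, ctx)
    fl <- sb$approx
    sd <- dim(fh$v)
    if (min(sd[3L], sd[4L]) >= self$pool) {
      fh <- op_avgpool(fh, self$pool, self$pool, ctx)
      fl <- op_avgpool(fl, self$pool, self$pool, ctx)
    }
    gh <- op_upsample_nearest(fh, sh$H, sh$W, ctx)
    gl <- op_upsample_nearest(fl, sh$H, sh$W, ctx)
    vv <- forward_sub(self$sub$v_proj, z, ctx)
    a1 <- op_window_attention(forward_sub(self$sub$q_fg, gh, ctx),
                              forward_sub(self$sub$k_fg, gh, ctx),
                              vv, self$pars$bias_fg, self$heads, self$window, ctx)
    xfg <- forward_sub(self$sub$f_proj1, a1, ctx)
    a2 <- op_window_attention(forward_sub(self$sub$q_bg, gl, ctx),
                              forward_sub(self$sub$k_bg, gl, ctx),
                              xfg, self$pars$bias_bg, self$heads, self$window, ctx)
    forward_sub(self$sub$phi_out, forward_sub(self$sub$f_proj2, a2, ctx), ctx)
  }
  m
}

#' Apply a BAFE block
#'
#' @param x feature map array or node
#' @param block module from [bafe_block()]
#' @param ctx optional context
#' @return enhanced feature map, same shape
#' @export
bafe_forward <- function(x, block, ctx = NULL) forward(block, x, ctx)
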