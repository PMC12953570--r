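# Spatial-channel augmented upsampling (SCAU): 2x upsample, depthwise
# separable convolution, grouped channel shuffle, multi-directional circular
# feature shifting, pointwise fusion. Shuffle and shift are pure index
# permutations: they conserve the value multiset exactly and cost no
# parameters.

# group-transpose permutation, gather form: y[, j] = x[, perm[j]]
shuffle_perm <- function(C, g) {
  if (C %% g != 0L) stop(sprintf("channel count %d not divisible by %d groups", C, g))
  src <- seq_len(C) - 1L
  dest <- (src %% g) * (C %/% g) + src %/% g
  perm <- integer(C)
  perm[dest + 1L] <- src + 1L
  perm
}

#' Channel shuffle
#'
#' Standard group-transpose permutation: channels are reshaped to
#' `(g, C/g)`, transposed and flattened, so channel `i` (0-based) moves to
#' `(i mod g) * (C/g) + floor(i/g)`. Values are untouched; `g = 1` is the
#' identity, and shuffling with `g` followed by `C/g` restores the input.
#'
#' @param x feature map array `(B, C, H, W)`
#' @param g group count dividing `C`
#' @return shuffled array, same shape
#' @export
channel_shuffle <- function(x, g) {
  check_feature_map(x)
  op_permute_ch(tnode(x), shuffle_perm(dim(x)[2L], as.integer(g)), new_ctx())$v
}

#' Multi-directional feature shift (MDFS)
#'
#' Splits the channels into four equal quarters and applies circular shifts:
#' quarter 1 by `+s` along height (downward), quarter 2 by `-s` (upward),
#' quarter 3 by `+s` along width (rightward), quarter 4 by `-s` (leftward),
#' then reconcatenates. A pure index permutation: shape and value multiset
#' are conserved, and negating the shift restores the input exactly.
#'
#' @param x feature map array with channels divisible by 4
#' @param s shift magnitude, `|s| < min(H, W)`; the usual case is positive
#'   (downward/rightward for quarters 1 and 3), a negated `s` applies the
#'   exact inverse permutation
#' @return shifted array, same shape
#' @export
mdfs <- function(x, s) {
  check_feature_map(x)
  if (abs(s) < 1L) stop("shift magnitude must be >= 1")
  op_mdfs(tnode(x), as.integer(s), new_ctx())$v
}

#' Spatial-channel augmented upsampling block (SCAU)
#'
#' 2x nearest-neighbour upsampling, depthwise-separable convolution
#' (depthwise 3x3 + pointwise 1x1, each with BN and SiLU), grouped channel
#' shuffle, multi-directional feature shifting, and a pointwise fusion
#' convolution. Output spatial dims are exactly `2H x 2W`. The block is
#' deterministic: identical input and weights give identical output.
#'
#' @param in_channels,out_channels block widths; `out_channels` must be
#'   divisible by 4 (feature-shift quarters) and by `groups`
#' @param shift circular shift magnitude
#' @param groups channel-shuffle group count
#' @return a module
#' @export
scau_block <- function(in_channels, out_channels = in_channels,
                       shift = 1L, groups = 4L) {
  if (out_channels %% 4L != 0L)
    stop("output channels must be divisible by 4 for the shift quarters")
  if (out_channels %% groups != 0L)
    stop("output channels must be divisible by the shuffle group count")
  m <- new_module("scau")
  m$s <- as.integer(shift); m$g <- as.integer(groups)
  m$sub <- list(
    dw = dw_unit(in_channels, 3L),
    pw = conv_unit(in_channels, out_channels, 1L),
    fuse = conv_unit(out_channels, out_channels, 1L)
  )
  m$fwd <- function(self, x, ctx) {
    sh <- fm_shape(x)
    y <- op_upsample_nearest(x, 2L * sh$H, 2L * sh$W, ctx)
    y <- forward_sub(self$sub$pw, forward_sub(self$sub$dw, y, ctx), ctx)
    y <- op_permute_ch(y, shuffle_perm(dim(y$v)[2L], self$g), ctx)
    y <- op_mdfs(y, self$s, ctx)
    forward_sub(self$sub$fuse, y, ctx)
  }
  m
}

#' Apply a SCAU block
#'
#' @param x feature map array or node
#' @param block module from [scau_block()]
#' @param ctx optional context
#' @return upsampled feature map `(B, C_out, 2H, 2W)`
#' @export
scau_forward <- function(x, block, ctx = NULL) forward(block, x, ctx)
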