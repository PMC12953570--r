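# Network assembly: the nano-scale baseline topology (conv stem, four CSP
# stages, SPPF, terminal attention, PAN neck, decoupled anchor-free heads)
# and the four module toggles that define every ablation variant:
#   A = MEN backbone stages, B = BAFE terminal block,
#   C = EM-BFPN neck, D = SCAU upsamplers.

#' Model configuration
#'
#' @param men,bafe,embfpn,scau module toggles (ablation letters A/B/C/D)
#' @param num_classes number of object classes (default 11)
#' @param input_size square input resolution, divisible by 32
#' @param widths the five backbone stage widths, stem to P5 (nano defaults)
#' @param neck_width unified width of the bidirectional neck (toggle C)
#' @param men_scales pooling scale set used inside MEN blocks, either one
#'   vector for all stages or a list of four vectors (stages P2..P5)
#' @param bafe_heads,bafe_window,bafe_pool BAFE attention settings
#' @param mscm_e,mscm_n,mscm_expansion MSCM settings for the neck
#' @param scau_shift,scau_groups SCAU settings
#' @param reg_max distribution-focal bins per box side
#' @return a list of class `ew_config`
#' @export
model_config <- function(men = FALSE, bafe = FALSE, embfpn = FALSE, scau = FALSE,
                         num_classes = 11L, input_size = 640L,
                         widths = c(16L, 32L, 64L, 128L, 256L),
                         neck_width = 128L,
                         men_scales = c(3L, 6L, 9L, 12L),
                         bafe_heads = 4L, bafe_window = 3L, bafe_pool = 2L,
                         mscm_e = 0.5, mscm_n = 1L, mscm_expansion = 2L,
                         scau_shift = 1L, scau_groups = 4L, reg_max = 16L) {
  if (num_classes < 1L) stop("num_classes must be >= 1")
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  if (length(widths) != 5L) stop("widths must have five entries (stem to P5)")
  if (!is.list(men_scales)) men_scales <- rep(list(men_scales), 4L)
  cfg <- list(men = men, bafe = bafe, embfpn = embfpn, scau = scau,
              num_classes = as.integer(num_classes),
              input_size = as.integer(input_size),
              widths = as.integer(widths), neck_width = as.integer(neck_width),
              men_scales = men_scales,
              bafe_heads = as.integer(bafe_heads),
              bafe_window = as.integer(bafe_window),
              bafe_pool = as.integer(bafe_pool),
              mscm_e = mscm_e, mscm_n = as.integer(mscm_n),
              mscm_expansion = as.integer(mscm_expansion),
              scau_shift = as.integer(scau_shift),
              scau_groups = as.integer(scau_groups),
              reg_max = as.integer(reg_max))
  class(cfg) <- "ew_config"
  cfg
}

#' Configuration for a named ablation variant
#'
#' @param variant `"baseline"` or a `+`-joined toggle string such as
#'   `"A+C"` or `"A+B+C+D"` (A = MEN, B = BAFE, C = EM-BFPN, D = SCAU)
#' @param ... further arguments passed to [model_config()]
#' @return an `ew_config`
#' @export
ablation_config <- function(variant, ...) {
  v <- toupper(variant)
  if (v %in% c("BASELINE", "")) return(model_config(...))
  letters_on <- strsplit(v, "+", fixed = TRUE)[[1L]]
  if (!all(letters_on %in% c("A", "B", "C", "D")))
    stop("variant must be 'baseline' or a combination of A, B, C, D")
  model_config(men = "A" %in% letters_on, bafe = "B" %in% letters_on,
               embfpn = "C" %in% letters_on, scau = "D" %in% letters_on, ...)
}

#' Read a model configuration from YAML
#'
#' Expects keys `toggles` (map with A/B/C/D), `num_classes`, `input_size`,
#' and optionally any other [model_config()] argument.
#'
#' @param path YAML file path
#' @return an `ew_config`
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  tg <- y$toggles %||% list()
  y$toggles <- NULL
  args <- c(list(men = isTRUE(tg$A), bafe = isTRUE(tg$B),
                 embfpn = isTRUE(tg$C), scau = isTRUE(tg$D)), y)
  do.call(model_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Baseline PAN-style neck (top-down + bottom-up with concatenation), with
# interpolation upsamplers or SCAU blocks when toggle D is on.
pan_neck <- function(w, use_scau, scau_shift = 1L, scau_groups = 4L) {
  # incoming taps: P3 = w[4], P4 = w[4], P5 = w[5] channels
  m <- new_module("pan")
  m$use_scau <- use_scau
  m$sub <- list(
    h1 = c3k2_block(w[5L] + w[4L], w[4L], 1L, FALSE),
    out3 = c3k2_block(w[4L] + w[4L], w[3L], 1L, FALSE),
    d1 = conv_unit(w[3L], w[3L], 3L, s = 2L),
    out4 = c3k2_block(w[3L] + w[4L], w[4L], 1L, FALSE),
    d2 = conv_unit(w[4L], w[4L], 3L, s = 2L),
    out5 = c3k2_block(w[4L] + w[5L], w[5L], 1L, TRUE)
  )
  if (use_scau) {
    m$sub$up54 <- scau_block(w[5L], w[5L], shift = scau_shift, groups = scau_groups)
    m$sub$up43 <- scau_block(w[4L], w[4L], shift = scau_shift, groups = scau_groups)
  }
  m$fwd <- function(self, xs, ctx) {
    d3 <- dim(xs$p3$v); d4 <- dim(xs$p4$v)
    up <- function(x, Ho, Wo, which) {
      if (self$use_scau) forward_sub(self$sub[[which]], x, ctx)
      else op_upsample_nearest(x, Ho, Wo, ctx)
    }
    h1 <- forward_sub(self$sub$h1,
      op_concat_ch(list(up(xs$p5, d4[3L], d4[4L], "up54"), xs$p4), ctx), ctx)
    out3 <- forward_sub(self$sub$out3,
      op_concat_ch(list(up(h1, d3[3L], d3[4L], "up43"), xs$p3), ctx), ctx)
    out4 <- forward_sub(self$sub$out4,
      op_concat_ch(list(forward_sub(self$sub$d1, out3, ctx), h1), ctx), ctx)
    out5 <- forward_sub(self$sub$out5,
      op_concat_ch(list(forward_sub(self$sub$d2, out4, ctx), xs$p5), ctx), ctx)
    list(p3 = out3, p4 = out4, p5 = out5)
  }
  m
}

#' Build a detection model
#'
#' Assembles backbone (conv stem, four stages, SPPF, terminal attention),
#' neck and three decoupled detection heads at strides 8/16/32 according to
#' the configuration toggles. All 16 toggle combinations are legal.
#'
#' @param cfg an `ew_config` from [model_config()] / [ablation_config()]
#' @param seed optional integer seed for weight initialisation
#' @return a module of type `detection_model`
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "ew_config"))
  if (!is.null(seed)) return(with_seed(seed, function() build_model(cfg)))
  w <- cfg$widths
  m <- new_module("detection_model")
  m$cfg <- cfg
  m$strides <- c(8L, 16L, 32L)
  stage <- function(cin, cout, c3k, e, i) {
    if (cfg$men) {
      split_ch <- as.integer(round(cout * e))
      men_block(cin, cout, n_units = 1L, split_channels = split_ch,
                n_msf = 1L, scales = cfg$men_scales[[i]])
    } else c3k2_block(cin, cout, 1L, c3k, e)
  }
  m$sub <- list(
    stem1 = conv_unit(3L, w[1L], 3L, s = 2L),
    stem2 = conv_unit(w[1L], w[2L], 3L, s = 2L),
    s2 = stage(w[2L], w[3L], FALSE, 0.25, 1L),
    d3 = conv_unit(w[3L], w[3L], 3L, s = 2L),
    s4 = stage(w[3L], w[4L], FALSE, 0.25, 2L),
    d5 = conv_unit(w[4L], w[4L], 3L, s = 2L),
    s6 = stage(w[4L], w[4L], TRUE, 0.5, 3L),
    d7 = conv_unit(w[4L], w[5L], 3L, s = 2L),
    s8 = stage(w[5L], w[5L], TRUE, 0.5, 4L),
    sppf = sppf_block(w[5L], w[5L], 5L),
    terminal = if (cfg$bafe)
      bafe_block(w[5L], cfg$bafe_heads, cfg$bafe_window, cfg$bafe_pool)
    else c2psa_block(w[5L], 1L),
    neck = if (cfg$embfpn)
      embfpn_neck(c(w[4L], w[4L], w[5L]), cfg$neck_width,
                  cfg$mscm_e, cfg$mscm_n, cfg$mscm_expansion,
                  use_scau = cfg$scau, cfg$scau_shift, cfg$scau_groups)
    else pan_neck(w, use_scau = cfg$scau, cfg$scau_shift, cfg$scau_groups)
  )
  head_ch <- if (cfg$embfpn) rep(cfg$neck_width, 3L) else c(w[3L], w[4L], w[5L])
  m$sub$head <- detect_head(cfg$num_classes, head_ch, cfg$reg_max)
  m$fwd <- function(self, x, ctx) {
    d <- dim(x$v)
    if (d[2L] != 3L) stop("expected a 3-channel image batch")
    if (d[3L] %% 32L != 0L || d[4L] %% 32L != 0L)
      stop("input height and width must be divisible by 32")
    y <- forward_sub(self$sub$stem2, forward_sub(self$sub$stem1, x, ctx), ctx)
    y <- forward_sub(self$sub$s2, y, ctx)
    p3 <- forward_sub(self$sub$s4, forward_sub(self$sub$d3, y, ctx), ctx)
    p4 <- forward_sub(self$sub$s6, forward_sub(self$sub$d5, p3, ctx), ctx)
    p5 <- forward_sub(self$sub$d7, p4, ctx)
    p5 <- forward_sub(self$sub$s8, p5, ctx)
    p5 <- forward_sub(self$sub$sppf, p5, ctx)
    p5 <- forward_sub(self$sub$terminal, p5, ctx)
    feats <- self$sub$neck$fwd(self$sub$neck, list(p3 = p3, p4 = p4, p5 = p5), ctx)
    self$sub$head$fwd(self$sub$head, list(feats$p3, feats$p4, feats$p5), ctx)
  }
  m
}

#' Run a model on an image batch
#'
#' @param model module from [build_model()]
#' @param x image batch array `(B, 3, H, W)` with `H`, `W` divisible by 32
#' @param ctx optional context
#' @return list of three per-level outputs, each with `box`
#'   (`4*reg_max`-channel) and `cls` (`num_classes`-channel) maps at strides
#'   8, 16 and 32
#' @export
model_forward <- function(model, x, ctx = NULL) forward(model, x, ctx)

#' Count FLOPs of a model
#'
#' Analytic count accumulated during a real forward pass at batch 1:
#' 2 operations per multiply-accumulate for dense ops, one operation per
#' element for elementwise ops.
#'
#' @param model module from [build_model()]
#' @param input_size square input resolution (defaults to the configured one)
#' @return list with `flops_giga` and the raw operation count `flops`
#' @export
count_flops <- function(model, input_size = NULL) {
  sz <- as.integer(input_size %||% model$cfg$input_size)
  ctx <- new_ctx(grad = FALSE, training = FALSE)
  x <- tnode(array(0, c(1L, 3L, sz, sz)))
  model$fwd(model, x, ctx)
  list(flops_giga = ctx$flops / 1e9, flops = ctx$flops)
}

#' Parameter and FLOP budget of a model
#'
#' @param model module from [build_model()]
#' @param input_size square input resolution for the FLOP count
#' @return list with `params_millions`, `flops_giga`, `n_trainable`, `n_frozen`
#' @export
budget_report <- function(model, input_size = NULL) {
  p <- count_params(model)
  f <- count_flops(model, input_size)
  list(params_millions = p$params_millions, flops_giga = f$flops_giga,
       n_trainable = p$n_trainable, n_frozen = p$n_frozen)
}

#' Flat summary of a module tree
#'
#' @param module any module
#' @return data frame with one row per (sub)module: `path` and `type`
#' @export
module_summary <- function(module) {
  rows <- list()
  walk <- function(m, path) {
    rows[[length(rows) + 1L]] <<- data.frame(path = path, type = m$type,
                                             stringsAsFactors = FALSE)
    for (nm in names(m$sub)) walk(m$sub[[nm]], paste(path, nm, sep = "/"))
  }
  walk(module, "model")
  do.call(rbind, rows)
}
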