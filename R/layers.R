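# Standard single-stage-detector building blocks: Conv+BN+SiLU units,
# cross-stage-partial bottleneck stacks, SPPF, and the baseline terminal
# attention stage. Widths follow the nano scaling of the baseline family.

bn_module <- function(C, eps = 1e-3, momentum = 0.03) {
  m <- new_module("bn")
  m$pars <- list(gamma = param_tensor(rep(1, C)), beta = param_tensor(numeric(C)))
  m$rm <- numeric(C)
  m$rv <- rep(1, C)
  m$eps <- eps
  m$momentum <- momentum
  m$fwd <- function(self, x, ctx) op_bn(x, self, ctx)
  m
}

# Conv -> BN -> SiLU (the family's standard convolution unit).
conv_unit <- function(cin, cout, k = 1L, s = 1L, p = NULL, act = TRUE) {
  if (is.null(p)) p <- k %/% 2L
  m <- new_module("conv_unit")
  m$stride <- as.integer(s); m$pad <- as.integer(p); m$act <- act
  m$pars <- list(w = param_tensor(init_uniform(c(cin, k, k, cout), cin * k * k)))
  m$sub <- list(bn = bn_module(cout))
  m$fwd <- function(self, x, ctx) {
    y <- op_bn(op_conv(x, self$pars$w, NULL, self$stride, self$pad, ctx), self$sub$bn, ctx)
    if (self$act) op_silu(y, ctx) else y
  }
  m
}

# Plain convolution with bias, no normalisation (head output layers).
plain_conv <- function(cin, cout, k = 1L, s = 1L, p = NULL) {
  if (is.null(p)) p <- k %/% 2L
  m <- new_module("plain_conv")
  m$stride <- as.integer(s); m$pad <- as.integer(p)
  m$pars <- list(
    w = param_tensor(init_uniform(c(cin, k, k, cout), cin * k * k)),
    b = param_tensor(init_uniform(cout, cin * k * k))
  )
  m$fwd <- function(self, x, ctx)
    op_conv(x, self$pars$w, self$pars$b, self$stride, self$pad, ctx)
  m
}

# Depthwise conv -> BN -> SiLU.
dw_unit <- function(C, k = 3L, s = 1L, act = TRUE) {
  m <- new_module("dw_unit")
  m$stride <- as.integer(s); m$pad <- k %/% 2L; m$act <- act
  m$pars <- list(w = param_tensor(init_uniform(c(C, k, k), k * k)))
  m$sub <- list(bn = bn_module(C))
  m$fwd <- function(self, x, ctx) {
    y <- op_bn(op_dwconv(x, self$pars$w, NULL, self$stride, self$pad, ctx), self$sub$bn, ctx)
    if (self$act) op_silu(y, ctx) else y
  }
  m
}

bottleneck_block <- function(c1, c2, shortcut = TRUE, k = c(3L, 3L), e = 0.5) {
  ch <- as.integer(round(c2 * e))
  m <- new_module("bottleneck")
  m$shortcut <- shortcut && c1 == c2
  m$sub <- list(cv1 = conv_unit(c1, ch, k[1L]), cv2 = conv_unit(ch, c2, k[2L]))
  m$fwd <- function(self, x, ctx) {
    y <- forward_sub(self$sub$cv2, forward_sub(self$sub$cv1, x, ctx), ctx)
    if (self$shortcut) op_add(x, y, ctx) else y
  }
  m
}

# internal: apply a child module inside another module's forward
forward_sub <- function(mod, x, ctx) mod$fwd(mod, x, ctx)

c3k_block <- function(c1, c2, n = 2L, e = 0.5, k = 3L) {
  ch <- as.integer(round(c1 * e))
  m <- new_module("c3k")
  m$sub <- list(cv1 = conv_unit(c1, ch, 1L), cv2 = conv_unit(c1, ch, 1L),
                cv3 = conv_unit(2L * ch, c2, 1L))
  for (i in seq_len(n))
    m$sub[[paste0("m", i)]] <- bottleneck_block(ch, ch, TRUE, c(k, k), e = 1.0)
  m$n <- n
  m$fwd <- function(self, x, ctx) {
    a <- forward_sub(self$sub$cv1, x, ctx)
    for (i in seq_len(self$n)) a <- forward_sub(self$sub[[paste0("m", i)]], a, ctx)
    b <- forward_sub(self$sub$cv2, x, ctx)
    forward_sub(self$sub$cv3, op_concat_ch(list(a, b), ctx), ctx)
  }
  m
}

c3k2_block <- function(c1, c2, n = 1L, c3k = FALSE, e = 0.5) {
  ch <- as.integer(round(c2 * e))
  m <- new_module("c3k2")
  m$ch <- ch; m$n <- n
  m$sub <- list(cv1 = conv_unit(c1, 2L * ch, 1L),
                cv2 = conv_unit((2L + n) * ch, c2, 1L))
  for (i in seq_len(n))
    m$sub[[paste0("m", i)]] <- if (c3k) c3k_block(ch, ch, 2L)
                               else bottleneck_block(ch, ch, TRUE, c(3L, 3L), 0.5)
  m$fwd <- function(self, x, ctx) {
    y <- forward_sub(self$sub$cv1, x, ctx)
    parts <- op_split_ch(y, c(self$ch, self$ch), ctx)
    cur <- parts[[2L]]
    for (i in seq_len(self$n)) {
      cur <- forward_sub(self$sub[[paste0("m", i)]], cur, ctx)
      parts[[length(parts) + 1L]] <- cur
    }
    forward_sub(self$sub$cv2, op_concat_ch(parts, ctx), ctx)
  }
  m
}

sppf_block <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  m <- new_module("sppf")
  m$k <- as.integer(k)
  m$sub <- list(cv1 = conv_unit(c1, ch, 1L), cv2 = conv_unit(4L * ch, c2, 1L))
  m$fwd <- function(self, x, ctx) {
    y <- forward_sub(self$sub$cv1, x, ctx)
    p1 <- op_maxpool(y, self$k, 1L, self$k %/% 2L, ctx)
    p2 <- op_maxpool(p1, self$k, 1L, self$k %/% 2L, ctx)
    p3 <- op_maxpool(p2, self$k, 1L, self$k %/% 2L, ctx)
    forward_sub(self$sub$cv2, op_concat_ch(list(y, p1, p2, p3), ctx), ctx)
  }
  m
}

# Global multi-head attention block of the baseline terminal stage.
global_attention_block <- function(dim, heads, attn_ratio = 0.5) {
  head_dim <- dim %/% heads
  key_dim <- as.integer(head_dim * attn_ratio)
  h <- dim + 2L * heads * key_dim
  m <- new_module("global_attn")
  m$heads <- heads; m$key_dim <- key_dim; m$dim <- dim
  m$sub <- list(
    qkv = conv_unit(dim, h, 1L, act = FALSE),
    proj = conv_unit(dim, dim, 1L, act = FALSE),
    pe = dw_unit(dim, 3L, act = FALSE)
  )
  m$fwd <- function(self, x, ctx) {
    qkv <- forward_sub(self$sub$qkv, x, ctx)
    nk <- self$heads * self$key_dim
    parts <- op_split_ch(qkv, c(nk, nk, self$dim), ctx)
    att <- op_global_attention(parts[[1L]], parts[[2L]], parts[[3L]], self$heads, ctx)
    y <- op_add(att, forward_sub(self$sub$pe, parts[[3L]], ctx), ctx)
    forward_sub(self$sub$proj, y, ctx)
  }
  m
}

psa_block <- function(C, heads) {
  m <- new_module("psa")
  m$sub <- list(
    attn = global_attention_block(C, heads),
    ffn1 = conv_unit(C, 2L * C, 1L),
    ffn2 = conv_unit(2L * C, C, 1L, act = FALSE)
  )
  m$fwd <- function(self, x, ctx) {
    x <- op_add(x, forward_sub(self$sub$attn, x, ctx), ctx)
    y <- forward_sub(self$sub$ffn2, forward_sub(self$sub$ffn1, x, ctx), ctx)
    op_add(x, y, ctx)
  }
  m
}

c2psa_block <- function(C, n = 1L) {
  ch <- C %/% 2L
  heads <- max(1L, ch %/% 64L)
  m <- new_module("c2psa")
  m$ch <- ch; m$n <- n
  m$sub <- list(cv1 = conv_unit(C, 2L * ch, 1L), cv2 = conv_unit(2L * ch, C, 1L))
  for (i in seq_len(n)) m$sub[[paste0("m", i)]] <- psa_block(ch, heads)
  m$fwd <- function(self, x, ctx) {
    y <- forward_sub(self$sub$cv1, x, ctx)
    parts <- op_split_ch(y, c(self$ch, self$ch), ctx)
    b <- parts[[2L]]
    for (i in seq_len(self$n)) b <- forward_sub(self$sub[[paste0("m", i)]], b, ctx)
    forward_sub(self$sub$cv2, op_concat_ch(list(parts[[1L]], b), ctx), ctx)
  }
  m
}

# Decoupled anchor-free detection head (distribution-focal box regression
# with reg_max bins per side + per-class logits), one branch pair per level.
detect_head <- function(nc, ch, reg_max = 16L) {
  c2 <- max(16L, ch[1L] %/% 4L, 4L * reg_max)
  c3 <- max(ch[1L], min(nc, 100L))
  m <- new_module("detect")
  m$nc <- as.integer(nc); m$reg_max <- as.integer(reg_max)
  m$nl <- length(ch)
  for (i in seq_along(ch)) {
    box_out <- plain_conv(c2, 4L * reg_max, 1L)
    cls_out <- plain_conv(c3, nc, 1L)
    box_out$pars$b$v[] <- 1.0     # bias prior: distances start near one cell
    cls_out$pars$b$v[] <- -4.6    # rare-object prior keeps early loss stable
    m$sub[[paste0("box", i)]] <- seq_modules(
      conv_unit(ch[i], c2, 3L), conv_unit(c2, c2, 3L), box_out)
    m$sub[[paste0("cls", i)]] <- seq_modules(
      dw_unit(ch[i], 3L), conv_unit(ch[i], c3, 1L),
      dw_unit(c3, 3L), conv_unit(c3, c3, 1L), cls_out)
  }
  # distribution-focal bin values: fixed, non-trainable
  m$pars <- list(dfl_bins = param_tensor(as.numeric(0:(reg_max - 1L)), trainable = FALSE))
  m$fwd <- function(self, xs, ctx) {
    lapply(seq_len(self$nl), function(i) list(
      box = forward_sub(self$sub[[paste0("box", i)]], xs[[i]], ctx),
      cls = forward_sub(self$sub[[paste0("cls", i)]], xs[[i]], ctx)
    ))
  }
  m
}

# Sequential container.
seq_modules <- function(...) {
  m <- new_module("seq")
  m$sub <- list(...)
  m$fwd <- function(self, x, ctx) {
    for (s in self$sub) x <- forward_sub(s, x, ctx)
    x
  }
  m
}
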