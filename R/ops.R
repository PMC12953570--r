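# Differentiable tensor operations.
#
# Convolutions are computed per sample as gather (im2col) + GEMM; backward
# passes scatter gradients through the same precomputed index maps. Index maps
# depend only on geometry and are memoised in a package-local cache.

.ew_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  v <- .ew_cache[[key]]
  if (is.null(v)) {
    v <- make()
    .ew_cache[[key]] <- v
  }
  v
}

# Gather indices for a k x k window sweep over a (H, W) grid padded by `pad`,
# visited with `stride`. Columns of $idx are output positions (h fastest);
# rows are window taps ordered (dh fastest, then dw). $icol maps original
# pixels into the padded grid.
conv_cache <- function(H, W, k, stride, pad) {
  key <- paste("cv", H, W, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    Hout <- (Hp - k) %/% stride + 1L
    Wout <- (Wp - k) %/% stride + 1L
    if (Hout < 1L || Wout < 1L) stop("spatial dims too small for this window")
    L <- Hout * Wout
    h0 <- rep(seq_len(Hout) - 1L, times = Wout) * stride
    w0 <- rep(seq_len(Wout) - 1L, each = Hout) * stride
    # tap order: dh fastest within dw, matching (Cin, kh, kw, Cout) weight layout
    idx <- matrix(0L, k * k, L)
    t <- 0L
    for (dw in 0:(k - 1L)) for (dh in 0:(k - 1L)) {
      t <- t + 1L
      idx[t, ] <- (h0 + dh) + Hp * (w0 + dw) + 1L
    }
    ih <- rep(seq_len(H), times = W) + pad
    iw <- rep(seq_len(W), each = H) + pad
    icol <- ih + Hp * (iw - 1L)
    list(idx = idx, idxv = as.vector(idx), Hout = Hout, Wout = Wout,
         Hp = Hp, Wp = Wp, icol = icol, L = L)
  })
}

# (B,C,H,W) array -> (C, H*W) matrix for sample b (no copy when B == 1).
slice_cm <- function(v, b) {
  d <- dim(v)
  if (d[1L] == 1L) {
    dim(v) <- c(d[2L], d[3L] * d[4L])
    v
  } else {
    s <- v[b, , , ]
    dim(s) <- c(d[2L], d[3L] * d[4L])
    s
  }
}

pad_zero <- function(xm, ci) {
  xp <- matrix(0, nrow(xm), ci$Hp * ci$Wp)
  xp[, ci$icol] <- xm
  xp
}

# ---- dense convolution ------------------------------------------------------

op_conv <- function(x, w, b = NULL, stride = 1L, pad = 0L, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  wd <- dim(w$v); k <- wd[2L]; Cout <- wd[4L]
  if (wd[1L] != C) stop(sprintf("conv expects %d input channels, got %d", wd[1L], C))
  ci <- conv_cache(H, W, k, stride, pad)
  L <- ci$L
  k2 <- k * k
  wflat <- w$v; dim(wflat) <- c(C * k2, Cout)
  trivial <- (k == 1L && stride == 1L && pad == 0L)
  y <- array(0, c(B, Cout, ci$Hout, ci$Wout))
  need <- ctx$grad
  cols <- if (need) vector("list", B)
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    if (trivial) {
      A <- xm
    } else {
      xp <- if (pad > 0L) pad_zero(xm, ci) else xm
      A <- xp[, ci$idxv, drop = FALSE]
      dim(A) <- c(C * k2, L)
    }
    yb <- crossprod(wflat, A)
    if (!is.null(b)) yb <- yb + b$v
    y[bb, , , ] <- yb
    if (need) cols[[bb]] <- A
  }
  add_flops(ctx, (2 * C * k2 + if (is.null(b)) 0 else 1) * Cout * L * B)
  out <- tnode(y)
  if (need) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    dwflat <- matrix(0, C * k2, Cout)
    dbv <- if (!is.null(b)) numeric(Cout)
    for (bb in seq_len(B)) {
      gyb <- slice_cm(gy, bb)
      A <- cols[[bb]]
      dwflat <- dwflat + tcrossprod(A, gyb)
      if (!is.null(b)) dbv <- dbv + rowSums(gyb)
      dA <- wflat %*% gyb
      if (trivial) {
        dx[bb, , , ] <- dA
      } else {
        dim(dA) <- c(C, k2, L)
        dxp <- matrix(0, C, ci$Hp * ci$Wp)
        for (t in seq_len(k2)) {
          cc <- ci$idx[t, ]
          dxp[, cc] <- dxp[, cc] + dA[, t, ]
        }
        dx[bb, , , ] <- dxp[, ci$icol, drop = FALSE]
      }
    }
    accum_grad(x, dx)
    dw <- dwflat; dim(dw) <- wd
    accum_grad(w, dw)
    if (!is.null(b)) accum_grad(b, dbv)
  })
  out
}

# ---- depthwise convolution --------------------------------------------------

op_dwconv <- function(x, w, b = NULL, stride = 1L, pad = 0L, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  wd <- dim(w$v); k <- wd[2L]
  if (wd[1L] != C) stop("depthwise conv channel mismatch")
  ci <- conv_cache(H, W, k, stride, pad)
  k2 <- k * k
  wm <- w$v; dim(wm) <- c(C, k2)
  y <- array(0, c(B, C, ci$Hout, ci$Wout))
  need <- ctx$grad
  pads <- if (need) vector("list", B)
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    xp <- if (pad > 0L) pad_zero(xm, ci) else xm
    yb <- matrix(0, C, ci$L)
    for (t in seq_len(k2)) yb <- yb + wm[, t] * xp[, ci$idx[t, ], drop = FALSE]
    if (!is.null(b)) yb <- yb + b$v
    y[bb, , , ] <- yb
    if (need) pads[[bb]] <- xp
  }
  add_flops(ctx, 2 * C * k2 * ci$L * B)
  out <- tnode(y)
  if (need) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    dwm <- matrix(0, C, k2)
    dbv <- if (!is.null(b)) numeric(C)
    for (bb in seq_len(B)) {
      gyb <- slice_cm(gy, bb)
      xp <- pads[[bb]]
      dxp <- matrix(0, C, ci$Hp * ci$Wp)
      for (t in seq_len(k2)) {
        cc <- ci$idx[t, ]
        dwm[, t] <- dwm[, t] + rowSums(gyb * xp[, cc, drop = FALSE])
        dxp[, cc] <- dxp[, cc] + gyb * wm[, t]
      }
      if (!is.null(b)) dbv <- dbv + rowSums(gyb)
      dx[bb, , , ] <- dxp[, ci$icol, drop = FALSE]
    }
    accum_grad(x, dx)
    dw <- dwm; dim(dw) <- wd
    accum_grad(w, dw)
    if (!is.null(b)) accum_grad(b, dbv)
  })
  out
}

# ---- batch normalisation ----------------------------------------------------

op_bn <- function(x, bn, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; HW <- d[3L] * d[4L]
  xm <- xv; dim(xm) <- c(B * C, HW)
  gam <- bn$pars$gamma$v; bet <- bn$pars$beta$v
  eps <- bn$eps
  add_flops(ctx, 2 * length(xv))
  if (ctx$training) {
    N <- B * HW
    s1 <- rowSums(xm); s2 <- rowSums(xm * xm)
    mu <- colSums(matrix(s1, B, C)) / N
    ex2 <- colSums(matrix(s2, B, C)) / N
    vr <- pmax(ex2 - mu * mu, 0)
    istd <- 1 / sqrt(vr + eps)
    mubc <- rep(mu, each = B)
    istdbc <- rep(istd, each = B)
    xh <- (xm - mubc) * istdbc
    ym <- xh * rep(gam, each = B) + rep(bet, each = B)
    mom <- bn$momentum
    bn$rm <- (1 - mom) * bn$rm + mom * mu
    uv <- if (N > 1L) vr * N / (N - 1L) else vr
    bn$rv <- (1 - mom) * bn$rv + mom * uv
    y <- ym; dim(y) <- d
    out <- tnode(y)
    if (ctx$grad) ctx_push(ctx, function() {
      gy <- out$g; if (is.null(gy)) return(invisible(NULL))
      gym <- gy; dim(gym) <- c(B * C, HW)
      sg <- colSums(matrix(rowSums(gym), B, C))            # sum gy per channel
      sgx <- colSums(matrix(rowSums(gym * xh), B, C))      # sum gy*xhat
      accum_grad(bn$pars$beta, sg)
      accum_grad(bn$pars$gamma, sgx)
      gbc <- rep(gam, each = B) * istdbc
      dxm <- gbc * (gym - rep(sg / N, each = B) - xh * rep(sgx / N, each = B))
      dim(dxm) <- d
      accum_grad(x, dxm)
    })
    out
  } else {
    istd <- 1 / sqrt(bn$rv + eps)
    scale <- gam * istd
    shift <- bet - bn$rm * scale
    ym <- xm * rep(scale, each = B) + rep(shift, each = B)
    y <- ym; dim(y) <- d
    out <- tnode(y)
    if (ctx$grad) ctx_push(ctx, function() {
      gy <- out$g; if (is.null(gy)) return(invisible(NULL))
      gym <- gy; dim(gym) <- c(B * C, HW)
      sg <- colSums(matrix(rowSums(gym), B, C))
      xhat <- (xm - rep(bn$rm, each = B)) * rep(istd, each = B)
      sgx <- colSums(matrix(rowSums(gym * xhat), B, C))
      accum_grad(bn$pars$beta, sg)
      accum_grad(bn$pars$gamma, sgx)
      dxm <- gym * rep(scale, each = B)
      dim(dxm) <- d
      accum_grad(x, dxm)
    })
    out
  }
}

# ---- elementwise ------------------------------------------------------------

op_silu <- function(x, ctx) {
  s <- 1 / (1 + exp(-x$v))
  out <- tnode(x$v * s)
  add_flops(ctx, length(s))
  if (ctx$grad) ctx_push(ctx, function() {
    if (is.null(out$g)) return(invisible(NULL))
    accum_grad(x, out$g * (s * (1 + x$v * (1 - s))))
  })
  out
}

op_relu <- function(x, ctx) {
  out <- tnode(pmax(x$v, 0))
  add_flops(ctx, length(x$v))
  if (ctx$grad) ctx_push(ctx, function() {
    if (is.null(out$g)) return(invisible(NULL))
    accum_grad(x, out$g * (x$v > 0))
  })
  out
}

op_sigmoid <- function(x, ctx) {
  s <- 1 / (1 + exp(-x$v))
  out <- tnode(s)
  add_flops(ctx, length(s))
  if (ctx$grad) ctx_push(ctx, function() {
    if (is.null(out$g)) return(invisible(NULL))
    accum_grad(x, out$g * s * (1 - s))
  })
  out
}

op_add <- function(a, b, ctx) {
  out <- tnode(a$v + b$v)
  add_flops(ctx, length(a$v))
  if (ctx$grad) ctx_push(ctx, function() {
    if (is.null(out$g)) return(invisible(NULL))
    accum_grad(a, out$g)
    accum_grad(b, out$g)
  })
  out
}

op_mul <- function(a, b, ctx) {
  out <- tnode(a$v * b$v)
  add_flops(ctx, length(a$v))
  if (ctx$grad) ctx_push(ctx, function() {
    if (is.null(out$g)) return(invisible(NULL))
    accum_grad(a, out$g * b$v)
    accum_grad(b, out$g * a$v)
  })
  out
}

# ---- channel concat / split -------------------------------------------------

op_concat_ch <- function(xs, ctx) {
  d1 <- dim(xs[[1L]]$v)
  Cs <- vapply(xs, function(x) dim(x$v)[2L], 0)
  y <- array(0, c(d1[1L], sum(Cs), d1[3L], d1[4L]))
  off <- 0L
  for (i in seq_along(xs)) {
    y[, off + seq_len(Cs[i]), , ] <- xs[[i]]$v
    off <- off + Cs[i]
  }
  out <- tnode(y)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    off <- 0L
    for (i in seq_along(xs)) {
      accum_grad(xs[[i]], gy[, off + seq_len(Cs[i]), , , drop = FALSE])
      off <- off + Cs[i]
    }
  })
  out
}

op_split_ch <- function(x, sizes, ctx) {
  d <- dim(x$v)
  stopifnot(sum(sizes) == d[2L])
  outs <- vector("list", length(sizes))
  off <- 0L
  for (i in seq_along(sizes)) {
    outs[[i]] <- tnode(x$v[, off + seq_len(sizes[i]), , , drop = FALSE])
    off <- off + sizes[i]
  }
  if (ctx$grad) ctx_push(ctx, function() {
    g <- array(0, d)
    any_g <- FALSE
    off <- 0L
    for (i in seq_along(sizes)) {
      if (!is.null(outs[[i]]$g)) {
        g[, off + seq_len(sizes[i]), , ] <- outs[[i]]$g
        any_g <- TRUE
      }
      off <- off + sizes[i]
    }
    if (any_g) accum_grad(x, g)
  })
  outs
}

# ---- pooling ----------------------------------------------------------------

op_maxpool <- function(x, k, stride = 1L, pad = 0L, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]
  ci <- conv_cache(d[3L], d[4L], k, stride, pad)
  k2 <- k * k
  y <- array(0, c(B, C, ci$Hout, ci$Wout))
  need <- ctx$grad
  args <- if (need) vector("list", B)
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    xp <- if (pad > 0L) {
      m <- matrix(-Inf, C, ci$Hp * ci$Wp); m[, ci$icol] <- xm; m
    } else xm
    best <- matrix(-Inf, C, ci$L)
    argt <- matrix(0L, C, ci$L)
    for (t in seq_len(k2)) {
      At <- xp[, ci$idx[t, ], drop = FALSE]
      sel <- At > best
      best[sel] <- At[sel]
      argt[sel] <- t
    }
    y[bb, , , ] <- best
    if (need) args[[bb]] <- argt
  }
  add_flops(ctx, k2 * C * ci$L * B)
  out <- tnode(y)
  if (need) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    for (bb in seq_len(B)) {
      gyb <- slice_cm(gy, bb)
      argt <- args[[bb]]
      dxp <- matrix(0, C, ci$Hp * ci$Wp)
      for (t in seq_len(k2)) {
        cc <- ci$idx[t, ]
        dxp[, cc] <- dxp[, cc] + gyb * (argt == t)
      }
      dx[bb, , , ] <- dxp[, ci$icol, drop = FALSE]
    }
    accum_grad(x, dx)
  })
  out
}

# Plain average pooling, no padding (used for guide downsampling).
op_avgpool <- function(x, k, stride, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]
  ci <- conv_cache(d[3L], d[4L], k, stride, 0L)
  k2 <- k * k
  y <- array(0, c(B, C, ci$Hout, ci$Wout))
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    yb <- matrix(0, C, ci$L)
    for (t in seq_len(k2)) yb <- yb + xm[, ci$idx[t, ], drop = FALSE]
    y[bb, , , ] <- yb / k2
  }
  add_flops(ctx, k2 * C * ci$L * B)
  out <- tnode(y)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    for (bb in seq_len(B)) {
      gyb <- slice_cm(gy, bb) / k2
      dxm <- matrix(0, C, d[3L] * d[4L])
      for (t in seq_len(k2)) {
        cc <- ci$idx[t, ]
        dxm[, cc] <- dxm[, cc] + gyb
      }
      dx[bb, , , ] <- dxm
    }
    accum_grad(x, dx)
  })
  out
}

# Replicate-padding source map: padded position -> original column index.
rep_pad_cache <- function(H, W) {
  key <- paste("rp", H, W, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L; Wp <- W + 2L
    ph <- pmin(pmax(rep(seq_len(Hp) - 1L, times = Wp), 1L), H)
    pw <- pmin(pmax(rep(seq_len(Wp) - 1L, each = Hp), 1L), W)
    ph + H * (pw - 1L)
  })
}

# 3x3 average pooling, stride 1, replicate padding: the local-background
# smoother of the edge enhancer.
op_avgpool3_rep <- function(x, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  if (H < 3L || W < 3L) stop("spatial dims smaller than the 3x3 pooling window")
  src <- rep_pad_cache(H, W)
  ci <- conv_cache(H + 2L, W + 2L, 3L, 1L, 0L)   # sweep over the padded grid
  y <- array(0, d)
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    xp <- xm[, src, drop = FALSE]
    yb <- matrix(0, C, ci$L)
    for (t in 1:9) yb <- yb + xp[, ci$idx[t, ], drop = FALSE]
    y[bb, , , ] <- yb / 9
  }
  add_flops(ctx, 9 * C * H * W * B)
  out <- tnode(y)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    for (bb in seq_len(B)) {
      gyb <- slice_cm(gy, bb) / 9
      dxp <- matrix(0, C, (H + 2L) * (W + 2L))
      for (t in 1:9) {
        cc <- ci$idx[t, ]
        dxp[, cc] <- dxp[, cc] + gyb
      }
      # fold replicate padding back (duplicated sources at the border)
      agg <- rowsum(t(dxp), group = src)          # (H*W, C), groups sorted 1..HW
      dx[bb, , , ] <- t(agg)
    }
    accum_grad(x, dx)
  })
  out
}

adaptive_cells <- function(H, W, s) {
  key <- paste("ap", H, W, s, sep = "_")
  cache_get(key, function() {
    hs <- floor((seq_len(s) - 1L) * H / s) + 1L
    he <- ceiling(seq_len(s) * H / s)
    ws <- floor((seq_len(s) - 1L) * W / s) + 1L
    we <- ceiling(seq_len(s) * W / s)
    cells <- vector("list", s * s)
    t <- 0L
    for (j in seq_len(s)) for (i in seq_len(s)) {
      t <- t + 1L
      hh <- hs[i]:he[i]; ww <- ws[j]:we[j]
      cells[[t]] <- as.vector(outer(hh, (ww - 1L) * H, `+`))
    }
    cells
  })
}

# Adaptive average pooling to an s x s output grid (near-uniform partition).
op_adaptive_avgpool <- function(x, s, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  if (s > min(H, W)) stop(sprintf("pooling scale %d exceeds spatial extent %d", s, min(H, W)))
  cells <- adaptive_cells(H, W, s)
  y <- array(0, c(B, C, s, s))
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    yb <- matrix(0, C, s * s)
    for (t in seq_along(cells))
      yb[, t] <- rowMeans(xm[, cells[[t]], drop = FALSE])
    y[bb, , , ] <- yb
  }
  add_flops(ctx, C * H * W * B)
  out <- tnode(y)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    for (bb in seq_len(B)) {
      gyb <- slice_cm(gy, bb)
      dxm <- matrix(0, C, H * W)
      for (t in seq_along(cells)) {
        cc <- cells[[t]]
        dxm[, cc] <- dxm[, cc] + gyb[, t] / length(cc)
      }
      dx[bb, , , ] <- dxm
    }
    accum_grad(x, dx)
  })
  out
}

# ---- resampling -------------------------------------------------------------

nearest_cache <- function(H, W, Ho, Wo) {
  key <- paste("nn", H, W, Ho, Wo, sep = "_")
  cache_get(key, function() {
    sh <- pmin(floor((seq_len(Ho) - 1L) * H / Ho) + 1L, H)
    sw <- pmin(floor((seq_len(Wo) - 1L) * W / Wo) + 1L, W)
    as.vector(outer(sh, (sw - 1L) * H, `+`))
  })
}

op_upsample_nearest <- function(x, Ho, Wo, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  cmap <- nearest_cache(H, W, Ho, Wo)
  y <- array(0, c(B, C, Ho, Wo))
  for (bb in seq_len(B)) y[bb, , , ] <- slice_cm(xv, bb)[, cmap, drop = FALSE]
  out <- tnode(y)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    for (bb in seq_len(B)) {
      agg <- rowsum(t(slice_cm(gy, bb)), group = cmap)
      dxm <- matrix(0, C, H * W)
      dxm[, as.integer(rownames(agg))] <- t(agg)
      dx[bb, , , ] <- dxm
    }
    accum_grad(x, dx)
  })
  out
}

bilinear_cache <- function(H, W, Ho, Wo) {
  key <- paste("bl", H, W, Ho, Wo, sep = "_")
  cache_get(key, function() {
    axis <- function(n, no) {
      s <- (seq_len(no) - 0.5) * n / no - 0.5
      i0 <- pmin(pmax(floor(s), 0), n - 1L)
      i1 <- pmin(i0 + 1L, n - 1L)
      fr <- pmin(pmax(s - i0, 0), 1)
      list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L, fr = fr)
    }
    ah <- axis(H, Ho); aw <- axis(W, Wo)
    grid <- function(hi, wi) as.vector(outer(hi, (wi - 1L) * H, `+`))
    fh <- rep(ah$fr, times = Wo); fw <- rep(aw$fr, each = Ho)
    list(
      cols = list(grid(ah$i0, aw$i0), grid(ah$i1, aw$i0),
                  grid(ah$i0, aw$i1), grid(ah$i1, aw$i1)),
      wts  = list((1 - fh) * (1 - fw), fh * (1 - fw), (1 - fh) * fw, fh * fw)
    )
  })
}

op_upsample_bilinear <- function(x, Ho, Wo, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  bc <- bilinear_cache(H, W, Ho, Wo)
  y <- array(0, c(B, C, Ho, Wo))
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    yb <- matrix(0, C, Ho * Wo)
    for (t in 1:4)
      yb <- yb + xm[, bc$cols[[t]], drop = FALSE] * rep(bc$wts[[t]], each = C)
    y[bb, , , ] <- yb
  }
  add_flops(ctx, 8 * C * Ho * Wo * B)
  out <- tnode(y)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dx <- array(0, d)
    for (bb in seq_len(B)) {
      gyb <- slice_cm(gy, bb)
      dxm <- matrix(0, C, H * W)
      for (t in 1:4) {
        contrib <- gyb * rep(bc$wts[[t]], each = C)
        agg <- rowsum(t(contrib), group = bc$cols[[t]])
        ii <- as.integer(rownames(agg))
        dxm[, ii] <- dxm[, ii] + t(agg)
      }
      dx[bb, , , ] <- dxm
    }
    accum_grad(x, dx)
  })
  out
}

# ---- pure index permutations ------------------------------------------------

op_permute_ch <- function(x, perm, ctx) {
  out <- tnode(x$v[, perm, , , drop = FALSE])
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
    accum_grad(x, gy[, inv, , , drop = FALSE])
  })
  out
}

roll_index <- function(n, s) ((seq_len(n) - 1L - s) %% n) + 1L

# Multi-directional circular shift of four channel quarters.
op_mdfs <- function(x, s, ctx) {
  d <- dim(x$v)
  C <- d[2L]; H <- d[3L]; W <- d[4L]
  if (C %% 4L != 0L) stop("channel count must be divisible by 4")
  if (abs(s) >= min(H, W)) stop("shift magnitude must be smaller than min(H, W)")
  q <- C %/% 4L
  qs <- lapply(0:3, function(i) i * q + seq_len(q))
  hplus <- roll_index(H, s); hminus <- roll_index(H, -s)
  wplus <- roll_index(W, s); wminus <- roll_index(W, -s)
  y <- x$v
  y[, qs[[1L]], , ] <- x$v[, qs[[1L]], hplus, , drop = FALSE]
  y[, qs[[2L]], , ] <- x$v[, qs[[2L]], hminus, , drop = FALSE]
  y[, qs[[3L]], , ] <- x$v[, qs[[3L]], , wplus, drop = FALSE]
  y[, qs[[4L]], , ] <- x$v[, qs[[4L]], , wminus, drop = FALSE]
  out <- tnode(y)
  if (ctx$grad) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    g <- gy
    g[, qs[[1L]], , ] <- gy[, qs[[1L]], hminus, , drop = FALSE]
    g[, qs[[2L]], , ] <- gy[, qs[[2L]], hplus, , drop = FALSE]
    g[, qs[[3L]], , ] <- gy[, qs[[3L]], , wminus, drop = FALSE]
    g[, qs[[4L]], , ] <- gy[, qs[[4L]], , wplus, drop = FALSE]
    accum_grad(x, g)
  })
  out
}

# ---- Haar decomposition -----------------------------------------------------

# Fixed filter bank; rows = (approx, horizontal, vertical, diagonal),
# columns = window taps ordered (dh fastest, dw next):
# tap1 = (0,0) top-left, tap2 = (1,0) bottom-left,
# tap3 = (0,1) top-right, tap4 = (1,1) bottom-right.
haar_coefs <- function() {
  0.5 * rbind(
    a = c(1,  1,  1, 1),
    h = c(-1, 1, -1, 1),
    v = c(-1, -1, 1, 1),
    d = c(1, -1, -1, 1)
  )
}

op_haar <- function(x, ctx) {
  xv <- x$v; d <- dim(xv)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  if (H < 2L || W < 2L) stop("Haar decomposition needs H >= 2 and W >= 2")
  ci <- conv_cache(H, W, 2L, 2L, 0L)
  cf <- haar_coefs()
  outs <- lapply(1:4, function(i) array(0, c(B, C, ci$Hout, ci$Wout)))
  for (bb in seq_len(B)) {
    xm <- slice_cm(xv, bb)
    taps <- lapply(1:4, function(t) xm[, ci$idx[t, ], drop = FALSE])
    for (f in 1:4) {
      yb <- cf[f, 1L] * taps[[1L]] + cf[f, 2L] * taps[[2L]] +
            cf[f, 3L] * taps[[3L]] + cf[f, 4L] * taps[[4L]]
      outs[[f]][bb, , , ] <- yb
    }
  }
  add_flops(ctx, 2 * 4 * 4 * C * ci$L * B)
  nodes <- lapply(outs, tnode)
  if (ctx$grad) ctx_push(ctx, function() {
    if (all(vapply(nodes, function(n) is.null(n$g), TRUE))) return(invisible(NULL))
    dx <- array(0, d)
    for (bb in seq_len(B)) {
      gs <- lapply(nodes, function(n)
        if (is.null(n$g)) matrix(0, C, ci$L) else slice_cm(n$g, bb))
      dxm <- matrix(0, C, H * W)
      for (t in 1:4) {
        acc <- cf[1L, t] * gs[[1L]] + cf[2L, t] * gs[[2L]] +
               cf[3L, t] * gs[[3L]] + cf[4L, t] * gs[[4L]]
        dxm[, ci$idx[t, ]] <- acc
      }
      dx[bb, , , ] <- dxm
    }
    accum_grad(x, dx)
  })
  names(nodes) <- c("approx", "horiz", "vert", "diag")
  nodes
}

# ---- windowed attention core ------------------------------------------------

# Softmax attention over sliding k x k windows. `q`, `k_`, `v` are same-shape
# (B, C, H, W) nodes; `bias` an optional (k2, k2, heads) parameter. Overlapping
# window outputs are folded back by count-averaging.
op_window_attention <- function(q, k_, v, bias, heads, win, ctx) {
  d <- dim(v$v)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  if (C %% heads != 0L) stop("channels must be divisible by the number of heads")
  if (win > min(H, W)) stop("attention window exceeds spatial extent")
  dh <- C %/% heads
  pad <- (win - 1L) %/% 2L
  ci <- conv_cache(H, W, win, 1L, pad)
  k2 <- win * win
  L <- ci$L
  scl <- 1 / sqrt(dh)
  cnt <- tabulate(ci$idxv, nbins = ci$Hp * ci$Wp)[ci$icol]
  need <- ctx$grad
  y <- array(0, c(B, C, H, W))
  saved <- if (need) vector("list", B)
  gl <- rep(seq_len(L), each = k2)
  slotrows <- lapply(seq_len(k2), function(j) j + k2 * (seq_len(L) - 1L))
  reprow <- rep(seq_len(L), each = k2)
  for (bb in seq_len(B)) {
    qp <- pad_zero(slice_cm(q$v, bb), ci)
    kp <- pad_zero(slice_cm(k_$v, bb), ci)
    vp <- pad_zero(slice_cm(v$v, bb), ci)
    sv <- if (need) vector("list", heads)
    for (hh in seq_len(heads)) {
      rr <- (hh - 1L) * dh + seq_len(dh)
      unf <- function(m) {
        A <- m[rr, ci$idxv, drop = FALSE]
        dim(A) <- c(dh, k2 * L)
        t(A)                                   # rows (slot, window), slot fastest
      }
      Qm <- unf(qp); Km <- unf(kp); Vm <- unf(vp)
      S <- matrix(0, k2 * L, k2)
      for (j in seq_len(k2)) {
        Kr <- Km[slotrows[[j]], , drop = FALSE][reprow, , drop = FALSE]
        S[, j] <- rowSums(Qm * Kr) * scl
        if (!is.null(bias)) S[, j] <- S[, j] + rep(bias$v[, j, hh], times = L)
      }
      A <- exp(S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))])
      A <- A / rowSums(A)
      O <- matrix(0, k2 * L, dh)
      for (j in seq_len(k2)) {
        Vr <- Vm[slotrows[[j]], , drop = FALSE][reprow, , drop = FALSE]
        O <- O + A[, j] * Vr
      }
      opad <- matrix(0, dh, ci$Hp * ci$Wp)
      for (i in seq_len(k2)) {
        cc <- ci$idx[i, ]
        opad[, cc] <- opad[, cc] + t(O[slotrows[[i]], , drop = FALSE])
      }
      y[bb, rr, , ] <- opad[, ci$icol, drop = FALSE] / rep(cnt, each = dh)
      if (need) sv[[hh]] <- list(Qm = Qm, Km = Km, Vm = Vm, A = A)
    }
    if (need) saved[[bb]] <- sv
  }
  add_flops(ctx, B * heads * (4 * k2 * k2 * dh * L + 5 * k2 * k2 * L))
  out <- tnode(y)
  if (need) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dq <- array(0, d); dk <- array(0, d); dv <- array(0, d)
    dbias <- if (!is.null(bias)) array(0, dim(bias$v))
    for (bb in seq_len(B)) {
      gym <- slice_cm(gy, bb)
      dqp <- matrix(0, C, ci$Hp * ci$Wp)
      dkp <- matrix(0, C, ci$Hp * ci$Wp)
      dvp <- matrix(0, C, ci$Hp * ci$Wp)
      for (hh in seq_len(heads)) {
        rr <- (hh - 1L) * dh + seq_len(dh)
        st <- saved[[bb]][[hh]]
        gop <- matrix(0, dh, ci$Hp * ci$Wp)
        gop[, ci$icol] <- gym[rr, , drop = FALSE] / rep(cnt, each = dh)
        dO <- matrix(0, k2 * L, dh)
        for (i in seq_len(k2)) dO[slotrows[[i]], ] <- t(gop[, ci$idx[i, ], drop = FALSE])
        dA <- matrix(0, k2 * L, k2)
        dVm <- matrix(0, k2 * L, dh)
        for (j in seq_len(k2)) {
          Vr <- st$Vm[slotrows[[j]], , drop = FALSE][reprow, , drop = FALSE]
          dA[, j] <- rowSums(dO * Vr)
          dVm[slotrows[[j]], ] <- rowsum(st$A[, j] * dO, gl)
        }
        dS <- st$A * (dA - rowSums(dA * st$A))
        if (!is.null(bias)) {
          irow <- rep(seq_len(k2), times = L)
          for (j in seq_len(k2))
            dbias[, j, hh] <- dbias[, j, hh] + rowsum(dS[, j], irow)
        }
        dQm <- matrix(0, k2 * L, dh)
        dKm <- matrix(0, k2 * L, dh)
        for (j in seq_len(k2)) {
          Kr <- st$Km[slotrows[[j]], , drop = FALSE][reprow, , drop = FALSE]
          dQm <- dQm + (dS[, j] * scl) * Kr
          dKm[slotrows[[j]], ] <- rowsum((dS[, j] * scl) * st$Qm, gl)
        }
        fold_back <- function(M, acc) {
          # M rows (slot, window) -> scatter into padded gradient rows rr
          dim_t <- t(M)                         # (dh, k2*L)
          dim(dim_t) <- c(dh, k2, L)
          for (t in seq_len(k2)) {
            cc <- ci$idx[t, ]
            acc[rr, cc] <- acc[rr, cc] + dim_t[, t, ]
          }
          acc
        }
        dqp <- fold_back(dQm, dqp)
        dkp <- fold_back(dKm, dkp)
        dvp <- fold_back(dVm, dvp)
      }
      dq[bb, , , ] <- dqp[, ci$icol, drop = FALSE]
      dk[bb, , , ] <- dkp[, ci$icol, drop = FALSE]
      dv[bb, , , ] <- dvp[, ci$icol, drop = FALSE]
    }
    accum_grad(q, dq); accum_grad(k_, dk); accum_grad(v, dv)
    if (!is.null(bias)) accum_grad(bias, dbias)
  })
  out
}

op_sub <- function(a, b, ctx) {
  out <- tnode(a$v - b$v)
  add_flops(ctx, length(a$v))
  if (ctx$grad) ctx_push(ctx, function() {
    if (is.null(out$g)) return(invisible(NULL))
    accum_grad(a, out$g)
    accum_grad(b, -out$g)
  })
  out
}

# Global (all-positions) multi-head attention used by the baseline terminal
# stage. q, k have heads*key_dim channels; v has heads*head_dim channels.
op_global_attention <- function(q, k_, v, heads, ctx) {
  dq <- dim(q$v); dv <- dim(v$v)
  B <- dq[1L]; HW <- dq[3L] * dq[4L]
  kd <- dq[2L] %/% heads
  dh <- dv[2L] %/% heads
  scl <- 1 / sqrt(kd)
  need <- ctx$grad
  y <- array(0, dv)
  saved <- if (need) vector("list", B)
  for (bb in seq_len(B)) {
    qm <- slice_cm(q$v, bb); km <- slice_cm(k_$v, bb); vm <- slice_cm(v$v, bb)
    sv <- if (need) vector("list", heads)
    for (hh in seq_len(heads)) {
      rq <- (hh - 1L) * kd + seq_len(kd)
      rv <- (hh - 1L) * dh + seq_len(dh)
      S <- crossprod(qm[rq, , drop = FALSE], km[rq, , drop = FALSE]) * scl
      A <- exp(S - S[cbind(seq_len(HW), max.col(S, ties.method = "first"))])
      A <- A / rowSums(A)
      y[bb, rv, , ] <- vm[rv, , drop = FALSE] %*% t(A)
      if (need) sv[[hh]] <- A
    }
    if (need) saved[[bb]] <- sv
  }
  add_flops(ctx, B * heads * (2 * HW * HW * kd + 2 * HW * HW * dh + 5 * HW * HW))
  out <- tnode(y)
  if (need) ctx_push(ctx, function() {
    gy <- out$g; if (is.null(gy)) return(invisible(NULL))
    dqa <- array(0, dq); dka <- array(0, dq); dva <- array(0, dv)
    for (bb in seq_len(B)) {
      qm <- slice_cm(q$v, bb); km <- slice_cm(k_$v, bb); vm <- slice_cm(v$v, bb)
      gym <- slice_cm(gy, bb)
      for (hh in seq_len(heads)) {
        rq <- (hh - 1L) * kd + seq_len(kd)
        rv <- (hh - 1L) * dh + seq_len(dh)
        A <- saved[[bb]][[hh]]
        go <- gym[rv, , drop = FALSE]
        dva[bb, rv, , ] <- go %*% A
        dA <- crossprod(go, vm[rv, , drop = FALSE])
        dS <- A * (dA - rowSums(dA * A))
        dqa[bb, rq, , ] <- km[rq, , drop = FALSE] %*% t(dS) * scl
        dka[bb, rq, , ] <- qm[rq, , drop = FALSE] %*% dS * scl
      }
    }
    accum_grad(q, dqa); accum_grad(k_, dka); accum_grad(v, dva)
  })
  out
}
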