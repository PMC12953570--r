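# Frequency-domain dual-attention block: exact Haar algebra (derived from the
# printed half-scaled coefficient grids), energy conservation, perfect
# reconstruction, attention normalisation, frozen filters.

test_that("Haar filter bank is orthonormal and matches the printed coefficients", {
  cf <- edgewave:::haar_coefs()
  expect_equal(unname(cf %*% t(cf)), diag(4))   # Gram matrix = identity, exactly
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, , ] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  sb <- haar_decompose(x)
  expect_equal(as.numeric(sb$approx), 5)
  expect_equal(as.numeric(sb$horiz), 2)
  expect_equal(as.numeric(sb$vert), 1)
  expect_equal(as.numeric(sb$diag), 0)
  # energy check: 1+4+9+16 = 30 = 25+4+1+0
  expect_equal(sum(vapply(sb, function(s) sum(s^2), 0)), 30)
  # constants are annihilated by the high-pass filters
  xc <- array(3, c(1, 2, 4, 4))
  sbc <- haar_decompose(xc)
  expect_equal(max(abs(sbc$approx - 6)), 0)
  expect_equal(max(abs(sbc$horiz)), 0)
  expect_equal(max(abs(sbc$vert)), 0)
  expect_equal(max(abs(sbc$diag)), 0)
  expect_error(haar_decompose(array(1, c(1, 1, 1, 4))), "H >= 2")
})

test_that("Haar decomposition conserves energy and reconstructs exactly on even dims", {
  for (seed in 1:5) {
    x <- rand_fm(1, 3, 8, 8, seed = seed)
    sb <- haar_decompose(x)
    expect_lt(abs(sum(vapply(sb, function(s) sum(s^2), 0)) - sum(x^2)) / sum(x^2), 1e-5)
    expect_lt(max(abs(haar_reconstruct(sb) - x)), 1e-6)
  }
  # inverse of the printed single-block example
  sb1 <- list(approx = array(5, c(1, 1, 1, 1)), horiz = array(2, c(1, 1, 1, 1)),
              vert = array(1, c(1, 1, 1, 1)), diag = array(0, c(1, 1, 1, 1)))
  expect_equal(haar_reconstruct(sb1)[1, 1, , ],
               matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  zero <- lapply(sb1, function(s) s * 0)
  expect_true(all(haar_reconstruct(zero) == 0))
  bad <- sb1; bad$diag <- array(0, c(1, 1, 2, 2))
  expect_error(haar_reconstruct(bad), "identical shape")
})

test_that("subband fusion sums the high-pass bands and is linear", {
  sb <- list(approx = array(5, c(1, 1, 2, 2)), horiz = array(2, c(1, 1, 2, 2)),
             vert = array(1, c(1, 1, 2, 2)), diag = array(0, c(1, 1, 2, 2)))
  f <- subband_fuse(sb)
  expect_equal(max(abs(f$f_high - 3)), 0)
  expect_equal(max(abs(f$f_low - 5)), 0)
  # linearity
  f2 <- subband_fuse(lapply(sb, function(s) 2.5 * s))
  expect_equal(f2$f_high, 2.5 * f$f_high)
  expect_equal(f2$f_low, 2.5 * f$f_low)
  # constant input has zero high-frequency content
  fc <- subband_fuse(haar_decompose(array(1.7, c(1, 2, 4, 4))))
  expect_equal(max(abs(fc$f_high)), 0)
})

test_that("windowed attention is normalised: constant values pass through, k=1 is exact", {
  set.seed(31)
  guide <- rand_fm(1, 8, 5, 6)
  v <- rand_fm(1, 8, 5, 6)
  # rows sum to one + count-averaged fold => constant V maps to itself away
  # from borders (zero-padded window slots dilute border positions)
  vc <- array(0.7, c(1, 8, 5, 6))
  yc <- windowed_attention(guide, vc, heads = 4L, window = 3L)
  expect_lt(max(abs(yc[1, , 3, 3:4] - 0.7)), 1e-6)
  # zero guide => uniform attention => output is the windowed mean of V
  y0 <- windowed_attention(guide * 0, v, heads = 1L, window = 3L)
  oracle <- v * 0
  for (i in 1:5) for (j in 1:6) {
    # windows (stride 1, zero pad) containing (i, j), uniform slot weights
    acc <- numeric(8); cnt <- 0
    for (ci in (i - 1):(i + 1)) for (cj in (j - 1):(j + 1)) {
      if (ci < 1 || ci > 5 || cj < 1 || cj > 6) next
      wm <- numeric(8)
      for (wi in (ci - 1):(ci + 1)) for (wj in (cj - 1):(cj + 1)) {
        if (wi >= 1 && wi <= 5 && wj >= 1 && wj <= 6) wm <- wm + v[1, , wi, wj]
      }
      acc <- acc + wm / 9
      cnt <- cnt + 1
    }
    oracle[1, , i, j] <- acc / cnt
  }
  expect_lt(max(abs(y0 - oracle)), 1e-8)
  # degenerate window: attention is the 1x1 identity
  expect_equal(windowed_attention(guide, v, heads = 2L, window = 1L), v)
  expect_error(windowed_attention(guide, v, heads = 3L, window = 3L), "divisible")
  expect_error(windowed_attention(guide, v, heads = 2L, window = 9L), "exceeds")
})

test_that("BAFE block keeps its shape, its frozen filters, and numerical stability", {
  blk <- edgewave:::with_seed(17, function() bafe_block(16L, heads = 4L, window = 3L))
  x <- rand_fm(1, 16, 8, 8, seed = 18)
  y <- bafe_forward(x, blk)
  expect_identical(dim(y), dim(x))
  # five optimisation steps leave the Haar coefficients untouched
  before <- blk$pars$haar$v
  for (i in 1:5) {
    ctx <- edgewave:::new_ctx(grad = TRUE, training = TRUE)
    out <- blk$fwd(blk, edgewave:::tnode(x), ctx)
    loss <- edgewave:::tnode(sum(out$v^2))
    edgewave:::ctx_push(ctx, function() edgewave:::accum_grad(out, 2 * out$v))
    edgewave:::backward(ctx, loss)
    edgewave:::sgd_step(blk, 0.01)
    edgewave:::zero_grads(blk)
  }
  expect_identical(blk$pars$haar$v, before)
  # adversarial amplitude stays finite
  xa <- rand_fm(1, 16, 8, 8, seed = 19) * 1e3
  expect_true(all(is.finite(bafe_forward(xa, blk))))
  expect_error(bafe_forward(array(1, c(1, 16, 1, 1)), blk), "H >= 2")
})
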