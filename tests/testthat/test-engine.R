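# The autodiff engine: backward passes of the core tensor ops must agree
# with central finite differences, and the module bookkeeping (parameter
# counting, SGD state) must behave.

loss_of <- function(y) sum(sin(y))
dloss <- function(y) cos(y)

run_backward <- function(make_out, x) {
  ctx <- edgewave:::new_ctx(grad = TRUE, training = TRUE)
  xn <- edgewave:::tnode(x)
  out <- make_out(xn, ctx)
  out$g <- array(dloss(out$v), dim(out$v))
  if (ctx$n > 0L) for (i in rev(seq_len(ctx$n))) ctx$tape[[i]]()
  xn$g
}

test_that("convolution, depthwise and batch-norm gradients match finite differences", {
  set.seed(101)
  x <- array(rnorm(2 * 3 * 6 * 5), c(2, 3, 6, 5))
  w <- edgewave:::param_tensor(array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4)))
  b <- edgewave:::param_tensor(rnorm(4))
  g <- run_backward(function(xn, ctx) edgewave:::op_conv(xn, w, b, 2L, 1L, ctx), x)
  fn <- function(xx) loss_of(edgewave:::op_conv(edgewave:::tnode(xx), w, b, 2L, 1L,
                                                edgewave:::new_ctx())$v)
  expect_lt(max_rel_err(g, num_grad(fn, x)), 1e-6)
  expect_lt(max_rel_err(w$g, num_grad(function(ww) {
    loss_of(edgewave:::op_conv(edgewave:::tnode(x), edgewave:::param_tensor(ww),
                               b, 2L, 1L, edgewave:::new_ctx())$v)
  }, w$v)), 1e-6)

  wd <- edgewave:::param_tensor(array(rnorm(3 * 3 * 3) * 0.4, c(3, 3, 3)))
  g <- run_backward(function(xn, ctx) edgewave:::op_dwconv(xn, wd, NULL, 1L, 1L, ctx), x)
  fn <- function(xx) loss_of(edgewave:::op_dwconv(edgewave:::tnode(xx), wd, NULL, 1L, 1L,
                                                  edgewave:::new_ctx())$v)
  expect_lt(max_rel_err(g, num_grad(fn, x)), 1e-6)

  bn <- edgewave:::bn_module(3)
  mkbn <- function() { b2 <- edgewave:::bn_module(3); b2 }
  g <- run_backward(function(xn, ctx) edgewave:::op_bn(xn, bn, ctx), x)
  fn <- function(xx) {
    ctx <- edgewave:::new_ctx(grad = FALSE, training = TRUE)
    loss_of(edgewave:::op_bn(edgewave:::tnode(xx), mkbn(), ctx)$v)
  }
  expect_lt(max_rel_err(g, num_grad(fn, x)), 1e-4)
})

test_that("pooling, resampling and attention gradients match finite differences", {
  set.seed(102)
  x <- array(rnorm(1 * 2 * 6 * 6), c(1, 2, 6, 6))
  cases <- list(
    maxpool = function(xn, ctx) edgewave:::op_maxpool(xn, 3L, 1L, 1L, ctx),
    avg3rep = function(xn, ctx) edgewave:::op_avgpool3_rep(xn, ctx),
    adaptive = function(xn, ctx) edgewave:::op_adaptive_avgpool(xn, 4L, ctx),
    bilinear = function(xn, ctx) edgewave:::op_upsample_bilinear(xn, 9L, 13L, ctx),
    nearest = function(xn, ctx) edgewave:::op_upsample_nearest(xn, 12L, 12L, ctx)
  )
  for (nm in names(cases)) {
    g <- run_backward(cases[[nm]], x)
    fn <- function(xx) loss_of(cases[[nm]](edgewave:::tnode(xx), edgewave:::new_ctx())$v)
    expect_lt(max_rel_err(g, num_grad(fn, x)), 1e-6, label = nm)
  }

  qv <- array(rnorm(1 * 8 * 4 * 5) * 0.5, c(1, 8, 4, 5))
  kv <- array(rnorm(1 * 8 * 4 * 5) * 0.5, c(1, 8, 4, 5))
  vv <- array(rnorm(1 * 8 * 4 * 5) * 0.5, c(1, 8, 4, 5))
  bias <- edgewave:::param_tensor(array(rnorm(9 * 9 * 2) * 0.1, c(9, 9, 2)))
  ctx <- edgewave:::new_ctx(grad = TRUE)
  qn <- edgewave:::tnode(qv); kn <- edgewave:::tnode(kv); vn <- edgewave:::tnode(vv)
  o <- edgewave:::op_window_attention(qn, kn, vn, bias, 2L, 3L, ctx)
  o$g <- array(dloss(o$v), dim(o$v))
  for (i in rev(seq_len(ctx$n))) ctx$tape[[i]]()
  att <- function(q, k, v, b) edgewave:::op_window_attention(
    edgewave:::tnode(q), edgewave:::tnode(k), edgewave:::tnode(v),
    edgewave:::param_tensor(b), 2L, 3L, edgewave:::new_ctx())$v
  expect_lt(max_rel_err(qn$g, num_grad(function(z) loss_of(att(z, kv, vv, bias$v)), qv)), 1e-5)
  expect_lt(max_rel_err(kn$g, num_grad(function(z) loss_of(att(qv, z, vv, bias$v)), kv)), 1e-5)
  expect_lt(max_rel_err(vn$g, num_grad(function(z) loss_of(att(qv, kv, z, bias$v)), vv)), 1e-5)
  expect_lt(max_rel_err(bias$g, num_grad(function(z) loss_of(att(qv, kv, vv, z)), bias$v)), 1e-5)
})

test_that("parameter accounting separates trainable from frozen and SGD moves only the former", {
  m <- bafe_block(8L, heads = 2L, window = 3L)
  p <- count_params(m)
  expect_gt(p$n_trainable, 0)
  expect_equal(p$n_frozen, 16)       # the four 2x2 Haar grids
  haar_before <- m$pars$haar$v
  w_before <- m$sub$phi_in$pars$w$v
  x <- rand_fm(1, 8, 8, 8, seed = 5)
  ctx <- edgewave:::new_ctx(grad = TRUE, training = TRUE)
  out <- m$fwd(m, edgewave:::tnode(x), ctx)
  loss <- edgewave:::tnode(sum(out$v^2))
  edgewave:::ctx_push(ctx, function() edgewave:::accum_grad(out, 2 * out$v * loss$g))
  edgewave:::backward(ctx, loss)
  edgewave:::sgd_step(m, lr = 0.05)
  expect_identical(m$pars$haar$v, haar_before)
  expect_false(identical(m$sub$phi_in$pars$w$v, w_before))
})

test_that("feature map contract rejects malformed input", {
  expect_error(check_feature_map(matrix(1, 2, 2)), "rank-4")
  bad <- array(1, c(1, 2, 3, 3)); bad[1, 1, 1, 1] <- NaN
  expect_error(check_feature_map(bad), "finite")
  expect_silent(check_feature_map(array(0, c(1, 1, 1, 1))))
})
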