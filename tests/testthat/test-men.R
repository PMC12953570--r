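# Edge-enhancement backbone blocks: hand-computed oracles for the edge gate
# and adaptive pooling, elementwise bounds, and channel bookkeeping.

test_that("edge gate matches the hand 3x3-average-pool + sigmoid oracle", {
  # single unit pixel on a zero background, H = identity 1x1 conv, BN identity
  ee <- edgewave:::with_seed(1, function() edge_enhancer(1L))
  ee$sub$h$pars$w$v[] <- 1
  set_bn_identity(ee$sub$h$sub$bn)
  x <- array(0, c(1, 1, 5, 5)); x[1, 1, 3, 3] <- 1
  y <- edge_enhance(x, ee)
  expect_equal(y[1, 1, 3, 3], 1 + stats::plogis(1 - 1 / 9), tolerance = 1e-10)
  expect_equal(y[1, 1, 3, 3], 1.70861, tolerance = 1e-4)
  expect_equal(y[1, 1, 1, 1], 0)   # zero input stays zero
})

test_that("edge enhancement is elementwise bounded on positive input and constant-preserving", {
  ee <- edgewave:::with_seed(2, function() edge_enhancer(3L))
  for (rep in 1:5) {
    x <- abs(rand_fm(2, 3, 7, 6, seed = rep)) + 0.01
    y <- edge_enhance(x, ee)
    expect_true(all(y >= x))
    expect_true(all(y < 2 * x))
  }
  # spatially constant map: zero edge signal, constant output per channel
  xc <- array(0, c(1, 3, 6, 6))
  xc[1, 1, , ] <- 0.5; xc[1, 2, , ] <- 1.5; xc[1, 3, , ] <- 0.25
  yc <- edge_enhance(xc, ee)
  for (cc in 1:3)
    expect_equal(max(abs(yc[1, cc, , ] - yc[1, cc, 1, 1])), 0)
  # non-finite input rejected
  xb <- xc; xb[1, 1, 1, 1] <- Inf
  expect_error(edge_enhance(xb, ee), "finite")
})

test_that("adaptive pooling matches the explicit window-average oracle", {
  # 6x6 iota (row-major) pooled to 3x3 averages disjoint 2x2 windows
  m <- matrix(0:35, 6, 6, byrow = TRUE)
  x <- array(0, c(1, 1, 6, 6)); x[1, 1, , ] <- m
  got <- adaptive_avg_pool(x, 3L)[1, 1, , ]
  want <- matrix(c(3.5, 5.5, 7.5, 15.5, 17.5, 19.5, 27.5, 29.5, 31.5),
                 3, 3, byrow = TRUE)
  expect_equal(got, want)
  # brute-force oracle on an uneven 7x5 -> 3 partition
  x2 <- rand_fm(1, 2, 7, 5, seed = 9)
  got2 <- adaptive_avg_pool(x2, 3L)
  for (i in 1:3) for (j in 1:3) {
    hh <- (floor((i - 1) * 7 / 3) + 1):ceiling(i * 7 / 3)
    ww <- (floor((j - 1) * 5 / 3) + 1):ceiling(j * 5 / 3)
    for (cc in 1:2)
      expect_equal(got2[1, cc, i, j], mean(x2[1, cc, hh, ww]))
  }
})

test_that("MSF preserves shape, concatenates all branches, and rejects oversized scales", {
  msf <- edgewave:::with_seed(3, function() msf_unit(16L, c(3L, 6L, 9L, 12L)))
  x <- rand_fm(1, 16, 32, 32, seed = 4)
  y <- forward(msf, x)
  expect_identical(dim(y), dim(x))
  # 5 branches (local + 4 scales) concatenated before the 1x1 fusion
  expect_identical(dim(msf$sub$fuse$pars$w$v)[1], 5L * 16L)
  expect_error(forward(msf, rand_fm(1, 16, 10, 10)), "scale")
  # constant input stays constant through the pooled branch
  xc <- array(2.5, c(1, 4, 8, 8))
  expect_equal(max(abs(adaptive_avg_pool(xc, 1L) - 2.5)), 0)
})

test_that("dual-path unit honours the shape contract and both paths carry gradient signal", {
  dp <- edgewave:::with_seed(5, function() dpm_unit(32L, n_msf = 1L, scales = c(2L, 4L)))
  x <- rand_fm(1, 32, 16, 16, seed = 6)
  y <- forward(dp, x)
  expect_identical(dim(y), c(1L, 32L, 16L, 16L))
  # zero MSF units: E is the identity chain
  dp0 <- edgewave:::with_seed(5, function() dpm_unit(8L, n_msf = 0L))
  y0 <- forward(dp0, rand_fm(1, 8, 6, 6, seed = 7))
  expect_identical(dim(y0), c(1L, 8L, 6L, 6L))
  # sensitivity: perturbing only Q's weights changes the output
  y1 <- forward(dp, x)
  dp$sub$q$pars$w$v <- dp$sub$q$pars$w$v + 0.1
  y2 <- forward(dp, x)
  expect_gt(max(abs(y2 - y1)), 0)
})

test_that("MEN block keeps CSP channel bookkeeping and survives zeroed weights", {
  blk <- edgewave:::with_seed(8, function()
    men_block(64L, 64L, n_units = 2L, split_channels = 16L, scales = c(2L, 4L)))
  # concat before fusion: 16 + 16 + 16 + 16 = 64 channels
  expect_identical(dim(blk$sub$fuse$pars$w$v)[1], 64L)
  x <- rand_fm(1, 64, 16, 16, seed = 9)
  expect_identical(dim(forward(blk, x)), c(1L, 64L, 16L, 16L))
  # degenerate n = 0: plain CSP shortcut
  blk0 <- edgewave:::with_seed(8, function() men_block(16L, 32L, n_units = 0L))
  expect_identical(dim(forward(blk0, rand_fm(1, 16, 8, 8, seed = 1))),
                   c(1L, 32L, 8L, 8L))
  expect_identical(dim(blk0$sub$fuse$pars$w$v)[1], 32L)
  # wrong input channels rejected; odd split rejected
  expect_error(forward(blk, rand_fm(1, 32, 16, 16)), "channels")
  expect_error(men_block(16L, 16L, n_units = 1L, split_channels = 7L), "even")
  # all-zero weights still give a finite map
  edgewave:::walk_params(blk, function(p) if (p$trainable) p$v[] <- 0)
  yz <- forward(blk, x)
  expect_true(all(is.finite(yz)))
})

test_that("MEN, MSF and DPM preserve spatial dims across random valid shapes", {
  for (seed in 1:3) {
    sh <- edgewave:::with_seed(seed, function()
      list(H = sample(8:14, 1), W = sample(8:14, 1), C = sample(c(8L, 16L), 1)))
    x <- rand_fm(1, sh$C, sh$H, sh$W, seed = seed + 10)
    msf <- edgewave:::with_seed(seed, function() msf_unit(sh$C, c(2L, 4L)))
    expect_identical(dim(forward(msf, x)), dim(x))
    blk <- edgewave:::with_seed(seed, function()
      men_block(sh$C, sh$C, 1L, split_channels = sh$C %/% 2L, scales = c(2L, 4L)))
    expect_identical(dim(forward(blk, x)), dim(x))
  }
})
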