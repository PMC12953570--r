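# Shared fixtures: random feature maps, central-difference gradients, and the
# tiny desk-scale model configuration used by training tests.

rand_fm <- function(B, C, H, W, sd = 1, seed = NULL) {
  gen <- function() array(stats::rnorm(B * C * H * W, sd = sd), c(B, C, H, W))
  if (is.null(seed)) gen() else edgewave:::with_seed(seed, gen)
}

num_grad <- function(fn, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(got, want) {
  max(abs(got - want)) / max(1, max(abs(want)))
}

# force a conv/BN unit to the exact identity in running-statistics mode
set_bn_identity <- function(bn) {
  bn$pars$gamma$v[] <- 1
  bn$pars$beta$v[] <- 0
  bn$rm[] <- 0
  bn$rv[] <- 1
  bn$eps <- 0
  invisible(bn)
}

tiny_full_config <- function(num_classes = 3L) {
  model_config(men = TRUE, bafe = TRUE, embfpn = TRUE, scau = TRUE,
               num_classes = num_classes, input_size = 96L,
               widths = c(8L, 16L, 16L, 32L, 32L), neck_width = 16L,
               men_scales = list(c(2L, 4L), c(2L, 4L), c(2L, 3L), c(1L, 2L)))
}

tiny_baseline_config <- function(num_classes = 3L, input_size = 64L) {
  model_config(num_classes = num_classes, input_size = input_size,
               widths = c(8L, 16L, 16L, 32L, 32L), neck_width = 16L)
}

easy_scene_spec <- function(seed = 42L) {
  scene_spec(image_size = 96L, num_classes = 3L, objects_per_image = c(1L, 3L),
             object_size_px = c(16L, 32L), contrast = "high", seed = seed)
}
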