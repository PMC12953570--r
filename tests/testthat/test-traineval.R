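# Decoding, matching and mAP arithmetic against hand-enumerated oracles, and
# smoke-training behaviour (determinism, frozen optimiser, convergence trend).

mk_gt <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(class_id = r[1], cx = r[2], cy = r[3], w = r[4], h = r[5])))
}

test_that("a perfect detector scores 1.0 and an empty one scores 0", {
  gt <- list(mk_gt(c(0, 0.3, 0.3, 0.2, 0.2), c(1, 0.7, 0.7, 0.1, 0.1)),
             mk_gt(c(0, 0.5, 0.5, 0.3, 0.3)))
  perfect <- lapply(gt, function(g) { g$confidence <- 1.0; g })
  ev <- evaluate_detections(perfect, gt)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map50_95, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  none <- lapply(gt, function(g) g[0, c(names(g))][, c(1:5)])
  none <- lapply(none, function(g) { g$confidence <- numeric(0); g })
  ev0 <- evaluate_detections(none, gt)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$map50, 0)
})

test_that("a single IoU-0.61 match is a TP at thresholds .50-.60 only: mAP@50-95 = 3/10", {
  gt <- list(mk_gt(c(0, 0.3, 0.3, 0.2, 0.2)))
  det <- gt[[1]]
  det$cx <- det$cx + 0.048          # IoU = 0.152/0.248 = 0.6129...
  det$confidence <- 0.9
  ev <- evaluate_detections(list(det), gt)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map50_95, 3 / 10)
})

test_that("evaluation is order-invariant and duplicates never raise AP", {
  gt <- list(mk_gt(c(0, 0.3, 0.3, 0.2, 0.2), c(0, 0.7, 0.7, 0.2, 0.2)))
  det <- gt[[1]]
  det$confidence <- c(0.9, 0.8)
  ev1 <- evaluate_detections(list(det), gt)
  ev2 <- evaluate_detections(list(det[2:1, ]), gt)
  expect_equal(ev1, ev2)
  dup <- rbind(det, transform(det[1, ], confidence = 0.7))
  ev3 <- evaluate_detections(list(dup), gt)
  expect_lte(ev3$map50, ev1$map50)
  expect_lte(ev3$map50_95, ev1$map50_95)
})

test_that("map50 dominates map50_95 on noisy random detections", {
  for (seed in 1:5) {
    sets <- edgewave:::with_seed(seed, function() {
      gt <- list(mk_gt(c(0, 0.3, 0.3, 0.2, 0.2), c(1, 0.6, 0.6, 0.2, 0.2)))
      det <- do.call(rbind, lapply(1:6, function(i) {
        data.frame(class_id = sample(0:1, 1), cx = runif(1, 0.2, 0.8),
                   cy = runif(1, 0.2, 0.8), w = 0.2, h = 0.2,
                   confidence = runif(1))
      }))
      list(gt = gt, det = det)
    })
    ev <- evaluate_detections(list(sets$det), sets$gt)
    expect_gte(ev$map50, ev$map50_95)
    expect_gte(ev$map50, 0); expect_lte(ev$map50, 1)
  }
  # empty ground truth with nonempty detections stays defined
  det <- data.frame(class_id = 0, cx = .5, cy = .5, w = .1, h = .1, confidence = .9)
  ev <- evaluate_detections(list(det), list(NULL))
  expect_equal(ev$map50, 0)
  expect_equal(ev$recall, 0)
})

test_that("decoding follows the cell arithmetic and NMS keeps the top-confidence survivor", {
  reg_max <- 16L
  box <- array(0, c(1, 64, 4, 4)); cls <- array(-20, c(1, 3, 4, 4))
  spike <- function(bins) { z <- rep(-20, reg_max); z[bins + 1L] <- 20; z }
  # cell (1,1): distances (0.5, 0.5, 1.5, 1.5) -> box x:[0,.5] y:[0,.5]
  box[1, , 1, 1] <- c(spike(0:1), spike(0:1), spike(1:2), spike(1:2))
  cls[1, 3, 1, 1] <- 3
  # cell (1,2): distances (1.5, 0.5, 0.5, 1.5) -> identical box, lower confidence
  box[1, , 1, 2] <- c(spike(1:2), spike(0:1), spike(0:1), spike(1:2))
  cls[1, 3, 1, 2] <- 2
  dets <- decode_predictions(list(list(box = box, cls = cls)),
                             conf_thresh = 0.25, iou_thresh = 0.5)
  expect_identical(nrow(dets), 1L)
  expect_equal(dets$confidence, stats::plogis(3), tolerance = 1e-6)
  expect_equal(dets$class_id, 2)
  expect_equal(as.numeric(dets[1, c("cx", "cy", "w", "h")]), c(0.25, 0.25, 0.5, 0.5),
               tolerance = 1e-6)
  # all-suppressed logits give an empty list; bad thresholds are rejected
  expect_identical(nrow(decode_predictions(list(list(box = box, cls = cls * 0 - 30)),
                                           0.25, 0.5)), 0L)
  expect_error(decode_predictions(list(), conf_thresh = 1.5), "\\[0, 1\\]")
})

test_that("a zero learning rate freezes the loss and identical seeds reproduce the trace", {
  sp <- scene_spec(64L, 2L, c(1L, 2L), c(12L, 24L), "high", seed = 30L)
  ds <- lapply(1:2, function(i) {
    s <- generate_scene(sp, i); list(image = s$image, annotations = s$annotations)
  })
  cfg0 <- train_config(epochs = 3L, batch_size = 2L, lr = 0, image_size = 64L)
  m <- build_model(tiny_baseline_config(2L, 64L), seed = 60)
  tr <- smoke_train(m, ds, cfg0, seed = 1)
  expect_length(tr, 3L)
  expect_lt(max(abs(tr - tr[1])), 1e-9)
  cfg1 <- train_config(epochs = 2L, batch_size = 2L, lr = 0.005, image_size = 64L)
  m1 <- build_model(tiny_baseline_config(2L, 64L), seed = 61)
  m2 <- build_model(tiny_baseline_config(2L, 64L), seed = 61)
  t1 <- smoke_train(m1, ds, cfg1, seed = 2)
  t2 <- smoke_train(m2, ds, cfg1, seed = 2)
  expect_lt(max(abs(t1 - t2)), 1e-6)
})

test_that("fifty smoke steps show a decreasing loss trend on easy scenes", {
  sp <- scene_spec(64L, 2L, c(1L, 2L), c(12L, 24L), "high", seed = 31L)
  ds <- lapply(1:8, function(i) {
    s <- generate_scene(sp, i); list(image = s$image, annotations = s$annotations)
  })
  m <- build_model(tiny_baseline_config(2L, 64L), seed = 62)
  cfg <- train_config(epochs = 25L, batch_size = 4L, image_size = 64L)
  tr <- smoke_train(m, ds, cfg, seed = 3)
  expect_length(tr, 50L)
  expect_true(all(is.finite(tr)))
  expect_lt(mean(tail(tr, 10)), mean(head(tr, 10)))
})
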