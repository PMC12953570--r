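# Scene generator, label I/O and splitting: seeded determinism, tight-box
# geometry, lossless round trips, largest-remainder arithmetic.

test_that("scene generation is a pure function of spec and seed", {
  sp <- easy_scene_spec(seed = 7L)
  a <- generate_scene(sp, 3L)
  b <- generate_scene(sp, 3L)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  d <- generate_scene(easy_scene_spec(seed = 8L), 3L)
  expect_false(identical(a$image, d$image))
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("zero objects gives a background-only scene with an empty annotation list", {
  sp <- scene_spec(image_size = 96L, num_classes = 3L, objects_per_image = 0L,
                   seed = 5L)
  sc <- generate_scene(sp)
  expect_identical(nrow(sc$annotations), 0L)
  expect_identical(dim(sc$image), c(96L, 96L, 3L))
})

test_that("rendered boxes are tight: 20 px circular objects give w = h = 20/640 within tolerance", {
  sp <- scene_spec(image_size = 640L, num_classes = 1L, objects_per_image = 5L,
                   object_size_px = c(20, 20), contrast = "high", seed = 11L)
  sc <- generate_scene(sp)
  expect_identical(nrow(sc$annotations), 5L)
  expect_true(all(abs(sc$annotations$w - 20 / 640) < 0.2 * 20 / 640))
  expect_true(all(abs(sc$annotations$h - 20 / 640) < 0.2 * 20 / 640))
  # every annotation satisfies the box invariants (validated on write)
  tmp <- tempfile(fileext = ".txt")
  expect_silent(write_yolo_labels(sc$annotations, tmp))
  # emitted boxes overlap the intended placement geometry
  for (r in seq_len(5)) {
    expect_lt(abs(sc$annotations$cx[r] - sc$placement$cx[r]), 2 / 640)
    expect_lt(abs(sc$annotations$cy[r] - sc$placement$cy[r]), 2 / 640)
  }
})

test_that("YOLO label lines use the fixed six-decimal dialect and round-trip losslessly", {
  tmp <- tempfile(fileext = ".txt")
  a <- data.frame(class_id = 3L, cx = 0.5, cy = 0.5, w = 0.1, h = 0.2)
  write_yolo_labels(a, tmp)
  expect_identical(readLines(tmp), "3 0.500000 0.500000 0.100000 0.200000")
  # empty set -> empty file
  write_yolo_labels(a[0, ], tmp)
  expect_identical(length(readLines(tmp)), 0L)
  expect_identical(nrow(read_yolo_labels(tmp)), 0L)
  # fuzz: 1000 random valid annotations round-trip at the stated tolerance
  n <- 1000L
  fz <- edgewave:::with_seed(99L, function() {
    w <- runif(n, 0.01, 0.4); h <- runif(n, 0.01, 0.4)
    data.frame(class_id = sample(0:10, n, replace = TRUE),
               cx = runif(n, w / 2, 1 - w / 2), cy = runif(n, h / 2, 1 - h / 2),
               w = w, h = h)
  })
  write_yolo_labels(fz, tmp)
  back <- read_yolo_labels(tmp)
  expect_identical(back$class_id, fz$class_id)
  for (col in c("cx", "cy", "w", "h"))
    expect_lt(max(abs(back[[col]] - fz[[col]])), 5e-7)
})

test_that("malformed label files are rejected with the offending line number", {
  tmp <- tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.5 0.5 0.1"), tmp)
  expect_error(read_yolo_labels(tmp), "line 2.*5 fields")
  writeLines("0 0.5 oops 0.1 0.1", tmp)
  expect_error(read_yolo_labels(tmp), "line 1")
  writeLines("0 0.99 0.5 0.1 0.1", tmp)     # box sticks out of the image
  expect_error(read_yolo_labels(tmp), "outside")
  writeLines("-2 0.5 0.5 0.1 0.1", tmp)
  expect_error(read_yolo_labels(tmp), "class id")
})

test_that("dataset writer produces image/label pairs and a manifest", {
  dir <- file.path(tempdir(), "ew_ds")
  sp <- scene_spec(image_size = 64L, num_classes = 2L, objects_per_image = 1L,
                   object_size_px = c(10, 16), seed = 3L)
  files <- generate_dataset(3L, sp, dir)
  expect_true(all(file.exists(files$image)))
  expect_true(all(file.exists(files$label)))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  img <- png::readPNG(files$image[1])
  expect_identical(dim(img), c(64L, 64L, 3L))
  unlink(dir, recursive = TRUE)
})

test_that("largest-remainder splitting reproduces the printed 8:1:1 arithmetic", {
  sp <- split_dataset(4565L, c(8, 1, 1), seed = 0L)
  expect_identical(lengths(sp), c(train = 3652L, val = 456L, test = 457L))
  expect_identical(lengths(split_dataset(10L, c(8, 1, 1))), c(train = 8L, val = 1L, test = 1L))
})

test_that("splits partition the items, respect quotas within 1, and are reproducible", {
  for (n in c(7L, 101L, 4565L)) {
    sp <- split_dataset(n, c(8, 1, 1), seed = 3L)
    ids <- sort(unname(unlist(sp)))
    expect_identical(ids, seq_len(n))                        # disjoint + complete
    for (i in 1:3) expect_lt(abs(lengths(sp)[i] - n * c(.8, .1, .1)[i]), 1)
  }
  expect_identical(split_dataset(50L, seed = 9L), split_dataset(50L, seed = 9L))
  expect_false(identical(split_dataset(50L, seed = 9L)$train,
                         split_dataset(50L, seed = 10L)$train))
  expect_error(split_dataset(2L, c(8, 1, 1)), "at least 3")
  # stratified option keeps the partition property
  strat <- rep(c("a", "b"), each = 20L)
  sps <- split_dataset(40L, c(8, 1, 1), seed = 1L, stratify = strat)
  expect_identical(sort(unname(unlist(sps))), seq_len(40L))
})
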