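# Synthetic small-pest scene generator, YOLO-format label I/O and
# deterministic ratio splitting. Scenes emulate the field regime the detector
# targets: 640x640 frames, 11 classes, small (10-60 px) targets on textured
# vegetation-like backgrounds, with a low-contrast mode that draws objects
# close to the local background colour. Class appearance is synthetic
# (hue/shape-coded), not entomological.

#' Scene specification
#'
#' @param image_size square scene size in pixels
#' @param num_classes number of object classes
#' @param objects_per_image integer range `c(min, max)`
#' @param object_size_px object long-side range in pixels
#' @param contrast `"low"`, `"med"` or `"high"`: how far object colours sit
#'   from the local background
#' @param seed integer seed; all generator output is a pure function of the
#'   spec including this seed
#' @return list of class `ew_scene_spec`
#' @export
scene_spec <- function(image_size = 640L, num_classes = 11L,
                       objects_per_image = c(3L, 8L),
                       object_size_px = c(10L, 60L),
                       contrast = c("low", "med", "high"),
                       seed = 0L) {
  contrast <- match.arg(contrast)
  if (length(objects_per_image) == 1L) objects_per_image <- rep(objects_per_image, 2L)
  if (length(object_size_px) == 1L) object_size_px <- rep(object_size_px, 2L)
  if (max(object_size_px) >= image_size) stop("object sizes must be smaller than the image")
  if (any(objects_per_image < 0L)) stop("object counts must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 num_classes = as.integer(num_classes),
                 objects_per_image = as.integer(objects_per_image),
                 object_size_px = as.numeric(object_size_px),
                 contrast = contrast, seed = as.integer(seed)),
            class = "ew_scene_spec")
}

# multi-octave value noise in [0, 1], (n x n)
value_noise <- function(n, octaves = c(4L, 8L, 16L, 32L)) {
  acc <- matrix(0, n, n)
  wsum <- 0
  for (i in seq_along(octaves)) {
    g <- octaves[i]
    w <- 1 / 2^(i - 1)
    grid <- array(stats::rnorm(g * g), c(1L, 1L, g, g))
    up <- op_upsample_bilinear(tnode(grid), n, n, new_ctx())$v
    acc <- acc + w * matrix(up, n, n)
    wsum <- wsum + w
  }
  acc <- acc / wsum
  (acc - min(acc)) / (max(acc) - min(acc) + 1e-9)
}

# per-class appearance: hue, aspect ratio, silhouette family
class_style <- function(class_id, num_classes) {
  hue <- ((class_id * 360 / num_classes) + 15) %% 360
  list(hue = hue,
       aspect = 1 + 1.2 * ((class_id * 3L) %% num_classes) / max(1L, num_classes - 1L),
       shape = class_id %% 3L)   # 0 ellipse, 1 rectangle, 2 superellipse
}

#' Generate one synthetic scene
#'
#' Deterministic given the spec (same spec + seed gives a bit-identical image
#' and annotation list). Objects are hue/shape-coded by class, placed without
#' heavy overlap, and each annotation is tight around the rendered extent of
#' its object. In low-contrast mode object colours are pulled most of the way
#' towards the local background.
#'
#' @param spec an `ew_scene_spec`
#' @param index scene index; scenes of a dataset differ by this offset on the
#'   spec seed
#' @return list with `image` (`(H, W, 3)` array in `[0, 1]`), `annotations`
#'   (data frame `class_id, cx, cy, w, h`, normalised center format) and
#'   `placement` (intended geometry log used for QC)
#' @export
generate_scene <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "ew_scene_spec"))
  with_seed(spec$seed + 7919L * as.integer(index), function() {
    n <- spec$image_size
    noise <- value_noise(n)
    noise2 <- value_noise(n)
    img <- array(0, c(n, n, 3L))
    img[, , 1L] <- 0.18 + 0.25 * noise + 0.05 * noise2
    img[, , 2L] <- 0.35 + 0.35 * noise + 0.08 * noise2
    img[, , 3L] <- 0.10 + 0.15 * noise2
    img <- img + array(stats::rnorm(n * n * 3L, sd = 0.015), c(n, n, 3L))
    img <- pmin(pmax(img, 0), 1)

    nobj <- if (spec$objects_per_image[1L] == spec$objects_per_image[2L])
      spec$objects_per_image[1L]
    else sample(spec$objects_per_image[1L]:spec$objects_per_image[2L], 1L)
    ann <- list(); placed <- list(); plog <- list()
    blend <- switch(spec$contrast, low = 0.72, med = 0.45, high = 0.08)
    for (io in seq_len(nobj)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        cls <- sample.int(spec$num_classes, 1L) - 1L
        st <- class_style(cls, spec$num_classes)
        size <- stats::runif(1L, spec$object_size_px[1L], spec$object_size_px[2L])
        a <- size / 2
        b <- a / st$aspect
        th <- stats::runif(1L, 0, pi)
        # per-axis half-extents of the rotated silhouette's bounding box
        ex <- 1.05 * sqrt((a * cos(th))^2 + (b * sin(th))^2)
        ey <- 1.05 * sqrt((a * sin(th))^2 + (b * cos(th))^2)
        if (2 * max(ex, ey) + 4 >= n) next           # cannot fit; retry
        cx <- stats::runif(1L, ex + 1, n - ex - 1)
        cy <- stats::runif(1L, ey + 1, n - ey - 1)
        cand <- c(cx - ex, cy - ey, cx + ex, cy + ey)
        clash <- FALSE
        for (p in placed) {
          ix <- max(0, min(cand[3L], p[3L]) - max(cand[1L], p[1L]))
          iy <- max(0, min(cand[4L], p[4L]) - max(cand[2L], p[2L]))
          inter <- ix * iy
          uni <- (cand[3L] - cand[1L]) * (cand[4L] - cand[2L]) +
                 (p[3L] - p[1L]) * (p[4L] - p[2L]) - inter
          if (inter / uni > 0.05) { clash <- TRUE; break }
        }
        if (clash) next
        # render into the local window
        x0 <- max(1L, floor(cx - ex)); x1 <- min(n, ceiling(cx + ex))
        y0 <- max(1L, floor(cy - ey)); y1 <- min(n, ceiling(cy + ey))
        xs <- x0:x1; ys <- y0:y1
        dx <- outer(rep(1, length(ys)), xs - cx)     # rows = y, cols = x
        dy <- outer(ys - cy, rep(1, length(xs)))
        u <- (dx * cos(th) + dy * sin(th)) / a
        v <- (-dx * sin(th) + dy * cos(th)) / b
        f <- switch(as.character(st$shape),
                    "0" = sqrt(u^2 + v^2),
                    "1" = pmax(abs(u), abs(v)),
                    "2" = (u^4 + v^4)^0.25)
        alpha <- pmin(pmax((1.05 - f) / 0.12, 0), 1)
        if (!any(alpha > 0.5)) next
        col <- grDevices::col2rgb(grDevices::hsv(st$hue / 360,
                                                 0.85, 0.85)) / 255
        patch_r <- img[ys, xs, 1L]; patch_g <- img[ys, xs, 2L]; patch_b <- img[ys, xs, 3L]
        bgm <- c(mean(patch_r), mean(patch_g), mean(patch_b))
        oc <- (1 - blend) * col[, 1L] + blend * bgm
        shade <- 1 - 0.25 * (f * (f <= 1))          # mild interior shading
        img[ys, xs, 1L] <- patch_r * (1 - alpha) + oc[1L] * shade * alpha
        img[ys, xs, 2L] <- patch_g * (1 - alpha) + oc[2L] * shade * alpha
        img[ys, xs, 3L] <- patch_b * (1 - alpha) + oc[3L] * shade * alpha
        # tight box from the rendered extent
        core <- alpha > 0.5
        rx <- range(xs[colSums(core) > 0]); ry <- range(ys[rowSums(core) > 0])
        bw <- (rx[2L] - rx[1L] + 1) / n; bh <- (ry[2L] - ry[1L] + 1) / n
        bcx <- (rx[1L] + rx[2L]) / 2 / n; bcy <- (ry[1L] + ry[2L]) / 2 / n
        ann[[length(ann) + 1L]] <- data.frame(class_id = cls, cx = bcx, cy = bcy,
                                              w = bw, h = bh)
        plog[[length(plog) + 1L]] <- data.frame(class_id = cls, cx = cx / n,
                                                cy = cy / n, size_px = size,
                                                theta = th)
        placed[[length(placed) + 1L]] <- cand
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible packing: could not place object after retries")
    }
    anns <- if (length(ann)) do.call(rbind, ann) else
      data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                 w = numeric(), h = numeric())
    list(image = img,
         annotations = anns,
         placement = if (length(plog)) do.call(rbind, plog) else NULL)
  })
}

#' Generate a dataset of scenes on disk
#'
#' Writes `img_%04d.png` plus matching YOLO `.txt` label files and a
#' `manifest.yaml` (paths, class names) under `dir`.
#'
#' @param n number of scenes
#' @param spec an `ew_scene_spec`
#' @param dir output directory (created if needed)
#' @return invisibly, a data frame of image/label paths
#' @export
generate_dataset <- function(n, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_scene(spec, index = i)
    ip <- file.path(dir, sprintf("img_%04d.png", i))
    lp <- file.path(dir, sprintf("img_%04d.txt", i))
    png::writePNG(sc$image, ip)
    write_yolo_labels(sc$annotations, lp)
    rows[[i]] <- data.frame(image = ip, label = lp)
  }
  manifest <- list(n = n, image_size = spec$image_size,
                   classes = paste0("class_", seq_len(spec$num_classes) - 1L))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(do.call(rbind, rows))
}

#' Write YOLO-format labels
#'
#' One line per box: `class cx cy w h`, space-separated, six-decimal fixed
#' point, normalised center format. An empty annotation set gives an empty
#' file.
#'
#' @param annotations data frame with columns `class_id, cx, cy, w, h`
#' @param path output `.txt` path
#' @return `path`, invisibly
#' @export
write_yolo_labels <- function(annotations, path) {
  if (nrow(annotations) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  check_annotations(annotations)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   as.integer(annotations$class_id), annotations$cx,
                   annotations$cy, annotations$w, annotations$h)
  writeLines(lines, path)
  invisible(path)
}

check_annotations <- function(a, line = NULL) {
  where <- function(i) if (is.null(line)) sprintf("row %d", i) else sprintf("line %d", line[i])
  for (i in seq_len(nrow(a))) {
    if (a$class_id[i] < 0 || a$class_id[i] != round(a$class_id[i]))
      stop(sprintf("invalid class id at %s", where(i)))
    if (a$w[i] <= 0 || a$h[i] <= 0 || a$w[i] > 1 || a$h[i] > 1)
      stop(sprintf("box size out of (0, 1] at %s", where(i)))
    if (a$cx[i] - a$w[i] / 2 < -1e-6 || a$cx[i] + a$w[i] / 2 > 1 + 1e-6 ||
        a$cy[i] - a$h[i] / 2 < -1e-6 || a$cy[i] + a$h[i] / 2 > 1 + 1e-6)
      stop(sprintf("box extends outside the image at %s", where(i)))
  }
  invisible(a)
}

#' Read YOLO-format labels
#'
#' Inverse of [write_yolo_labels()]. Malformed lines (wrong field count,
#' non-numeric fields, out-of-range values) raise an error naming the line.
#'
#' @param path label `.txt` path
#' @return data frame `class_id, cx, cy, w, h`
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  parts <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(parts))
    if (length(parts[[i]]) != 5L)
      stop(sprintf("malformed label at line %d: expected 5 fields, got %d",
                   i, length(parts[[i]])))
  mat <- suppressWarnings(vapply(parts, as.numeric, numeric(5L)))
  bad <- which(colSums(is.na(mat)) > 0)
  if (length(bad))
    stop(sprintf("malformed label at line %d: non-numeric field", bad[1L]))
  a <- data.frame(class_id = as.integer(mat[1L, ]), cx = mat[2L, ],
                  cy = mat[3L, ], w = mat[4L, ], h = mat[5L, ])
  check_annotations(a, line = seq_along(lines))
  a
}

#' Deterministic ratio split
#'
#' Shuffles `1:n_items` with the given seed and partitions by the
#' largest-remainder rule: each partition gets `floor(n * ratio)` items and
#' leftovers go to the partitions with the largest fractional quota, later
#' partitions first on ties. Splitting 4565 items at 8:1:1 therefore yields
#' exactly 3652 / 456 / 457. Partitions are disjoint, their union is
#' complete, and each size differs from `n * ratio` by less than 1.
#'
#' @param n_items number of items
#' @param ratios positive weights, one per partition (normalised internally)
#' @param seed shuffle seed
#' @param stratify optional per-item labels; when given, the same rule is
#'   applied within each stratum
#' @return list of index vectors, named `train`, `val`, `test` for three
#'   ratios, `split_1..k` otherwise
#' @export
split_dataset <- function(n_items, ratios = c(8, 1, 1), seed = 0L, stratify = NULL) {
  k <- length(ratios)
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (n_items < k) stop(sprintf("need at least %d items for %d partitions", k, k))
  nm <- if (k == 3L) c("train", "val", "test") else paste0("split_", seq_len(k))
  apportion <- function(n) {
    q <- n * ratios / sum(ratios)
    base <- floor(q)
    rem <- n - sum(base)
    if (rem > 0) {
      pri <- order(q - base, seq_len(k), decreasing = TRUE)  # frac desc, later first
      base[pri[seq_len(rem)]] <- base[pri[seq_len(rem)]] + 1
    }
    as.integer(base)
  }
  assign_ids <- function(ids) {
    shuffled <- with_seed(seed, function() sample(ids))
    sizes <- apportion(length(ids))
    out <- vector("list", k)
    off <- 0L
    for (i in seq_len(k)) {
      out[[i]] <- sort(shuffled[off + seq_len(sizes[i])])
      off <- off + sizes[i]
    }
    out
  }
  if (is.null(stratify)) {
    parts <- assign_ids(seq_len(n_items))
  } else {
    stopifnot(length(stratify) == n_items)
    parts <- rep(list(integer(0)), k)
    for (s in unique(stratify)) {
      sub <- assign_ids(which(stratify == s))
      for (i in seq_len(k)) parts[[i]] <- sort(c(parts[[i]], sub[[i]]))
    }
  }
  names(parts) <- nm
  parts
}
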