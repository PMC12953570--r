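# Desk-scale training and COCO-style evaluation. The loss follows the
# baseline family: binary cross-entropy classification, distribution-focal
# box regression (cross-entropy on the two bins bracketing each target
# distance) plus an L1 term on the decoded distances. Targets are assigned
# to the level whose stride best matches the object size and to the cell
# containing the box center.

#' Training configuration
#'
#' Defaults mirror the full-scale recipe (250 epochs, batch 16, SGD with
#' initial learning rate 0.01 and momentum 0.937, 640 px inputs); smoke runs
#' scale `epochs`, `batch_size` and `image_size` down.
#'
#' @param epochs,batch_size,lr,momentum,image_size training settings
#' @param loss_weights named weights for the `box` (L1), `dfl` and `cls` terms
#' @param warmup_steps linear learning-rate warmup length
#' @return list of class `ew_train_config`
#' @export
train_config <- function(epochs = 250L, batch_size = 16L, lr = 0.01,
                         momentum = 0.937, image_size = 640L,
                         loss_weights = c(box = 7.5, dfl = 1.5, cls = 0.5),
                         warmup_steps = 20L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr >= 0, lr < 1, momentum >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, image_size = as.integer(image_size),
                 loss_weights = loss_weights, warmup_steps = as.integer(warmup_steps)),
            class = "ew_train_config")
}

# Assign ground-truth boxes to (level, cell) positions.
# annotations: list (one data frame per image in the batch).
build_targets <- function(annotations, strides, img_size, reg_max) {
  out <- lapply(strides, function(s) NULL)
  rows <- lapply(seq_along(strides), function(l) list())
  for (b in seq_along(annotations)) {
    a <- annotations[[b]]
    for (r in seq_len(nrow(a))) {
      msz <- max(a$w[r], a$h[r]) * img_size
      l <- which.min(abs(log2(pmax(msz, 1) / (4 * strides))))
      G <- img_size %/% strides[l]
      j <- min(max(floor(a$cx[r] * G), 0), G - 1)   # column, 0-based
      i <- min(max(floor(a$cy[r] * G), 0), G - 1)   # row, 0-based
      x1 <- a$cx[r] * G - a$w[r] * G / 2; x2 <- a$cx[r] * G + a$w[r] * G / 2
      y1 <- a$cy[r] * G - a$h[r] * G / 2; y2 <- a$cy[r] * G + a$h[r] * G / 2
      d <- c(j + 0.5 - x1, i + 0.5 - y1, x2 - j - 0.5, y2 - i - 0.5)
      d <- pmin(pmax(d, 0.01), reg_max - 1.01)
      key <- paste(b, i, j)
      if (!is.null(rows[[l]][[key]])) next          # cell already claimed
      rows[[l]][[key]] <- list(b = b, i = i, j = j, cls = a$class_id[r], d = d)
    }
  }
  lapply(rows, function(r) unname(r))
}

# Composite detection loss: writes gradients straight into the head output
# nodes. Returns a scalar node plus the term breakdown.
op_detection_loss <- function(outs, targets, nc, reg_max, weights, ctx) {
  n_pos <- sum(vapply(targets, length, 0L))
  norm <- max(1L, n_pos)
  bins <- 0:(reg_max - 1L)
  loss_cls <- 0; loss_box <- 0; loss_dfl <- 0
  grads <- vector("list", length(outs))
  for (l in seq_along(outs)) {
    cl <- outs[[l]]$cls; bx <- outs[[l]]$box
    dc <- dim(cl$v)
    ytab <- array(0, dc)
    for (tg in targets[[l]])
      ytab[tg$b, tg$cls + 1L, tg$i + 1L, tg$j + 1L] <- 1
    z <- cl$v
    loss_cls <- loss_cls + sum(pmax(z, 0) - z * ytab + log1p(exp(-abs(z))))
    gcls <- (1 / (1 + exp(-z)) - ytab) / norm
    gbox <- array(0, dim(bx$v))
    for (tg in targets[[l]]) {
      for (sdx in 1:4) {
        ch <- (sdx - 1L) * reg_max + seq_len(reg_max)
        zz <- bx$v[tg$b, ch, tg$i + 1L, tg$j + 1L]
        p <- exp(zz - max(zz)); p <- p / sum(p)
        e <- sum(p * bins)
        t <- tg$d[sdx]
        li <- floor(t); wl <- li + 1 - t; wr <- t - li
        loss_box <- loss_box + abs(e - t)
        loss_dfl <- loss_dfl - (wl * log(p[li + 1L] + 1e-12) +
                                wr * log(p[li + 2L] + 1e-12))
        tgt <- numeric(reg_max)
        tgt[li + 1L] <- wl; tgt[li + 2L] <- wr
        g <- weights[["box"]] * sign(e - t) * p * (bins - e) / (4 * norm) +
             weights[["dfl"]] * (p - tgt) / (4 * norm)
        gbox[tg$b, ch, tg$i + 1L, tg$j + 1L] <- g
      }
    }
    grads[[l]] <- list(cls = gcls * weights[["cls"]], box = gbox)
  }
  total <- weights[["cls"]] * loss_cls / norm +
           weights[["box"]] * loss_box / (4 * norm) +
           weights[["dfl"]] * loss_dfl / (4 * norm)
  node <- tnode(total)
  if (ctx$grad) ctx_push(ctx, function() {
    if (is.null(node$g)) return(invisible(NULL))
    for (l in seq_along(outs)) {
      accum_grad(outs[[l]]$cls, node$g * grads[[l]]$cls)
      accum_grad(outs[[l]]$box, node$g * grads[[l]]$box)
    }
  })
  attr(node, "terms") <- c(cls = loss_cls / norm, box = loss_box / (4 * norm),
                           dfl = loss_dfl / (4 * norm))
  node
}

#' Smoke-train a detection model
#'
#' Short CPU training loop over an in-memory synthetic dataset. Sample order
#' is shuffled once (seeded) and kept fixed across epochs, so the run is
#' reproducible and a zero learning rate yields a constant loss trace on a
#' single-batch dataset. Aborts with a diagnostic if the loss diverges.
#'
#' @param model module from [build_model()]
#' @param dataset list of samples, each a list with `image` (`(H, W, 3)`
#'   array) and `annotations` (data frame)
#' @param cfg an `ew_train_config`
#' @param seed shuffle seed
#' @param verbose print per-epoch losses to stderr?
#' @return numeric vector: total loss per step
#' @export
smoke_train <- function(model, dataset, cfg = train_config(), seed = 0L,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "ew_train_config"))
  n <- length(dataset)
  ord <- with_seed(seed, function() sample(n))
  batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
  trace <- numeric(0)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    for (bt in batches) {
      step <- step + 1L
      x <- array(0, c(length(bt), 3L, dim(dataset[[bt[1L]]]$image)[1L],
                      dim(dataset[[bt[1L]]]$image)[2L]))
      for (q in seq_along(bt))
        x[q, , , ] <- aperm(dataset[[bt[q]]]$image, c(3L, 1L, 2L))
      anns <- lapply(dataset[bt], `[[`, "annotations")
      ctx <- new_ctx(grad = TRUE, training = TRUE)
      outs <- model$fwd(model, tnode(x), ctx)
      tg <- build_targets(anns, model$strides, cfg$image_size, model$cfg$reg_max)
      loss <- op_detection_loss(outs, tg, model$cfg$num_classes,
                                model$cfg$reg_max, cfg$loss_weights, ctx)
      if (!is.finite(loss$v)) stop(sprintf("loss diverged (non-finite) at step %d", step))
      backward(ctx, loss)
      lr <- cfg$lr * min(1, step / max(1L, cfg$warmup_steps))
      sgd_step(model, lr, cfg$momentum)
      zero_grads(model)
      trace[step] <- loss$v
    }
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs,
                      mean(trace[(step - length(batches) + 1L):step])))
  }
  trace
}

# IoU between two boxes in normalised center format c(cx, cy, w, h)
box_iou <- function(b1, b2) {
  x1 <- pmax(b1[1L] - b1[3L] / 2, b2[1L] - b2[3L] / 2)
  y1 <- pmax(b1[2L] - b1[4L] / 2, b2[2L] - b2[4L] / 2)
  x2 <- pmin(b1[1L] + b1[3L] / 2, b2[1L] + b2[3L] / 2)
  y2 <- pmin(b1[2L] + b1[4L] / 2, b2[2L] + b2[4L] / 2)
  inter <- pmax(0, x2 - x1) * pmax(0, y2 - y1)
  inter / (b1[3L] * b1[4L] + b2[3L] * b2[4L] - inter)
}

#' Decode raw head outputs into detections
#'
#' Distribution-focal expectation per box side, anchor-free cell arithmetic
#' (cell centers at `(j + 0.5) * stride`), sigmoid class scores, confidence
#' thresholding and class-wise greedy non-maximum suppression.
#'
#' @param head_outputs list of per-level `box`/`cls` arrays for one image
#'   (batch size 1), as returned by [model_forward()]
#' @param conf_thresh minimum class probability in `[0, 1]`
#' @param iou_thresh NMS overlap threshold in `[0, 1]`
#' @param reg_max distribution-focal bin count
#' @return data frame `class_id, cx, cy, w, h, confidence`
#' @export
decode_predictions <- function(head_outputs, conf_thresh = 0.25,
                               iou_thresh = 0.45, reg_max = 16L) {
  if (conf_thresh < 0 || conf_thresh > 1 || iou_thresh < 0 || iou_thresh > 1)
    stop("thresholds must lie in [0, 1]")
  bins <- 0:(reg_max - 1L)
  cand <- list()
  for (l in seq_along(head_outputs)) {
    cls <- head_outputs[[l]]$cls
    box <- head_outputs[[l]]$box
    if (is_tnode(cls)) { cls <- cls$v; box <- box$v }
    G <- dim(cls)[3L]
    prob <- 1 / (1 + exp(-cls[1L, , , , drop = FALSE]))
    for (i in seq_len(G)) for (j in seq_len(dim(cls)[4L])) {
      pc <- prob[1L, , i, j]
      k <- which.max(pc)
      if (pc[k] < conf_thresh) next
      d <- numeric(4L)
      for (sdx in 1:4) {
        zz <- box[1L, (sdx - 1L) * reg_max + seq_len(reg_max), i, j]
        p <- exp(zz - max(zz)); p <- p / sum(p)
        d[sdx] <- sum(p * bins)
      }
      x1 <- (j - 0.5 - d[1L]) / G; y1 <- (i - 0.5 - d[2L]) / G
      x2 <- (j - 0.5 + d[3L]) / G; y2 <- (i - 0.5 + d[4L]) / G
      x1 <- max(0, x1); y1 <- max(0, y1); x2 <- min(1, x2); y2 <- min(1, y2)
      if (x2 <= x1 || y2 <= y1) next
      cand[[length(cand) + 1L]] <- data.frame(
        class_id = k - 1L, cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
        w = x2 - x1, h = y2 - y1, confidence = pc[k])
    }
  }
  if (!length(cand))
    return(data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric(), confidence = numeric()))
  dets <- do.call(rbind, cand)
  keep <- logical(nrow(dets))
  for (cls in unique(dets$class_id)) {
    idx <- which(dets$class_id == cls)
    idx <- idx[order(-dets$confidence[idx])]
    while (length(idx)) {
      top <- idx[1L]
      keep[top] <- TRUE
      idx <- idx[-1L]
      if (length(idx)) {
        ious <- vapply(idx, function(q)
          box_iou(as.numeric(dets[top, 2:5]), as.numeric(dets[q, 2:5])), 0)
        idx <- idx[ious <= iou_thresh]
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  out[order(-out$confidence), , drop = FALSE]
}

# AP by 101-point interpolated precision-recall integration
ap_101 <- function(tp, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(tp)) return(0)
  ctp <- cumsum(tp)
  cfp <- cumsum(!tp)
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  # precision envelope: max precision at recall >= r
  pts <- seq(0, 1, by = 0.01)
  env <- rev(cummax(rev(prec)))
  ap <- 0
  for (r in pts) {
    ok <- which(rec >= r - 1e-12)
    ap <- ap + (if (length(ok)) env[ok[1L]] else 0)
  }
  ap / length(pts)
}

# greedy confidence-descending matching for one class at one IoU threshold;
# returns logical TP flags in confidence order
match_class <- function(dets, gts, thr) {
  ord <- order(-dets$confidence)
  used <- lapply(gts, function(g) logical(nrow(g)))
  tp <- logical(length(ord))
  for (qi in seq_along(ord)) {
    r <- dets[ord[qi], ]
    g <- gts[[r$image]]
    if (nrow(g) == 0L) next
    ious <- vapply(seq_len(nrow(g)), function(t)
      box_iou(as.numeric(r[c("cx", "cy", "w", "h")]),
              as.numeric(g[t, c("cx", "cy", "w", "h")])), 0)
    ious[used[[r$image]]] <- -1
    best <- which.max(ious)
    if (length(best) && ious[best] >= thr) {
      tp[qi] <- TRUE
      used[[r$image]][best] <- TRUE
    }
  }
  tp
}

#' Evaluate detections against ground truth
#'
#' Greedy confidence-descending matching per class and image; average
#' precision by 101-point interpolated precision-recall integration, averaged
#' over classes present in the ground truth; `map50_95` averages IoU
#' thresholds 0.50 to 0.95 in steps of 0.05. `precision` and `recall` are
#' reported at IoU 0.50 over all supplied detections. Results are invariant
#' to the ordering of the detection lists.
#'
#' @param detections list (one data frame per image) with columns
#'   `class_id, cx, cy, w, h, confidence`
#' @param ground_truth list (one data frame per image) with columns
#'   `class_id, cx, cy, w, h`
#' @return list with `precision`, `recall`, `map50`, `map50_95`
#' @export
evaluate_detections <- function(detections, ground_truth) {
  stopifnot(length(detections) == length(ground_truth))
  empty_gt <- data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                         w = numeric(), h = numeric())
  ground_truth <- lapply(ground_truth, function(g)
    if (is.null(g) || !nrow(g)) empty_gt else g)
  all_det <- do.call(rbind, lapply(seq_along(detections), function(i) {
    d <- detections[[i]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    d$image <- i
    d
  }))
  classes <- sort(unique(unlist(lapply(ground_truth, function(g) g$class_id))))
  thrs <- seq(0.5, 0.95, by = 0.05)
  aps <- matrix(NA_real_, length(classes), length(thrs))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    gts <- lapply(ground_truth, function(g) g[g$class_id == cls, , drop = FALSE])
    n_gt <- sum(vapply(gts, nrow, 0L))
    dsub <- if (is.null(all_det)) NULL else all_det[all_det$class_id == cls, , drop = FALSE]
    for (ti in seq_along(thrs)) {
      tp <- if (is.null(dsub) || nrow(dsub) == 0L) logical(0)
            else match_class(dsub, gts, thrs[ti])
      aps[ci, ti] <- ap_101(tp, n_gt)
    }
  }
  map_t <- if (length(classes)) colMeans(aps, na.rm = TRUE) else rep(0, length(thrs))
  map_t[is.nan(map_t)] <- 0
  # headline precision/recall at IoU 0.5 over all detections
  n_gt_all <- sum(vapply(ground_truth, nrow, 0L))
  tp_all <- 0L; n_det <- 0L
  for (cls in if (is.null(all_det)) integer(0) else unique(all_det$class_id)) {
    dsub <- all_det[all_det$class_id == cls, , drop = FALSE]
    gts <- lapply(ground_truth, function(g) g[g$class_id == cls, , drop = FALSE])
    tp <- match_class(dsub, gts, 0.5)
    tp_all <- tp_all + sum(tp)
    n_det <- n_det + length(tp)
  }
  list(precision = if (n_det) tp_all / n_det else 0,
       recall = if (n_gt_all) tp_all / n_gt_all else 0,
       map50 = map_t[1L],
       map50_95 = mean(map_t))
}

#' Run a model over images and collect decoded detections
#'
#' @param model module from [build_model()]
#' @param images list of `(H, W, 3)` arrays
#' @param conf_thresh,iou_thresh decoding thresholds
#' @return list of detection data frames, one per image
#' @export
predict_detections <- function(model, images, conf_thresh = 0.25,
                               iou_thresh = 0.45) {
  lapply(images, function(img) {
    x <- array(aperm(img, c(3L, 1L, 2L)), c(1L, 3L, dim(img)[1L], dim(img)[2L]))
    outs <- model$fwd(model, tnode(x), new_ctx())
    decode_predictions(outs, conf_thresh, iou_thresh, reg_max = model$cfg$reg_max)
  })
}
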