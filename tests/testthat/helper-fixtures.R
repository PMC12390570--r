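# Shared fixtures. The scaled-down end-to-end training run is expensive, so
# it is executed once per session and memoized; every test that needs a
# trained model reuses it.

.fixture_env <- new.env(parent = emptyenv())

tiny_cfg <- function(seed = 101L, ...) {
  germ_config(px_per_mm = 2, image_size = 192L, background_style = "black",
              instances_per_image = c(2L, 5L), seed = seed, ...)
}

# small dataset on disk, memoized per (n, seed)
fixture_dataset <- function(n = 6L, seed = 11L, image_size = 96L) {
  key <- sprintf("ds_%d_%d_%d", n, seed, image_size)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), key)
  cfg <- germ_config(px_per_mm = 1.5, image_size = as.integer(image_size),
                     background_style = "black",
                     instances_per_image = c(1L, 2L), seed = seed)
  generate_dataset(cfg, n, dir)
  .fixture_env[[key]] <- dir
  dir
}

# The scaled-down two-stage study: 260 synthetic 192x192 scenes (200 train,
# 60 held out), tiny-profile model, full two-stage schedule, held-out
# evaluation through the complete detection + length pipeline.
e2e_fixture <- function() {
  if (!is.null(.fixture_env$e2e)) return(.fixture_env$e2e)
  dir <- file.path(tempdir(), "ds_e2e")
  cfg <- tiny_cfg(seed = 101L)
  if (!file.exists(file.path(dir, "annotations.json")))
    generate_dataset(cfg, 260L, dir)
  ds <- read_dataset(dir)
  ds$split <- list(train = 1:200, val = 201:260)
  model <- glen_model("tiny", seed = 42L)
  tc <- train_config("tiny", seed = 42L)
  r1 <- train_stage1(ds, model, tc)
  ext_names <- setdiff(names(r1$state$params),
                       grep("^len_head", names(r1$state$params), value = TRUE))
  ext_before <- r1$state$params[ext_names]
  r2 <- train_stage2(ds, model, r1$state, tc)
  ext_after <- r2$state$params[ext_names]
  val <- radiclen:::dataset_samples(ds, ds$split$val)
  gtl <- c(); prl <- c(); ious <- c(); ndev <- c(); ngt <- 0L
  for (s in val) {
    pr <- predict_scene(model, s$image, grid_pitch_px = s$grid_pitch_px,
                        score_thr = 0.1)
    ngt <- ngt + nrow(s$boxes)
    if (!nrow(pr$boxes)) next
    preds <- lapply(seq_len(nrow(pr$boxes)), function(q)
      list(box = as.numeric(pr$boxes[q, c("x1", "y1", "x2", "y2")]),
           score = pr$boxes$score[q], mask = pr$masks[[q]],
           length_mm = pr$boxes$length_mm[q]))
    gts <- lapply(seq_len(nrow(s$boxes)), function(g)
      list(box = s$boxes[g, ], mask = s$masks[[g]],
           length_mm = s$length_mm[g], n_dev = s$n_dev[g]))
    mt <- match_instances(preds, gts, iou_thr = 0.5, on = "box")
    if (nrow(mt$pairs)) {
      gtl <- c(gtl, mt$pairs$length_gt)
      prl <- c(prl, mt$pairs$length_pred)
      ndev <- c(ndev, mt$pairs$n_dev)
      for (r in seq_len(nrow(mt$pairs)))
        ious <- c(ious, radiclen:::mask_iou(preds[[mt$pairs$pred[r]]]$mask,
                                            gts[[mt$pairs$gt[r]]]$mask))
    }
  }
  .fixture_env$e2e <- list(
    model = model, log1 = r1$log, log2 = r2$log,
    ext_before = ext_before, ext_after = ext_after,
    eval = list(length_gt = gtl, length_pred = prl, mask_iou = ious,
                n_dev = ndev, n_gt = ngt))
  .fixture_env$e2e
}

# brute-force oracles used across files --------------------------------------

oracle_nms <- function(boxes, scores, thr) {
  n <- length(scores)
  ord <- order(-scores, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      xx1 <- max(boxes[i, 1], boxes[k, 1]); yy1 <- max(boxes[i, 2], boxes[k, 2])
      xx2 <- min(boxes[i, 3], boxes[k, 3]); yy2 <- min(boxes[i, 4], boxes[k, 4])
      inter <- max(xx2 - xx1, 0) * max(yy2 - yy1, 0)
      a1 <- (boxes[i, 3] - boxes[i, 1]) * (boxes[i, 4] - boxes[i, 2])
      a2 <- (boxes[k, 3] - boxes[k, 1]) * (boxes[k, 4] - boxes[k, 2])
      if (inter / (a1 + a2 - inter) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# exhaustive precision-recall AP for one image set at one IoU threshold
oracle_ap <- function(scores, ious, ngt, thr, grid = seq(0, 1, by = 0.01)) {
  ord <- order(-scores, seq_along(scores))
  used <- rep(FALSE, ngt)
  tp <- numeric(length(scores))
  for (ii in seq_along(ord)) {
    q <- ord[ii]
    best <- 0; bg <- 0
    for (g in seq_len(ngt)) {
      if (used[g]) next
      if (ious[q, g] > best) { best <- ious[q, g]; bg <- g }
    }
    if (bg > 0 && best >= thr) { used[bg] <- TRUE; tp[ii] <- 1 }
  }
  ctp <- cumsum(tp); cfp <- cumsum(1 - tp)
  rec <- ctp / ngt; prec <- ctp / (ctp + cfp)
  mean(vapply(grid, function(r) {
    s <- rec >= r - 1e-12
    if (!any(s)) 0 else max(prec[s])
  }, 0))
}

# numeric gradient of f with respect to an ag_param node
numeric_grad <- function(f, p, eps = 1e-5) {
  g <- array(0, dim(p$val) %||% length(p$val))
  for (i in seq_along(p$val)) {
    old <- p$val[i]
    p$val[i] <- old + eps; up <- f()
    p$val[i] <- old - eps; dn <- f()
    p$val[i] <- old
    g[i] <- (up - dn) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
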