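# Two-stage training. Stage 1 jointly optimizes the pixel- and
# instance-level extractors with the combined loss (per-level mask BCE +
# semantic CE, focal objectness + IoU box + centerness BCE + instance-mask
# BCE), SGD with momentum, linear warmup, multi-scale resize and horizontal
# flip augmentation, and global-norm gradient clipping. Stage 2 freezes both
# extractors and trains only the length regressor with the hybrid L2/L1
# loss; because the extractors are frozen, RoI features are precomputed
# once per training image.

#' Training configuration
#'
#' Defaults follow the full-scale recipe (SGD momentum 0.9, weight decay
#' 1e-4, stage-1 lr 5e-3 over 1e4 iterations, stage-2 lr 1e-2 over 2e3
#' iterations, 1e3 warmup iterations, gradient clipping at max-norm 1.0,
#' batch 4, multi-scale shorter side 640-800, focal gamma 2, loss weights
#' lambda1 = lambda2 = 1, beta = 1, NMS 0.3). `batch_stage2` (default:
#' same as `batch`) sets the stage-2 batch separately; stage-2 steps are
#' far cheaper than stage-1 steps since RoI features are precomputed, so
#' a larger batch costs little. The tiny profile scales the schedule down
#' for CPU-scale experiments and resizes within 160-256.
#'
#' @param profile "resnet50" or "tiny".
#' @param ... named overrides of any field.
#' @return a `train_config` list.
#' @export
train_config <- function(profile = c("tiny", "resnet50"), ...) {
  profile <- match.arg(profile)
  cfg <- list(profile = profile,
              lr_stage1 = 5e-3, lr_stage2 = 1e-2,
              momentum = 0.9, weight_decay = 1e-4,
              iters_stage1 = 1e4, iters_stage2 = 2e3,
              warmup_iters = 1e3, clip_norm = 1.0,
              batch = 4L, batch_stage2 = NULL,
              input_sizes = c(640L, 672L, 704L, 736L, 768L, 800L),
              lambda1 = 1, lambda2 = 1, gamma = 2, beta = 1,
              nms_thr = 0.3, score_thr = 0.05, seed = 7L)
  if (profile == "tiny")
    cfg <- utils::modifyList(cfg, list(iters_stage1 = 600L, iters_stage2 = 1500L,
                                       lr_stage1 = 1e-2, lr_stage2 = 4e-2,
                                       warmup_iters = 50L, batch = 2L,
                                       batch_stage2 = 8L,
                                       input_sizes = c(160L, 192L, 224L, 256L)))
  cfg <- utils::modifyList(cfg, list(...))
  if (is.null(cfg$batch_stage2)) cfg$batch_stage2 <- cfg$batch
  stopifnot(cfg$lambda1 > 0, cfg$lambda2 > 0, cfg$beta > 0,
            cfg$clip_norm > 0, cfg$batch >= 1, cfg$batch_stage2 >= 1)
  class(cfg) <- "train_config"
  cfg
}

# linear warmup, then a single 10x step decay at 70% of the schedule
lr_at <- function(base, it, warmup, total = Inf, decay_frac = 0.7,
                  decay_factor = 0.1) {
  lr <- if (it <= warmup && warmup > 0) base * it / warmup else base
  if (is.finite(total) && it > decay_frac * total) lr <- lr * decay_factor
  lr
}

resize_image <- function(img, side) {
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  sc <- side / min(d[1], d[2])
  array(cpp_resize_bilinear_fw(array(img, c(d, 1L)),
                               as.integer(round(d[1] * sc)),
                               as.integer(round(d[2] * sc))),
        c(round(d[1] * sc), round(d[2] * sc), d[3]))
}

hflip_image <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

# Prepare one training sample: resize to `side`, random horizontal flip.
prep_sample <- function(img, boxes, masks, side, flip) {
  d0 <- dim(img)
  sc <- side / min(d0[1], d0[2])
  img <- resize_image(img, side)
  d <- dim(img)
  boxes <- boxes * sc
  if (flip) {
    img <- hflip_image(img)
    x1 <- d[2] - boxes[, 3]; x2 <- d[2] - boxes[, 1]
    boxes[, 1] <- x1; boxes[, 3] <- x2
  }
  union_mask <- matrix(0, d0[1], d0[2])
  for (m in masks) union_mask <- pmax(union_mask, m)
  um <- matrix(cpp_resize_bilinear_fw(array(union_mask, c(d0[1], d0[2], 1L, 1L)),
                                      d[1], d[2]), d[1], d[2])
  gmasks <- lapply(masks, function(m)
    matrix(cpp_resize_bilinear_fw(array(m + 0, c(d0[1], d0[2], 1L, 1L)),
                                  d[1], d[2]), d[1], d[2]))
  if (flip) {
    um <- um[, rev(seq_len(d[2]))]
    gmasks <- lapply(gmasks, function(m) m[, rev(seq_len(d[2]))])
  }
  list(image = img, boxes = boxes, union = um, masks = gmasks, scale = sc)
}

down_target <- function(um, H, W, thr = 0.1) {
  matrix(cpp_resize_bilinear_fw(array(um, c(dim(um), 1L, 1L)), H, W) > thr,
         H, W) + 0
}

# Build the stage-1 loss graph for one prepared batch.
stage1_batch_loss <- function(model, batch, cfg) {
  N <- length(batch)
  imgs <- array(0, c(dim(batch[[1]]$image), N))
  for (q in seq_len(N)) imgs[, , , q] <- batch[[q]]$image
  x <- ag_const(imgs)
  C <- forward_backbone(model, x, TRUE)
  P <- forward_fpn(model, C)
  Fm <- forward_se(model, P)
  B <- forward_decoder(model, Fm, TRUE)
  heads <- forward_heads(model, Fm)
  level_dims <- lapply(heads, function(h) dim4(h$cls$val)[1:2])
  strides <- model$strides

  # pixel path: per-level mask BCE on shared 1x1 projections of Fi
  mask_terms <- list()
  for (li in 1:5) {
    logit <- fwd_conv(model$proj_mask, Fm[[li]])
    dims <- dim4(logit$val)
    tgt <- array(0, dims)
    for (q in seq_len(N))
      tgt[, , 1, q] <- down_target(batch[[q]]$union, dims[1], dims[2])
    mask_terms[[li]] <- ag_bce_logits(logit, tgt)
  }
  sem_logit <- fwd_conv(model$sem, B)
  dB <- dim4(sem_logit$val)
  sem_lab <- array(0, c(dB[1], dB[2], N))
  for (q in seq_len(N))
    sem_lab[, , q] <- down_target(batch[[q]]$union, dB[1], dB[2], thr = 0.5)
  sem_term <- ag_softmax_ce2(sem_logit, sem_lab)

  # instance path: dense targets per image
  focal_terms <- list(); iou_terms <- list(); ctr_terms <- list()
  mask_inst_terms <- list()
  for (li in 1:5) {
    dims <- level_dims[[li]]
    tgt <- array(0, c(dims[1], dims[2], 1L, N))
    pos_idx <- NULL; pos_ltrb <- NULL; pos_ctr <- NULL
    for (q in seq_len(N)) {
      asn <- assign_dense_targets(batch[[q]]$boxes, list(dims), strides[li],
                                  ranges = model$ranges[li],
                                  masks = lapply(batch[[q]]$masks,
                                                 function(m) m > 0.4))
      lv <- asn[[1]]
      tgt[, , 1, q] <- lv$labels
      for (pp in lv$positives) {
        pos_idx <- rbind(pos_idx, c(pp$i, pp$j, q))
        pos_ltrb <- cbind(pos_ltrb, pp$ltrb)
        pos_ctr <- c(pos_ctr, pp$centerness)
      }
    }
    npos_l <- if (is.null(pos_idx)) 0L else nrow(pos_idx)
    focal_terms[[li]] <- ag_focal_logits(heads[[li]]$cls, tgt, cfg$gamma,
                                         npos = max(1L, npos_l))
    if (npos_l > 0) {
      reg_g <- ag_gather_loc(heads[[li]]$reg, pos_idx)
      ltrb_pred <- ag_scalar_mul(ag_exp(reg_g), strides[li])
      iou_terms[[length(iou_terms) + 1L]] <- ag_iou_loss(ltrb_pred, pos_ltrb)
      ctr_g <- ag_gather_loc(heads[[li]]$ctr, pos_idx)
      ctr_terms[[length(ctr_terms) + 1L]] <-
        ag_bce_logits(ctr_g, matrix(pos_ctr, 1), norm = npos_l)
    }
  }
  # instance-mask BCE via ground-truth boxes and training-mode attention
  for (q in seq_len(N)) {
    boxes <- batch[[q]]$boxes
    if (!nrow(boxes)) next
    srcq <- ag_select_n(if (model$basis_source == "B") B else Fm[[1]], q)
    crops <- ag_roi_align(srcq, boxes, model$R, 1 / model$basis_stride)
    att_cols <- list()
    dense_meta <- lapply(1:5, function(li)
      list(score = matrix(0, level_dims[[li]][1], level_dims[[li]][2]),
           stride = strides[li]))
    amaps <- list()
    for (g in seq_len(nrow(boxes))) {
      asn <- assign_gt_location(boxes[g, ], dense_meta, ranges = model$ranges,
                                mask = batch[[q]]$masks[[g]] > 0.4)
      a_g <- ag_gather_loc(heads[[asn$level]]$att,
                           matrix(c(asn$gi, asn$gj, q), 1))
      amaps[[g]] <- ag_softmax_cols(a_g)
    }
    acat <- ag_cbind(amaps)
    a4 <- ag_reshape(acat, c(model$M, model$M, 1L, nrow(boxes)))
    a_up <- ag_resize(a4, model$R, model$R)
    blended <- ag_mul_bc_ch(crops, a_up)
    mlogit <- fwd_conv(model$mask_head, blended)
    tgtm <- array(0, c(model$R, model$R, 1L, nrow(boxes)))
    for (g in seq_len(nrow(boxes))) {
      mm <- batch[[q]]$masks[[g]]
      tgtm[, , 1, g] <- matrix(cpp_roi_align_fw(
        array(mm + 0, c(dim(mm), 1L, 1L)),
        matrix(boxes[g, ], 1), model$R, 1) > 0.4, model$R, model$R) + 0
    }
    mask_inst_terms[[length(mask_inst_terms) + 1L]] <-
      ag_bce_logits(mlogit, tgtm, pos_weight = 4)
  }
  pixel_nodes <- c(mask_terms, list(sem_term))
  inst_nodes <- c(focal_terms, iou_terms, ctr_terms, mask_inst_terms)
  scale_terms <- function(nodes, w) if (length(nodes)) ag_sum_scalars(nodes, rep(w, length(nodes)))
  total <- ag_sum_scalars(c(pixel_nodes, inst_nodes),
                          c(rep(cfg$lambda1, length(pixel_nodes)),
                            rep(cfg$lambda2, length(inst_nodes))))
  comps <- c(mask_px = sum(vapply(mask_terms, function(n) n$val, 0)),
             semantic = sem_term$val,
             focal = sum(vapply(focal_terms, function(n) n$val, 0)),
             iou = sum(vapply(iou_terms, function(n) n$val, 0)),
             centerness = sum(vapply(ctr_terms, function(n) n$val, 0)),
             mask_inst = sum(vapply(mask_inst_terms, function(n) n$val, 0)))
  list(loss = total, components = comps)
}

dataset_samples <- function(dataset, ids) {
  lapply(ids, function(id) {
    im <- dataset$images[[as.character(id)]]
    anns <- Filter(function(a) a$image_id == id, dataset$annotations)
    list(id = id, image = im$pixels,
         grid_pitch_px = im$grid_pitch_px,
         boxes = do.call(rbind, lapply(anns, function(a) a$box)),
         masks = lapply(anns, function(a) a$mask),
         length_px = vapply(anns, function(a) a$length_px, 0),
         length_mm = vapply(anns, function(a) a$length_mm, 0),
         n_dev = vapply(anns, function(a) as.integer(a$n_dev), 0L))
  })
}

#' Stage-1 training of the two feature extractors
#'
#' @param dataset a `dataset_bundle` from [read_dataset()].
#' @param model a [glen_model()]; updated in place (parameters are mutable
#'   environments) and also returned in the checkpoint.
#' @param cfg a [train_config()].
#' @param verbose print progress every 25 iterations.
#' @return list: `model`, `state` (checkpoint), `log` (data frame with
#'   iteration, loss, components, post-clip gradient norm, lr).
#' @export
train_stage1 <- function(dataset, model, cfg = train_config(model$profile),
                         verbose = FALSE) {
  set.seed(cfg$seed)
  samples <- dataset_samples(dataset, dataset$split$train)
  params <- collect_params(model)
  log <- vector("list", cfg$iters_stage1)
  last_good <- NULL
  for (it in seq_len(cfg$iters_stage1)) {
    side <- sample(cfg$input_sizes, 1L)
    pick <- sample(seq_along(samples), min(cfg$batch, length(samples)))
    batch <- lapply(pick, function(q) {
      s <- samples[[q]]
      prep_sample(s$image, s$boxes, s$masks, side, stats::runif(1) < 0.5)
    })
    zero_grads(params)
    got <- stage1_batch_loss(model, batch, cfg)
    if (!is.finite(got$loss$val)) {
      if (!is.null(last_good)) load_model_state(model, last_good)
      stop("stage-1 loss diverged (non-finite) at iteration ", it,
           "; last stable checkpoint restored")
    }
    ag_backward(got$loss)
    lr <- lr_at(cfg$lr_stage1, it, cfg$warmup_iters, cfg$iters_stage1)
    gn <- sgd_step(params, lr, cfg$momentum, cfg$weight_decay, cfg$clip_norm)
    log[[it]] <- data.frame(iter = it, loss = got$loss$val,
                            t(got$components), grad_norm = gn, lr = lr)
    if (it %% 50L == 0L) last_good <- model_state(model)
    if (verbose && it %% 25L == 0L)
      message(sprintf("stage1 iter %d loss %.4f", it, got$loss$val))
  }
  list(model = model, state = model_state(model), stage = 1L,
       log = do.call(rbind, log))
}

# Precompute frozen RoI features (blended crops) and targets for stage 2.
stage2_cache <- function(model, samples, augment_flip = TRUE,
                         scales = c(1, 4 / 3)) {
  out <- list()
  for (s0 in samples) {
    if (is.null(s0$boxes) || !nrow(s0$boxes)) next
    variants <- list(s0)
    if (augment_flip) {
      W <- dim(s0$image)[2]
      sf <- s0
      sf$image <- hflip_image(s0$image)
      sf$boxes <- cbind(W - s0$boxes[, 3], s0$boxes[, 2],
                        W - s0$boxes[, 1], s0$boxes[, 4])
      sf$masks <- lapply(s0$masks, function(m) m[, rev(seq_len(ncol(m)))])
      variants[[length(variants) + 1L]] <- sf
    }
    for (sc in setdiff(scales, 1)) {
      d <- dim(s0$image)
      sv <- s0
      sv$image <- array(cpp_resize_bilinear_fw(array(s0$image, c(d, 1L)),
                        as.integer(round(d[1] * sc)),
                        as.integer(round(d[2] * sc))),
                        c(round(d[1] * sc), round(d[2] * sc), d[3]))
      sv$boxes <- s0$boxes * sc
      sv$masks <- lapply(s0$masks, function(m)
        matrix(cpp_resize_bilinear_fw(array(m + 0, c(dim(m), 1L, 1L)),
               as.integer(round(d[1] * sc)), as.integer(round(d[2] * sc))) > 0.4,
               round(d[1] * sc), round(d[2] * sc)))
      sv$length_px <- s0$length_px * sc
      variants[[length(variants) + 1L]] <- sv
    }
    for (s in variants) {
    fw <- forward_glen(model, s$image, training = FALSE)
    dense_meta <- lapply(seq_along(fw$heads), function(li)
      list(score = matrix(0, dim4(fw$heads[[li]]$cls$val)[1],
                          dim4(fw$heads[[li]]$cls$val)[2]),
           att = fw$heads[[li]]$att$val[, , , 1, drop = TRUE],
           stride = model$strides[li]))
    for (li in seq_along(dense_meta))
      dim(dense_meta[[li]]$att) <- dim4(fw$heads[[li]]$att$val)[c(1, 2, 3)]
    src <- if (model$basis_source == "B") fw$B else fw$F[[1]]
    src <- array(src$val, dim4(src$val)[1:3])
    crops <- roi_align(src, s$boxes, model$R, model$basis_stride)
    amaps <- lapply(seq_len(nrow(s$boxes)), function(g) {
      asn <- assign_gt_location(s$boxes[g, ], dense_meta,
                                ranges = model$ranges, mask = s$masks[[g]])
      logits <- dense_meta[[asn$level]]$att[asn$gi, asn$gj, ]
      e <- exp(logits - max(logits))
      matrix(e / sum(e), model$M, model$M)
    })
    blended <- blend(crops, amaps)
    out[[length(out) + 1L]] <- list(crops = blended, targets = s$length_px)
    }
  }
  out
}

#' Stage-2 training of the length regressor (extractors frozen)
#'
#' Only the length-head parameters receive gradient updates; every other
#' parameter is bit-identical before and after. RoI features are
#' precomputed once since the extractors are frozen.
#'
#' @param dataset a `dataset_bundle`.
#' @param model a [glen_model()] carrying stage-1 weights.
#' @param stage1_state stage-1 checkpoint state (from [train_stage1()]);
#'   required, loaded into the model before training.
#' @param cfg a [train_config()].
#' @param verbose print progress.
#' @return list: `model`, `state`, `log` (iteration, loss, grad norm, lr).
#' @export
train_stage2 <- function(dataset, model, stage1_state,
                         cfg = train_config(model$profile), verbose = FALSE) {
  if (is.null(stage1_state)) stop("stage-1 checkpoint required")
  load_model_state(model, stage1_state)
  set.seed(cfg$seed + 1L)
  samples <- dataset_samples(dataset, dataset$split$train)
  cache <- stage2_cache(model, samples)
  if (!length(cache)) stop("no instances available for stage-2 training")
  params <- collect_params(model$len_head)
  log <- vector("list", cfg$iters_stage2)
  for (it in seq_len(cfg$iters_stage2)) {
    pick <- sample(seq_along(cache),
                   min(cfg$batch_stage2 %||% cfg$batch, length(cache)))
    crops <- do.call(abind4, lapply(pick, function(q) cache[[q]]$crops))
    targets <- unlist(lapply(pick, function(q) cache[[q]]$targets))
    zero_grads(params)
    pred <- regress_lengths_node(model, ag_const(crops), training = TRUE)
    loss <- ag_hybrid_l1l2(pred, matrix(targets, 1), cfg$beta)
    ag_backward(loss)
    lr <- lr_at(cfg$lr_stage2, it, cfg$warmup_iters, cfg$iters_stage2)
    gn <- sgd_step(params, lr, cfg$momentum, cfg$weight_decay, cfg$clip_norm)
    log[[it]] <- data.frame(iter = it, loss = loss$val, grad_norm = gn, lr = lr)
    if (verbose && it %% 100L == 0L)
      message(sprintf("stage2 iter %d loss %.3f", it, loss$val))
  }
  list(model = model, state = model_state(model), stage = 2L,
       log = do.call(rbind, log))
}

abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[4], 0))
  out <- array(0, c(d[1:3], n))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[4]
    out[, , , at + seq_len(k)] <- x
    at <- at + k
  }
  out
}

#' Full inference on one image
#'
#' Runs the extractors, selects instances (top-d + NMS), blends RoI features
#' with per-instance attention, emits pasted instance masks and the 64-slot
#' length vector.
#'
#' @param model a trained [glen_model()].
#' @param image H x W x 3 array in [0, 1].
#' @param grid_pitch_px optional grid pitch for mm conversion.
#' @param score_thr,d,nms_thr detection filtering parameters.
#' @return list: `boxes` data frame (with per-instance `length_px`,
#'   `length_mm` when pitch is known), `masks`, `length_vector` (64 slots),
#'   `attention`.
#' @export
predict_scene <- function(model, image, grid_pitch_px = NULL,
                          score_thr = 0.05, d = NULL, nms_thr = NULL) {
  fw <- forward_glen(model, image, training = FALSE)
  dense <- lapply(seq_along(fw$heads), function(li) {
    h <- fw$heads[[li]]
    dd <- dim4(h$cls$val)
    list(score = matrix(1 / (1 + exp(-h$cls$val[, , 1, 1])), dd[1], dd[2]),
         centerness = matrix(1 / (1 + exp(-h$ctr$val[, , 1, 1])), dd[1], dd[2]),
         ltrb = array(exp(pmin(h$reg$val[, , , 1], 12)) * model$strides[li],
                      c(dd[1], dd[2], 4L)),
         att = array(h$att$val[, , , 1], c(dd[1], dd[2], model$M^2)),
         stride = model$strides[li])
  })
  det <- select_instances(dense, M = model$M, d = d %||% model$topk,
                          nms_thr = nms_thr %||% model$nms_thr,
                          score_thr = score_thr)
  if (nrow(det$boxes) > 64L) {
    warning("more than 64 detections; keeping the 64 highest-ranked")
    det$boxes <- det$boxes[1:64, , drop = FALSE]
    det$attention <- det$attention[1:64]
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  if (!nrow(det$boxes))
    return(list(boxes = det$boxes, masks = list(),
                length_vector = numeric(64L), attention = list()))
  boxes <- as.matrix(det$boxes[, c("x1", "y1", "x2", "y2")])
  boxes[, 1] <- pmax(boxes[, 1], 0); boxes[, 2] <- pmax(boxes[, 2], 0)
  boxes[, 3] <- pmin(boxes[, 3], W); boxes[, 4] <- pmin(boxes[, 4], H)
  src <- if (model$basis_source == "B") fw$B else fw$F[[1]]
  src <- array(src$val, dim4(src$val)[1:3])
  crops <- roi_align(src, boxes, model$R, model$basis_stride)
  blended <- blend(crops, det$attention)
  masks <- lapply(seq_len(nrow(boxes)), function(q)
    predict_instance_mask(model, blended[, , , q], boxes[q, ], c(H, W)))
  reg <- regress_lengths(model, blended, training = FALSE)
  out <- det$boxes
  out$length_px <- reg$lengths[seq_len(reg$live)]
  if (!is.null(grid_pitch_px))
    out$length_mm <- px_to_mm(out$length_px, grid_pitch_px)
  list(boxes = out, masks = masks, length_vector = reg$lengths,
       attention = det$attention)
}
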