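# Instance-level feature extraction: anchor-free dense heads shared across
# the five pyramid levels, five-tuple box decoding (location pi plus l/t/r/b
# edge distances), top-d candidate filtering, greedy class-agnostic NMS, and
# per-instance M x M attention maps read from the attention logits at each
# instance's assigned location.

#' Dense head predictions for one pyramid level
#'
#' The shared head produces, at every spatial location, an objectness logit,
#' a centerness logit, four nonnegative edge distances (exp parameterization,
#' in pixels) and M*M attention logits. A grid cell (i, j) (0-based) at
#' stride s corresponds to image point ((j + 0.5) s, (i + 0.5) s).
#'
#' @param model a [glen_model()].
#' @param F_level SE-enhanced feature array (H, W, C).
#' @param stride level stride in pixels.
#' @return list of arrays: `score` and `centerness` (H, W, probabilities),
#'   `ltrb` (H, W, 4, pixels), `att` (H, W, M*M logits).
#' @export
dense_head_forward <- function(model, F_level, stride) {
  x <- ag_const(array(F_level, c(dim(F_level), 1L)))
  for (cv in model$head$tower) x <- ag_relu(fwd_conv(cv, x))
  cls <- fwd_conv(model$head$cls, x)$val
  ctr <- fwd_conv(model$head$ctr, x)$val
  reg <- fwd_conv(model$head$reg, x)$val
  att <- fwd_conv(model$head$att, x)$val
  d <- dim(cls)
  list(score = matrix(1 / (1 + exp(-cls)), d[1], d[2]),
       centerness = matrix(1 / (1 + exp(-ctr)), d[1], d[2]),
       ltrb = array(exp(pmin(reg, 12)) * stride, c(d[1], d[2], 4L)),
       att = array(att, c(d[1], d[2], model$M^2)),
       stride = stride)
}

head_locations <- function(H, W, stride) {
  # (H*W) x 2 matrix of (x, y) image points, row-major over (i, j) grid
  i <- rep(0:(H - 1L), times = W)
  j <- rep(0:(W - 1L), each = H)
  cbind(x = (j + 0.5) * stride, y = (i + 0.5) * stride)
}

decode_boxes_level <- function(dense) {
  d <- dim(dense$ltrb)
  loc <- head_locations(d[1], d[2], dense$stride)
  l <- as.vector(dense$ltrb[, , 1]); t <- as.vector(dense$ltrb[, , 2])
  r <- as.vector(dense$ltrb[, , 3]); b <- as.vector(dense$ltrb[, , 4])
  cbind(x1 = loc[, 1] - l, y1 = loc[, 2] - t,
        x2 = loc[, 1] + r, y2 = loc[, 2] + b)
}

#' Pairwise IoU between two box sets
#'
#' @param a,b matrices with columns x1, y1, x2, y2.
#' @return nrow(a) x nrow(b) IoU matrix.
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  areaA <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  areaB <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  for (i in seq_len(n)) {
    iw <- pmax(pmin(a[i, 3], b[, 3]) - pmax(a[i, 1], b[, 1]), 0)
    ih <- pmax(pmin(a[i, 4], b[, 4]) - pmax(a[i, 2], b[, 2]), 0)
    inter <- iw * ih
    out[i, ] <- inter / pmax(areaA[i] + areaB - inter, 1e-12)
  }
  out
}

#' Greedy score-descending non-maximum suppression
#'
#' Ties in score are broken by lower candidate index (stable).
#'
#' @param boxes n x 4 matrix.
#' @param scores length-n vector.
#' @param iou_thr suppression threshold.
#' @return indices of kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thr = 0.3) {
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  alive <- rep(TRUE, length(scores))
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    if (any(alive)) {
      iou <- box_iou(boxes[i, , drop = FALSE], boxes)[1, ]
      alive[iou > iou_thr] <- FALSE
    }
    alive[i] <- FALSE
  }
  keep
}

#' Select instances from dense head outputs
#'
#' Pools the top-d candidates per level ranked by score x centerness,
#' applies greedy NMS, and attaches a softmax-normalized M x M attention
#' map per kept instance.
#'
#' @param dense_levels list of per-level outputs from
#'   [dense_head_forward()].
#' @param M attention resolution.
#' @param d top candidates kept per level before pooling.
#' @param nms_thr NMS IoU threshold.
#' @param score_thr minimum objectness score.
#' @return a `detection_set`: data frame `boxes` (box, score, centerness,
#'   level, grid location) plus list `attention` of M x M maps.
#' @export
select_instances <- function(dense_levels, M = 7L, d = 100L, nms_thr = 0.3,
                             score_thr = 0.05) {
  stopifnot(d >= 1L, nms_thr > 0, nms_thr < 1)
  cand <- list()
  for (li in seq_along(dense_levels)) {
    dl <- dense_levels[[li]]
    hw <- dim(dl$score)
    sc <- as.vector(dl$score)
    rank_score <- sc * as.vector(dl$centerness)
    ok <- which(sc >= score_thr)
    if (!length(ok)) next
    ok <- ok[order(-rank_score[ok], ok)]
    ok <- ok[seq_len(min(d, length(ok)))]
    bx <- decode_boxes_level(dl)[ok, , drop = FALSE]
    gi <- ((ok - 1L) %% hw[1]) + 1L
    gj <- ((ok - 1L) %/% hw[1]) + 1L
    cand[[length(cand) + 1L]] <- data.frame(
      x1 = bx[, 1], y1 = bx[, 2], x2 = bx[, 3], y2 = bx[, 4],
      score = sc[ok], centerness = as.vector(dl$centerness)[ok],
      rank_score = rank_score[ok], level = li + 2L, gi = gi, gj = gj)
  }
  if (!length(cand))
    return(structure(list(boxes = data.frame(), attention = list()),
                     class = "detection_set"))
  cand <- do.call(rbind, cand)
  keep <- nms(as.matrix(cand[, 1:4]), cand$rank_score, nms_thr)
  kept <- cand[keep, , drop = FALSE]
  att <- vector("list", nrow(kept))
  for (q in seq_len(nrow(kept))) {
    dl <- dense_levels[[kept$level[q] - 2L]]
    logits <- dl$att[kept$gi[q], kept$gj[q], ]
    e <- exp(logits - max(logits))
    att[[q]] <- matrix(e / sum(e), M, M)
  }
  rownames(kept) <- NULL
  structure(list(boxes = kept, attention = att), class = "detection_set")
}

# Assign a ground-truth box to the dense grid: its pyramid level by the
# regression-range scheme, then the grid location nearest the box centre —
# restricted to mask-covered cells when the instance mask is supplied, so
# that training-time attention reads from the same on-object locations that
# detections originate from at inference.
assign_gt_location <- function(box, dense_levels, ranges = fcos_ranges(),
                               mask = NULL) {
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  msize <- max(box[3] - box[1], box[4] - box[2])
  li <- 1L
  for (i in seq_along(ranges)) {
    if (msize >= ranges[[i]][1] && msize <= ranges[[i]][2]) { li <- i; break }
    li <- i
  }
  dl <- dense_levels[[li]]
  hw <- if (!is.null(dim(dl$score))) dim(dl$score) else dim(dl$cls$val)[1:2]
  s <- dl$stride
  if (!is.null(mask)) {
    cov <- which(cell_coverage(mask, hw[1], hw[2], s), arr.ind = TRUE)
    if (nrow(cov)) {
      d2 <- ((cov[, 2] - 0.5) * s - cx)^2 + ((cov[, 1] - 0.5) * s - cy)^2
      k <- which.min(d2)
      return(list(level = li, gi = cov[k, 1], gj = cov[k, 2]))
    }
  }
  gi <- pmin(pmax(round(cy / s - 0.5), 0), hw[1] - 1L) + 1L
  gj <- pmin(pmax(round(cx / s - 0.5), 0), hw[2] - 1L) + 1L
  list(level = li, gi = gi, gj = gj)
}

fcos_ranges <- function() {
  list(c(-1, 64), c(64, 128), c(128, 256), c(256, 512), c(512, Inf))
}

#' Per-instance attention maps
#'
#' In inference mode the maps come from a [select_instances()] result; in
#' training mode, ground-truth boxes are assigned to grid locations and the
#' attention logits are read there. Maps are softmax-normalized over the
#' M*M positions, so each sums to one.
#'
#' @param source a `detection_set` (mode "inference") or list of per-level
#'   [dense_head_forward()] outputs (mode "training").
#' @param gt_boxes n x 4 matrix of ground-truth boxes (training mode).
#' @param mode "inference" or "training".
#' @param M attention resolution.
#' @return list of M x M matrices, one per instance.
#' @export
attention_for_instances <- function(source, gt_boxes = NULL,
                                    mode = c("inference", "training"),
                                    M = 7L) {
  mode <- match.arg(mode)
  if (mode == "inference") {
    stopifnot(inherits(source, "detection_set"))
    return(source$attention)
  }
  stopifnot(is.matrix(gt_boxes))
  lapply(seq_len(nrow(gt_boxes)), function(i) {
    asn <- assign_gt_location(gt_boxes[i, ], source)
    logits <- source[[asn$level]]$att[asn$gi, asn$gj, ]
    e <- exp(logits - max(logits))
    matrix(e / sum(e), M, M)
  })
}
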