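# Evaluation: COCO-style average precision for boxes and masks, greedy
# score-descending instance matching, regression metrics, grouped error
# reports by deviation-point count and length bin, and tie-aware rank
# correlations with permutation p-values.

mask_iou <- function(a, b) {
  i <- sum(a & b)
  u <- sum(a | b)
  if (u == 0) return(0)
  i / u
}

iou_of <- function(p, g, on) {
  if (on == "mask") mask_iou(p$mask, g$mask)
  else box_iou(matrix(p$box, 1), matrix(g$box, 1))[1, 1]
}

#' COCO-style average precision
#'
#' 101-point interpolated AP for boxes and masks at IoU 0.50, 0.75 and the
#' mean over 0.50:0.05:0.95 (maxDets 100). Detections and ground truth are
#' lists per image; each detection has `box`, `score` and optionally
#' `mask`, each ground-truth instance `box` and `mask`.
#'
#' @param detections list (per image) of lists of detections.
#' @param ground_truth list (per image) of lists of GT instances.
#' @param iou_spec IoU thresholds; default COCO 0.5:0.05:0.95.
#' @return data frame with rows (type in bbox/segm) and columns AP50, AP75,
#'   mAP; `NA` when no ground truth exists.
#' @export
coco_ap <- function(detections, ground_truth,
                    iou_spec = seq(0.5, 0.95, by = 0.05)) {
  ngt <- sum(vapply(ground_truth, length, 0L))
  ap_one <- function(on, thr) {
    if (ngt == 0) return(NA_real_)
    recs <- list()
    for (im in seq_along(detections)) {
      dets <- detections[[im]]
      if (!length(dets)) next
      sc <- vapply(dets, function(d) d$score, 0)
      ord <- order(-sc, seq_along(sc))[seq_len(min(100L, length(sc)))]
      gts <- if (im <= length(ground_truth)) ground_truth[[im]] else list()
      used <- rep(FALSE, length(gts))
      for (q in ord) {
        best <- 0; bg <- 0L
        for (g in seq_along(gts)) {
          if (used[g]) next
          v <- iou_of(dets[[q]], gts[[g]], on)
          if (v > best) { best <- v; bg <- g }
        }
        tp <- best >= thr && bg > 0L
        if (tp) used[bg] <- TRUE
        recs[[length(recs) + 1L]] <- c(score = dets[[q]]$score, tp = as.numeric(tp))
      }
    }
    if (!length(recs)) return(0)
    m <- do.call(rbind, recs)
    m <- m[order(-m[, "score"]), , drop = FALSE]
    tp <- cumsum(m[, "tp"]); fp <- cumsum(1 - m[, "tp"])
    recall <- tp / ngt
    precision <- tp / (tp + fp)
    # 101-point interpolation
    rs <- seq(0, 1, by = 0.01)
    pr <- vapply(rs, function(r) {
      sel <- recall >= r - 1e-12
      if (!any(sel)) 0 else max(precision[sel])
    }, 0)
    mean(pr)
  }
  has_masks <- any(vapply(detections, function(d)
    length(d) > 0 && !is.null(d[[1]]$mask), FALSE))
  types <- if (has_masks) c("bbox", "segm") else "bbox"
  out <- lapply(types, function(on2) {
    on <- if (on2 == "bbox") "box" else "mask"
    aps <- vapply(iou_spec, function(thr) ap_one(on, thr), 0)
    data.frame(type = on2,
               AP50 = ap_one(on, 0.5), AP75 = ap_one(on, 0.75),
               mAP = mean(aps))
  })
  do.call(rbind, out)
}

#' Greedy matching of predictions to ground truth
#'
#' Predictions are visited in descending score order; each is paired with
#' the highest-IoU unmatched ground-truth instance provided the IoU reaches
#' the threshold. Each GT matches at most once; leftovers are reported.
#'
#' @param preds list of predictions (fields `box`, `score`, optionally
#'   `mask`, `length_mm`).
#' @param gts list of ground-truth instances (fields `box`, `mask`,
#'   `length_mm`, `n_dev`).
#' @param iou_thr matching threshold (default 0.5).
#' @param on "mask" or "box" IoU.
#' @return list: `pairs` data frame (iou, length_gt, length_pred, n_dev),
#'   `unmatched_gt`, `unmatched_pred` index vectors.
#' @export
match_instances <- function(preds, gts, iou_thr = 0.5, on = c("mask", "box")) {
  on <- match.arg(on)
  sc <- vapply(preds, function(p) p$score %||% 1, 0)
  ord <- order(-sc, seq_along(preds))
  used <- rep(FALSE, length(gts))
  rows <- list(); mp <- integer(0)
  for (q in ord) {
    best <- 0; bg <- 0L
    for (g in seq_along(gts)) {
      if (used[g]) next
      v <- iou_of(preds[[q]], gts[[g]], on)
      if (v > best) { best <- v; bg <- g }
    }
    if (bg > 0L && best >= iou_thr) {
      used[bg] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        pred = q, gt = bg, iou = best,
        length_gt = gts[[bg]]$length_mm %||% NA_real_,
        length_pred = preds[[q]]$length_mm %||% NA_real_,
        n_dev = gts[[bg]]$n_dev %||% NA_integer_)
    } else {
      mp <- c(mp, q)
    }
  }
  list(pairs = if (length(rows)) do.call(rbind, rows) else
         data.frame(pred = integer(), gt = integer(), iou = numeric(),
                    length_gt = numeric(), length_pred = numeric(),
                    n_dev = integer()),
       unmatched_gt = which(!used), unmatched_pred = mp)
}

#' Regression agreement metrics over matched pairs
#'
#' @param truth,pred numeric vectors (e.g. lengths in mm), or a `pairs`
#'   data frame from [match_instances()] as first argument.
#' @return list with MAE, RMSE, Pearson, R2 (correlation is `NA` for
#'   zero-variance truth).
#' @export
regression_metrics <- function(truth, pred = NULL) {
  if (is.data.frame(truth)) {
    pred <- truth$length_pred; truth <- truth$length_gt
  }
  stopifnot(length(truth) == length(pred))
  e <- truth - pred
  pearson <- if (length(truth) >= 2 && stats::sd(truth) > 0 && stats::sd(pred) > 0)
    stats::cor(truth, pred) else NA_real_
  sst <- sum((truth - mean(truth))^2)
  list(MAE = mean(abs(e)), RMSE = sqrt(mean(e^2)),
       Pearson = pearson,
       R2 = if (sst > 0) 1 - sum(e^2) / sst else NA_real_)
}

#' Grouped error report by deviation points and length bins
#'
#' @param pairs data frame with columns `length_gt`, `length_pred`,
#'   `n_dev`.
#' @param length_breaks bin edges in mm (10 mm bins by default).
#' @return data frame with one row per (grouping, group): n, MAE, RMSE.
#' @export
grouped_report <- function(pairs,
                           length_breaks = c(10, 20, 30, 40, 50, Inf)) {
  mk <- function(sel, grouping, group) {
    if (!any(sel)) return(NULL)
    m <- regression_metrics(pairs$length_gt[sel], pairs$length_pred[sel])
    data.frame(grouping = grouping, group = group, n = sum(sel),
               MAE = m$MAE, RMSE = m$RMSE)
  }
  out <- list()
  dev_groups <- list(`0` = pairs$n_dev == 0, `1` = pairs$n_dev == 1,
                     `2` = pairs$n_dev == 2, `>=3` = pairs$n_dev >= 3)
  for (g in names(dev_groups))
    out[[length(out) + 1L]] <- mk(dev_groups[[g]], "n_dev", g)
  labs <- paste0(utils::head(length_breaks, -1), "-",
                 utils::tail(length_breaks, -1))
  for (bi in seq_len(length(length_breaks) - 1L)) {
    sel <- pairs$length_gt >= length_breaks[bi] &
      pairs$length_gt < length_breaks[bi + 1L]
    out[[length(out) + 1L]] <- mk(sel, "length_mm", labs[bi])
  }
  do.call(rbind, out)
}

#' Rank correlation between lengths and curvature categories
#'
#' Tie-aware Spearman rho and Kendall tau-b with permutation p-values
#' (two-sided, permuting the category labels).
#'
#' @param lengths numeric vector.
#' @param categories ordinal vector (deviation-point counts).
#' @param n_perm permutations for the p-values.
#' @return list: rho, tau, p_rho, p_tau (`NA`s for constant input).
#' @export
rank_correlation <- function(lengths, categories, n_perm = 999L) {
  stopifnot(length(lengths) == length(categories))
  if (length(lengths) < 3L) stop("need at least 3 observations")
  if (stats::sd(lengths) == 0 || stats::sd(categories) == 0)
    return(list(rho = NA_real_, tau = NA_real_,
                p_rho = NA_real_, p_tau = NA_real_))
  rho <- stats::cor(lengths, categories, method = "spearman")
  tau <- stats::cor(lengths, categories, method = "kendall")
  pr <- pt2 <- 1
  for (b in seq_len(n_perm)) {
    cp <- sample(categories)
    pr <- pr + (abs(stats::cor(lengths, cp, method = "spearman")) >= abs(rho))
    pt2 <- pt2 + (abs(stats::cor(lengths, cp, method = "kendall")) >= abs(tau))
  }
  list(rho = rho, tau = tau,
       p_rho = pr / (n_perm + 1), p_tau = pt2 / (n_perm + 1))
}
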