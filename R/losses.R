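# Loss components. Stage 1 combines pixel-level supervision (per-level mask
# BCE, semantic CE on the basis tensor) with instance-level detection terms
# (focal objectness, IoU box loss, centerness BCE, instance-mask BCE).
# Stage 2 uses a hybrid L2/L1 regression loss with threshold beta.

#' Stage-2 hybrid regression loss
#'
#' Mean over live slots of e^2/(2 beta) when |e| < beta, |e| - beta/2
#' otherwise, where e is the per-instance length residual. Quadratic near
#' zero for precise fitting, linear in the tails for outlier robustness;
#' continuous and once-differentiable at |e| = beta.
#'
#' @param l ground-truth lengths (live slots only).
#' @param lhat predicted lengths, same length.
#' @param beta transition threshold (default 1.0).
#' @return scalar loss.
#' @export
stage2_loss <- function(l, lhat, beta = 1) {
  stopifnot(length(l) == length(lhat), beta > 0)
  if (!length(l)) {
    warning("empty batch in stage2_loss; returning 0")
    return(0)
  }
  e <- l - lhat
  ae <- abs(e)
  mean(ifelse(ae < beta, e^2 / (2 * beta), ae - beta / 2))
}

#' Focal loss over a sample set
#'
#' -(1/npos) * sum (1 - p_t)^gamma log(p_t), with p_t the predicted
#' probability of the true class. At gamma = 0 this reduces to summed
#' cross-entropy normalized by the positive count.
#'
#' @param p predicted foreground probabilities.
#' @param y 0/1 labels of the sample set.
#' @param gamma focusing parameter (default 2).
#' @param npos normalizer; defaults to the number of positives.
#' @return scalar loss (0, with a warning, when npos is 0).
#' @export
focal_loss <- function(p, y, gamma = 2, npos = sum(y == 1)) {
  if (npos == 0) {
    warning("no positive samples in focal_loss; returning 0")
    return(0)
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  pt <- ifelse(y == 1, p, 1 - p)
  sum(-(1 - pt)^gamma * log(pt)) / npos
}

#' IoU box loss: mean of 1 - IoU over box pairs
#'
#' Perfect overlap gives zero loss; disjoint boxes give 1. Degenerate
#' ground-truth boxes are excluded with a warning.
#'
#' @param pred,gt n x 4 matrices (x1, y1, x2, y2), paired by row.
#' @return scalar loss in [0, 1].
#' @export
iou_box_loss <- function(pred, gt) {
  pred <- matrix(pred, ncol = 4); gt <- matrix(gt, ncol = 4)
  stopifnot(nrow(pred) == nrow(gt))
  ok <- (gt[, 3] > gt[, 1]) & (gt[, 4] > gt[, 2])
  if (!all(ok)) {
    warning(sum(!ok), " degenerate ground-truth box(es) excluded")
    pred <- pred[ok, , drop = FALSE]; gt <- gt[ok, , drop = FALSE]
  }
  if (!nrow(gt)) return(0)
  iou <- diag(box_iou(pred, gt))
  mean(1 - iou)
}

#' Centerness target at a location inside a box
#'
#' sqrt((min(l, r)/max(l, r)) * (min(t, b)/max(t, b))) with l/t/r/b the
#' distances from the location to the box edges: 1 at the centre, 0 on any
#' edge, 0 outside the box.
#'
#' @param pi numeric (x, y) location in pixels.
#' @param box numeric (x1, y1, x2, y2).
#' @return centerness score in [0, 1].
#' @export
centerness_target <- function(pi, box) {
  l <- pi[1] - box[1]; rr <- box[3] - pi[1]
  t <- pi[2] - box[2]; b <- box[4] - pi[2]
  if (l < 0 || rr < 0 || t < 0 || b < 0) return(0)
  lo_lr <- min(l, rr); hi_lr <- max(l, rr)
  lo_tb <- min(t, b); hi_tb <- max(t, b)
  if (hi_lr == 0 || hi_tb == 0) return(0)
  sqrt((lo_lr / hi_lr) * (lo_tb / hi_tb))
}

#' Stage-1 combined loss
#'
#' lambda1 * (pixel components) + lambda2 * (instance components). Aborts on
#' non-finite components, naming the offender.
#'
#' @param pixel named numeric vector of pixel-level components.
#' @param instance named numeric vector of instance-level components.
#' @param lambda1,lambda2 component weights (both 1.0 by default).
#' @return scalar loss.
#' @export
stage1_loss <- function(pixel, instance, lambda1 = 1, lambda2 = 1) {
  comp <- c(pixel, instance)
  if (any(!is.finite(comp)))
    stop("non-finite loss component: ",
         paste(names(comp)[!is.finite(comp)], collapse = ", "))
  lambda1 * sum(pixel) + lambda2 * sum(instance)
}

# ---- dense target assignment (anchor-free, regression-range scheme) --------

# Grid-cell coverage of an instance mask at stride s: TRUE where any mask
# pixel falls inside the cell.
cell_coverage <- function(mask, H, W, s) {
  H0 <- nrow(mask); W0 <- ncol(mask)
  padded <- matrix(FALSE, H * s, W * s)
  padded[seq_len(min(H0, H * s)), seq_len(min(W0, W * s))] <-
    mask[seq_len(min(H0, H * s)), seq_len(min(W0, W * s))]
  dim(padded) <- c(s, H, s, W)
  apply(padded, c(2, 4), any)
}

# For one image: per-level 0/1 objectness targets, positive locations with
# their ltrb and centerness targets. With instance masks available,
# positives are the in-box grid cells that the mask actually covers (thin
# curved structures rarely pass through their own box centre, so sampling
# around the centre would supervise background cells); without masks,
# positives fall back to centre sampling within `radius` strides. Ties go
# to the smaller box.
assign_dense_targets <- function(gt_boxes, level_dims, strides,
                                 ranges = fcos_ranges(), radius = 1.5,
                                 masks = NULL) {
  nl <- length(level_dims)
  out <- vector("list", nl)
  areas <- if (nrow(gt_boxes)) (gt_boxes[, 3] - gt_boxes[, 1]) *
    (gt_boxes[, 4] - gt_boxes[, 2]) else numeric(0)
  for (li in seq_len(nl)) {
    H <- level_dims[[li]][1]; W <- level_dims[[li]][2]; s <- strides[li]
    loc <- head_locations(H, W, s)
    lab <- matrix(0, H, W)
    pos <- list()
    if (nrow(gt_boxes)) {
      best_area <- matrix(Inf, H, W)
      best_box <- matrix(0L, H, W)
      for (g in seq_len(nrow(gt_boxes))) {
        b <- gt_boxes[g, ]
        msize <- max(b[3] - b[1], b[4] - b[2])
        if (msize < ranges[[li]][1] || msize > ranges[[li]][2]) next
        cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
        l <- loc[, 1] - b[1]; t <- loc[, 2] - b[2]
        r <- b[3] - loc[, 1]; bo <- b[4] - loc[, 2]
        inside <- l > 0 & t > 0 & r > 0 & bo > 0
        near <- if (!is.null(masks))
          as.vector(cell_coverage(masks[[g]], H, W, s))
        else
          abs(loc[, 1] - cx) <= radius * s & abs(loc[, 2] - cy) <= radius * s
        sel <- which(inside & near)
        for (q in sel) {
          i <- ((q - 1L) %% H) + 1L; j <- ((q - 1L) %/% H) + 1L
          if (areas[g] < best_area[i, j]) {
            best_area[i, j] <- areas[g]; best_box[i, j] <- g
          }
        }
      }
      idx <- which(best_box > 0L, arr.ind = TRUE)
      if (nrow(idx)) {
        lab[idx] <- 1
        pos <- lapply(seq_len(nrow(idx)), function(kk) {
          i <- idx[kk, 1]; j <- idx[kk, 2]
          g <- best_box[i, j]
          b <- gt_boxes[g, ]
          x <- (j - 1 + 0.5) * s; y <- (i - 1 + 0.5) * s
          list(i = i, j = j, gt = g,
               ltrb = c(x - b[1], y - b[2], b[3] - x, b[4] - y),
               centerness = centerness_target(c(x, y), b))
        })
      }
    }
    out[[li]] <- list(labels = lab, positives = pos, stride = s)
  }
  out
}
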