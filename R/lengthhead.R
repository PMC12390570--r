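# Radicle length predictor: RoIAlign crops of the stride-8 pyramid level,
# multiplicative blending with per-instance attention, instance mask
# emission, and the conv-BN-ReLU -> GAP -> FC regressor that fills a fixed
# 64-slot per-image length vector.

#' RoIAlign crop of a feature map
#'
#' Bilinear RoI-aligned crop with 2x2 sampling points per output bin.
#'
#' @param feature array (H, W, C) in feature-grid resolution.
#' @param boxes n x 4 matrix (x1, y1, x2, y2) in image pixels.
#' @param R output resolution (R x R).
#' @param stride feature stride relative to image pixels.
#' @return array (R, R, C, n).
#' @export
roi_align <- function(feature, boxes, R = 14L, stride = 8) {
  if (R < 2L) stop("R must be >= 2")
  boxes <- matrix(boxes, ncol = 4)
  w <- boxes[, 3] - boxes[, 1]; h <- boxes[, 4] - boxes[, 2]
  if (any(w <= 0 | h <= 0))
    stop("degenerate box (zero area) in roi_align: instance ",
         which(w <= 0 | h <= 0)[1])
  d <- dim(feature)
  cpp_roi_align_fw(array(feature, c(d, 1L)), boxes, as.integer(R), 1 / stride)
}

#' Blend RoI features with an instance attention map
#'
#' The M x M attention map is bilinearly upsampled to R x R, broadcast over
#' channels and multiplied elementwise with the crop: f' = f (*) A.
#'
#' @param fi array (R, R, C) or (R, R, C, n) of RoI-aligned features.
#' @param Ai M x M attention matrix (single instance) or list of maps.
#' @return blended array of the same shape as `fi`.
#' @export
blend <- function(fi, Ai) {
  d <- dim(fi)
  if (length(d) == 3L) { fi <- array(fi, c(d, 1L)); d <- dim(fi) }
  maps <- if (is.list(Ai)) Ai else list(Ai)
  if (length(maps) != d[4]) stop("number of attention maps must match crops")
  out <- fi
  for (q in seq_len(d[4])) {
    A <- maps[[q]]
    up <- cpp_resize_bilinear_fw(array(A, c(dim(A), 1L, 1L)),
                                 as.integer(d[1]), as.integer(d[2]))
    out[, , , q] <- fi[, , , q] * array(up, c(d[1], d[2], d[3]))
  }
  out
}

#' Predict a pasted binary instance mask
#'
#' Applies the 1x1 mask projection to blended RoI features, takes sigmoid,
#' resizes the R x R probability patch to the box extent, thresholds, and
#' pastes into image coordinates. Pixels outside the box are background.
#'
#' @param model a [glen_model()].
#' @param blended array (R, R, C) of blended features for one instance.
#' @param box numeric (x1, y1, x2, y2) in image pixels.
#' @param image_size (H, W) of the target image.
#' @param threshold probability threshold in (0, 1).
#' @return logical H x W mask.
#' @export
predict_instance_mask <- function(model, blended, box, image_size,
                                  threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  d <- dim(blended)
  x <- ag_const(array(blended, c(d[1], d[2], d[3], 1L)))
  logits <- fwd_conv(model$mask_head, x)$val
  prob <- 1 / (1 + exp(-logits))
  H <- image_size[1]; W <- image_size[2]
  x1 <- max(0L, floor(box[1])); y1 <- max(0L, floor(box[2]))
  x2 <- min(W, ceiling(box[3])); y2 <- min(H, ceiling(box[4]))
  mask <- matrix(FALSE, H, W)
  bw <- x2 - x1; bh <- y2 - y1
  if (bw < 1 || bh < 1) return(mask)
  patch <- cpp_resize_bilinear_fw(prob, as.integer(bh), as.integer(bw))
  mask[(y1 + 1L):y2, (x1 + 1L):x2] <- matrix(patch, bh, bw) >= threshold
  mask
}

#' Regress per-instance lengths into the fixed 64-slot vector
#'
#' Two 3x3 conv + BN + ReLU blocks refine the blended crops, global average
#' pooling condenses them to one 64-vector per instance, and two fully
#' connected layers map to a scalar length (network-input pixels). Scalars
#' are placed in score order into a 64-slot vector; slots beyond the live
#' instance count are exactly zero.
#'
#' @param model a [glen_model()].
#' @param blended array (R, R, C, n) of blended crops in score order, or
#'   NULL/zero-instance input.
#' @param training use batch statistics in BN (training) or running
#'   statistics (inference).
#' @return list: `lengths` (the 64-slot vector), `live` (instance count).
#' @export
regress_lengths <- function(model, blended, training = FALSE) {
  slots <- 64L
  if (is.null(blended) || length(blended) == 0L || dim(blended)[4] == 0L) {
    warning("no instances; returning all-zero length vector")
    return(list(lengths = numeric(slots), live = 0L))
  }
  n <- dim(blended)[4]
  if (n > slots) {
    warning("more than ", slots, " instances; keeping the ", slots,
            " highest-scoring")
    blended <- blended[, , , seq_len(slots), drop = FALSE]
    n <- slots
  }
  node <- regress_lengths_node(model, ag_const(blended), training)
  out <- numeric(slots)
  out[seq_len(n)] <- as.numeric(node$val)
  list(lengths = out, live = n)
}

# node-level regressor used by both inference and stage-2 training
regress_lengths_node <- function(model, crops, training = FALSE) {
  lh <- model$len_head
  x <- ag_relu(fwd_bn(lh$bn1, fwd_conv(lh$conv1, crops), training))
  x <- ag_relu(fwd_bn(lh$bn2, fwd_conv(lh$conv2, x), training))
  v <- ag_gap2d(x)                        # (64, n)
  v <- ag_relu(fwd_fc(lh$fc1, v))
  fwd_fc(lh$fc2, v)                       # (1, n)
}
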