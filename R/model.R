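# Model construction and the pixel-level path: residual backbone (C3-C5),
# feature pyramid (P3-P7, one shared channel width), per-level
# squeeze-and-excitation recalibration (F3-F7) and the basis decoder that
# fuses F3-F5 into a k-channel stride-4 basis tensor B.

#' Construct a radicle segmentation/length model
#'
#' @param profile "resnet50" (bottleneck backbone with 256-channel pyramid,
#'   the full-scale configuration) or "tiny" (3-stage residual backbone with
#'   channels 64/128/256 and a 64-channel pyramid for CPU-scale training).
#' @param k number of basis channels produced by the pixel decoder.
#' @param n number of 3x3 convolutions in the decoder fusion tower.
#' @param se_ratio squeeze-and-excitation reduction ratio r.
#' @param M spatial resolution of per-instance attention maps (M x M).
#' @param R RoIAlign output resolution.
#' @param topk top-d candidate boxes retained per pyramid level.
#' @param nms_thr IoU threshold of greedy non-maximum suppression.
#' @param basis_source feature map RoIAligned by the length head: "F3" (the
#'   finest SE-enhanced pyramid level, stride 8) or "B" (the decoder's basis
#'   tensor, stride 4, in the style of attention-blended basis methods).
#' @param seed seed for weight initialization.
#' @return a `glen_model` list.
#' @export
glen_model <- function(profile = c("tiny", "resnet50"), k = 4L, n = 3L,
                       se_ratio = 16L, M = 7L, R = 14L, topk = 100L,
                       nms_thr = 0.3, basis_source = c("F3", "B"),
                       seed = NULL) {
  profile <- match.arg(profile)
  basis_source <- match.arg(basis_source)
  if (n < 1L || k < 1L) stop("decoder hyperparameters n and k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (profile == "resnet50") {
    fpn_ch <- 256L
    cch <- c(512L, 1024L, 2048L)
    backbone <- list(
      stem = list(conv = new_conv(7, 7, 3, 64, 2, pad = 3L), bn = new_bn(64)),
      stages = list(
        make_stage_bottleneck(64L, 64L, 3L, stride = 1L),
        make_stage_bottleneck(256L, 128L, 4L, stride = 2L),
        make_stage_bottleneck(512L, 256L, 6L, stride = 2L),
        make_stage_bottleneck(1024L, 512L, 3L, stride = 2L)))
    len_mid <- 128L
  } else {
    fpn_ch <- 64L
    cch <- c(64L, 128L, 256L)
    backbone <- list(
      stem = list(conv1 = new_conv(3, 3, 3, 16, 2), bn1 = new_bn(16),
                  conv2 = new_conv(3, 3, 16, 32, 2), bn2 = new_bn(32)),
      stages = list(
        list(new_basic_block(32L, 64L, 2L)),
        list(new_basic_block(64L, 128L, 2L)),
        list(new_basic_block(128L, 256L, 2L))))
    len_mid <- 64L
  }
  model <- list(
    profile = profile, k = as.integer(k), n = as.integer(n),
    se_ratio = as.integer(se_ratio), M = as.integer(M), R = as.integer(R),
    topk = as.integer(topk), nms_thr = nms_thr,
    fpn_ch = fpn_ch, strides = c(8L, 16L, 32L, 64L, 128L),
    # regression-range level assignment; the tiny profile works on ~192-256 px
    # inputs where objects are proportionally large, so its ranges keep most
    # instances on the two finest levels
    ranges = if (profile == "resnet50") fcos_ranges() else
      list(c(-1, 96), c(96, 192), c(192, 384), c(384, 768), c(768, Inf)),
    basis_source = basis_source,
    basis_stride = if (basis_source == "B") 4L else 8L,
    backbone = backbone,
    fpn = list(lat3 = new_conv(1, 1, cch[1], fpn_ch, 1, pad = 0L),
               lat4 = new_conv(1, 1, cch[2], fpn_ch, 1, pad = 0L),
               lat5 = new_conv(1, 1, cch[3], fpn_ch, 1, pad = 0L)),
    se = lapply(1:5, function(i) new_se(fpn_ch, se_ratio)),
    decoder = list(
      norm = lapply(1:3, function(i)
        list(conv = new_conv(3, 3, fpn_ch, fpn_ch, 1), bn = new_bn(fpn_ch))),
      tower = lapply(seq_len(n), function(i) new_conv(3, 3, fpn_ch, fpn_ch, 1)),
      post = new_conv(3, 3, fpn_ch, fpn_ch, 1),
      final = new_conv(1, 1, fpn_ch, k, 1, pad = 0L)),
    head = list(
      tower = list(new_conv(3, 3, fpn_ch, fpn_ch, 1),
                   new_conv(3, 3, fpn_ch, fpn_ch, 1)),
      cls = new_conv(3, 3, fpn_ch, 1, 1, bias_init = -log(99)),
      ctr = new_conv(3, 3, fpn_ch, 1, 1),
      reg = new_conv(3, 3, fpn_ch, 4, 1, bias_init = 0.7),
      att = new_conv(3, 3, fpn_ch, M * M, 1)),
    proj_mask = new_conv(1, 1, fpn_ch, 1, 1, pad = 0L),
    sem = new_conv(1, 1, k, 2, 1, pad = 0L),
    mask_head = new_conv(1, 1, if (basis_source == "B") k else fpn_ch,
                         1, 1, pad = 0L),
    len_head = list(conv1 = new_conv(3, 3,
                      if (basis_source == "B") k else fpn_ch, len_mid, 1),
                    bn1 = new_bn(len_mid),
                    conv2 = new_conv(3, 3, len_mid, 64, 1),
                    bn2 = new_bn(64),
                    fc1 = new_fc(64, 64),
                    fc2 = new_fc(64, 1, bias_init = 60)))
  class(model) <- "glen_model"
  model
}

make_stage_bottleneck <- function(ci, w, nblock, stride) {
  c(list(new_bottleneck(ci, w, stride)),
    lapply(seq_len(nblock - 1L), function(i) new_bottleneck(4L * w, w, 1L)))
}

#' @export
print.glen_model <- function(x, ...) {
  np <- sum(vapply(collect_params(x), function(p) length(p$val), 0))
  cat("<glen_model profile=", x$profile, " pyramid=", x$fpn_ch,
      "ch k=", x$k, " n=", x$n, " M=", x$M, " params=", np, ">\n", sep = "")
  invisible(x)
}

pad_to_stride <- function(img, stride = 32L) {
  d <- dim(img)
  H <- as.integer(ceiling(d[1] / stride) * stride)
  W <- as.integer(ceiling(d[2] / stride) * stride)
  if (H == d[1] && W == d[2]) return(img)
  out <- array(0, c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- img
  out
}

as_batch <- function(img) {
  # (H, W, 3) array -> (H, W, 3, 1)
  d <- dim(img)
  if (length(d) == 4L) return(img)
  array(img, c(d, 1L))
}

# ---- internal node-level forwards ------------------------------------------

forward_backbone <- function(model, x, training = FALSE) {
  bb <- model$backbone
  if (model$profile == "resnet50") {
    y <- ag_relu(fwd_bn(bb$stem$bn, fwd_conv(bb$stem$conv, x), training))
    y <- ag_maxpool(y, 3L, 2L, 1L)
    for (bl in bb$stages[[1]]) y <- fwd_bottleneck(bl, y, training)
    c3 <- y
    for (bl in bb$stages[[2]]) c3 <- fwd_bottleneck(bl, c3, training)
    c4 <- c3
    for (bl in bb$stages[[3]]) c4 <- fwd_bottleneck(bl, c4, training)
    c5 <- c4
    for (bl in bb$stages[[4]]) c5 <- fwd_bottleneck(bl, c5, training)
    list(C3 = c3, C4 = c4, C5 = c5)
  } else {
    y <- ag_relu(fwd_bn(bb$stem$bn1, fwd_conv(bb$stem$conv1, x), training))
    y <- ag_relu(fwd_bn(bb$stem$bn2, fwd_conv(bb$stem$conv2, y), training))
    c3 <- y
    for (bl in bb$stages[[1]]) c3 <- fwd_basic_block(bl, c3, training)
    c4 <- c3
    for (bl in bb$stages[[2]]) c4 <- fwd_basic_block(bl, c4, training)
    c5 <- c4
    for (bl in bb$stages[[3]]) c5 <- fwd_basic_block(bl, c5, training)
    list(C3 = c3, C4 = c4, C5 = c5)
  }
}

forward_fpn <- function(model, C) {
  p5 <- fwd_conv(model$fpn$lat5, C$C5)
  d4 <- dim4(C$C4$val); d3 <- dim4(C$C3$val); d5 <- dim4(p5$val)
  p4 <- ag_add(ag_resize(p5, d4[1], d4[2]), fwd_conv(model$fpn$lat4, C$C4))
  p3 <- ag_add(ag_resize(p4, d3[1], d3[2]), fwd_conv(model$fpn$lat3, C$C3))
  p6 <- ag_resize(p5, as.integer(ceiling(d5[1] / 2)), as.integer(ceiling(d5[2] / 2)))
  d6 <- dim4(p6$val)
  p7 <- ag_resize(p6, as.integer(ceiling(d6[1] / 2)), as.integer(ceiling(d6[2] / 2)))
  list(P3 = p3, P4 = p4, P5 = p5, P6 = p6, P7 = p7)
}

forward_se_level <- function(se, P) {
  z <- ag_gap2d(P)                       # (C, N) spatial means
  s <- ag_sigmoid(ag_matmul(se$W2, ag_relu(ag_matmul(se$W1, z))))
  ag_scale_channels(P, s)
}

forward_se <- function(model, P) {
  out <- lapply(1:5, function(i) forward_se_level(model$se[[i]], P[[i]]))
  names(out) <- paste0("F", 3:7)
  out
}

forward_decoder <- function(model, Fmaps, training = FALSE) {
  dc <- model$decoder
  tilde <- lapply(1:3, function(i)
    ag_relu(fwd_bn(dc$norm[[i]]$bn, fwd_conv(dc$norm[[i]]$conv, Fmaps[[i]]), training)))
  d3 <- dim4(tilde[[1]]$val)
  x <- ag_add(tilde[[1]],
              ag_add(ag_resize(tilde[[2]], d3[1], d3[2]),
                     ag_resize(tilde[[3]], d3[1], d3[2])))
  for (cv in dc$tower) x <- ag_relu(fwd_conv(cv, x))
  x <- ag_resize(x, 2L * d3[1], 2L * d3[2])
  x <- fwd_conv(dc$post, x)
  fwd_conv(dc$final, x)
}

forward_heads <- function(model, Fmaps) {
  lapply(seq_along(Fmaps), function(i) {
    x <- Fmaps[[i]]
    for (cv in model$head$tower) x <- ag_relu(fwd_conv(cv, x))
    list(cls = fwd_conv(model$head$cls, x),
         ctr = fwd_conv(model$head$ctr, x),
         reg = fwd_conv(model$head$reg, x),
         att = fwd_conv(model$head$att, x),
         stride = model$strides[i])
  })
}

# full pixel+instance forward used in training and inference
forward_glen <- function(model, img, training = FALSE) {
  x <- ag_const(as_batch(pad_to_stride(img)))
  C <- forward_backbone(model, x, training)
  P <- forward_fpn(model, C)
  Fm <- forward_se(model, P)
  B <- forward_decoder(model, Fm, training)
  heads <- forward_heads(model, Fm)
  list(input = x, C = C, P = P, F = Fm, B = B, heads = heads)
}

# ---- public array-level operations -----------------------------------------

#' Backbone feature maps C3-C5
#'
#' Runs the residual backbone on an RGB image (values in [0, 1]), returning
#' the stride-8/16/32 feature maps. Earlier, denser stages are never
#' materialized for downstream use.
#'
#' @param model a [glen_model()].
#' @param image H x W x 3 array; padded to a multiple of 32 internally.
#' @return list with arrays `C3`, `C4`, `C5` of dimension (H, W, C).
#' @export
backbone_forward <- function(model, image) {
  d <- dim(image)
  if (d[1] < 32 || d[2] < 32) stop("image smaller than one stride-32 cell")
  C <- forward_backbone(model, ag_const(as_batch(pad_to_stride(image))), FALSE)
  lapply(C, function(n) array(n$val, dim4(n$val)[1:3]))
}

#' Feature pyramid P3-P7 from backbone maps
#'
#' P5 is a 1x1 convolution of C5; P6 and P7 downsample by factors of two;
#' P4 and P3 add upsampled top-down context to 1x1 lateral projections of C4
#' and C3. All levels share one channel width.
#'
#' @param model a [glen_model()].
#' @param cmaps list with C3, C4, C5 arrays (H, W, C).
#' @return list of arrays P3..P7.
#' @export
build_pyramid <- function(model, cmaps) {
  tonode <- function(a) ag_const(array(a, c(dim(a), 1L)))
  P <- forward_fpn(model, list(C3 = tonode(cmaps$C3), C4 = tonode(cmaps$C4),
                               C5 = tonode(cmaps$C5)))
  lapply(P, function(n) array(n$val, dim4(n$val)[1:3]))
}

#' Squeeze-and-excitation channel recalibration
#'
#' Squeeze: per-channel spatial mean z. Excitation: gate
#' s = sigmoid(W2 ReLU(W1 z)). Scale: F = s * P channel-wise. A pure channel
#' reweighting -- spatial structure is untouched.
#'
#' @param P feature map array (H, W, C).
#' @param se a layer with matrices `W1` ((c/r) x c) and `W2` (c x (c/r)),
#'   e.g. one element of `model$se`.
#' @return recalibrated array F of the same shape, plus attributes `z`
#'   (squeeze vector) and `s` (gate).
#' @export
se_recalibrate <- function(P, se) {
  W1 <- if (inherits(se$W1, "agnode")) se$W1$val else se$W1
  W2 <- if (inherits(se$W2, "agnode")) se$W2$val else se$W2
  if (ncol(W1) != dim(P)[3]) stop("SE weight shape does not match channels")
  z <- apply(P, 3, mean)
  s <- 1 / (1 + exp(-(W2 %*% pmax(W1 %*% z, 0))))
  out <- sweep(P, 3, as.numeric(s), `*`)
  attr(out, "z") <- z
  attr(out, "s") <- as.numeric(s)
  out
}

#' Decode the basis tensor B from SE-enhanced maps F3-F5
#'
#' Each input is normalized by conv3x3 + BN + ReLU; F4 and F5 are upsampled
#' to the stride-8 grid and summed with F3; a tower of n 3x3 convolutions
#' fuses scales; the result is upsampled to stride 4 and projected to k
#' channels by a 3x3 then 1x1 convolution.
#'
#' @param model a [glen_model()].
#' @param fmaps list with F3, F4, F5 arrays.
#' @return basis array (H/4, W/4, k) for a stride-8 F3 of size (H/8, W/8).
#' @export
decode_bases <- function(model, fmaps) {
  tonode <- function(a) ag_const(array(a, c(dim(a), 1L)))
  B <- forward_decoder(model, list(tonode(fmaps$F3), tonode(fmaps$F4),
                                   tonode(fmaps$F5)), FALSE)
  array(B$val, dim4(B$val)[1:3])
}
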