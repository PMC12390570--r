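# Minimal reverse-mode autodiff over (H, W, C, N) arrays. Every differentiable
# quantity is an `agnode` environment holding a value, accumulated gradient,
# parent nodes and a backward closure. The graph is taped implicitly through
# parent links; ag_backward() runs a topological sweep from a scalar loss.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

ag_node <- function(val, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  .ag_counter$n <- .ag_counter$n + 1L
  e$id <- .ag_counter$n
  e$val <- val
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  class(e) <- "agnode"
  e
}

#' @export
print.agnode <- function(x, ...) {
  d <- dim(x$val)
  cat("<agnode", if (is.null(d)) paste0("len ", length(x$val)) else paste(d, collapse = "x"),
      if (isTRUE(x$is_param)) "param" else "", ">\n")
  invisible(x)
}

ag_param <- function(val) {
  e <- ag_node(val)
  e$is_param <- TRUE
  e$mom <- NULL
  e
}

ag_const <- function(val) ag_node(val)

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Topological order by iterative DFS, then reverse sweep.
ag_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  order <- list(); seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, i = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    key <- as.character(node$id)
    if (top$i == 0L && !is.null(seen[[key]])) { stack[[length(stack)]] <- NULL; next }
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- node$parents[[top$i + 1L]]
      ckey <- as.character(child$id)
      if (is.null(seen[[ckey]])) stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
    } else {
      seen[[key]] <- TRUE
      order[[length(order) + 1L]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  loss$grad <- 1
  for (k in rev(seq_along(order))) {
    node <- order[[k]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node$grad)
  }
  invisible(NULL)
}

dim4 <- function(x) { d <- dim(x); stopifnot(length(d) == 4L); d }

# ---- primitive ops ---------------------------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  y <- cpp_conv2d_fw(x$val, w$val, b$val, as.integer(stride), as.integer(pad))
  ag_node(y, list(x, w, b), function(g) {
    dim(g) <- dim(y)
    bw <- cpp_conv2d_bw(x$val, w$val, g, as.integer(stride), as.integer(pad))
    ag_accum(x, bw$gx); ag_accum(w, bw$gw); ag_accum(b, bw$gb)
  })
}

ag_relu <- function(x) {
  m <- x$val > 0
  ag_node(x$val * m, list(x), function(g) ag_accum(x, g * m))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ag_node(s, list(x), function(g) ag_accum(x, g * s * (1 - s)))
}

ag_exp <- function(x) {
  v <- exp(pmin(x$val, 20))
  ag_node(v, list(x), function(g) ag_accum(x, g * v * (x$val < 20)))
}

ag_add <- function(x, y) {
  ag_node(x$val + y$val, list(x, y), function(g) { ag_accum(x, g); ag_accum(y, g) })
}

ag_mul <- function(x, y) {
  ag_node(x$val * y$val, list(x, y), function(g) {
    ag_accum(x, g * y$val); ag_accum(y, g * x$val)
  })
}

ag_scalar_mul <- function(x, a) {
  ag_node(x$val * a, list(x), function(g) ag_accum(x, g * a))
}

# Spatial global average pool: (H,W,C,N) -> (C,N)
ag_gap2d <- function(x) {
  d <- dim4(x$val)
  v <- apply(x$val, c(3, 4), mean)
  dim(v) <- d[3:4]
  ag_node(v, list(x), function(g) {
    dim(g) <- d[3:4]
    gx <- aperm(array(g, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2)) / (d[1] * d[2])
    ag_accum(x, gx)
  })
}

# Matrix product w (Cout x Cin) %*% x (Cin, N), no bias.
ag_matmul <- function(w, x) {
  v <- w$val %*% x$val
  ag_node(v, list(w, x), function(g) {
    dim(g) <- dim(v)
    ag_accum(w, tcrossprod(g, x$val))
    ag_accum(x, crossprod(w$val, g))
  })
}

# Fully connected on (Cin, N) -> (Cout, N)
ag_fc <- function(x, w, b) {
  v <- w$val %*% x$val + b$val
  ag_node(v, list(x, w, b), function(g) {
    dim(g) <- dim(v)
    ag_accum(x, crossprod(w$val, g))
    ag_accum(w, tcrossprod(g, x$val))
    ag_accum(b, rowSums(g))
  })
}

# Channel-wise scaling: x (H,W,C,N) * s (C,N), broadcast over H, W.
ag_scale_channels <- function(x, s) {
  d <- dim4(x$val)
  sfull <- aperm(array(s$val, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
  ag_node(x$val * sfull, list(x, s), function(g) {
    dim(g) <- d
    ag_accum(x, g * sfull)
    gs <- apply(g * x$val, c(3, 4), sum)
    dim(gs) <- d[3:4]
    ag_accum(s, gs)
  })
}

ag_resize <- function(x, Ho, Wo) {
  d <- dim4(x$val)
  if (Ho == d[1] && Wo == d[2]) return(x)
  y <- cpp_resize_bilinear_fw(x$val, as.integer(Ho), as.integer(Wo))
  ag_node(y, list(x), function(g) {
    dim(g) <- dim(y)
    ag_accum(x, cpp_resize_bilinear_bw(g, d[1], d[2]))
  })
}

ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim4(x$val)
  r <- cpp_maxpool_fw(x$val, as.integer(k), as.integer(stride), as.integer(pad))
  ag_node(r$y, list(x), function(g) {
    dim(g) <- dim(r$y)
    ag_accum(x, cpp_maxpool_bw(g, r$argmax, d[1], d[2], d[3], d[4]))
  })
}

# Batch norm over (H, W, N) per channel. `state` is the layer environment
# holding running_mean / running_var; training mode uses batch statistics.
ag_bn2d <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim4(x$val)
  C <- d[3]
  xp <- aperm(x$val, c(1, 2, 4, 3))
  dim(xp) <- c(d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xp)
    va <- colMeans(xp^2) - mu^2
    m <- nrow(xp)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * m / max(m - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xp, 2, mu), 2, istd, `*`)
  yp <- sweep(sweep(xhat, 2, gamma$val, `*`), 2, beta$val, `+`)
  y <- aperm(array(yp, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  ag_node(y, list(x, gamma, beta), function(g) {
    gp <- aperm(g, c(1, 2, 4, 3))
    dim(gp) <- c(d[1] * d[2] * d[4], C)
    ag_accum(gamma, colSums(gp * xhat))
    ag_accum(beta, colSums(gp))
    gxh <- sweep(gp, 2, gamma$val, `*`)
    if (training) {
      m <- nrow(gp)
      t1 <- colMeans(gxh)
      t2 <- colMeans(gxh * xhat)
      gxp <- sweep(gxh, 2, t1) - sweep(xhat, 2, t2, `*`)
      gxp <- sweep(gxp, 2, istd, `*`)
    } else {
      gxp <- sweep(gxh, 2, istd, `*`)
    }
    gx <- aperm(array(gxp, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    ag_accum(x, gx)
  })
}

# Gather dense-map values at locations: x (H,W,C,N), idx (P x 3) 1-based
# (h, w, n) rows -> (C, P) matrix. Backward scatter-adds.
ag_gather_loc <- function(x, idx) {
  d <- dim4(x$val)
  P <- nrow(idx)
  v <- matrix(0, d[3], P)
  for (p in seq_len(P))
    v[, p] <- x$val[idx[p, 1], idx[p, 2], , idx[p, 3]]
  ag_node(v, list(x), function(g) {
    dim(g) <- c(d[3], P)
    gx <- array(0, d)
    for (p in seq_len(P))
      gx[idx[p, 1], idx[p, 2], , idx[p, 3]] <-
        gx[idx[p, 1], idx[p, 2], , idx[p, 3]] + g[, p]
    ag_accum(x, gx)
  })
}

# Column-wise softmax on (C, P).
ag_softmax_cols <- function(x) {
  v <- x$val
  v <- sweep(v, 2, apply(v, 2, max))
  e <- exp(v)
  s <- sweep(e, 2, colSums(e), `/`)
  ag_node(s, list(x), function(g) {
    dim(g) <- dim(s)
    dot <- colSums(g * s)
    ag_accum(x, s * sweep(g, 2, dot))
  })
}

# RoIAlign from a single-image feature node; boxes are image-space pixels.
ag_roi_align <- function(feat, boxes, R, scale) {
  d <- dim4(feat$val)
  stopifnot(d[4] == 1L)
  y <- cpp_roi_align_fw(feat$val, boxes, as.integer(R), scale)
  ag_node(y, list(feat), function(g) {
    dim(g) <- dim(y)
    ag_accum(feat, cpp_roi_align_bw(g, boxes, d[1], d[2], d[3], as.integer(R), scale))
  })
}

ag_sum_scalars <- function(nodes, weights = rep(1, length(nodes))) {
  v <- sum(vapply(seq_along(nodes), function(i) weights[i] * nodes[[i]]$val, 0))
  ag_node(v, nodes, function(g) {
    for (i in seq_along(nodes)) ag_accum(nodes[[i]], g * weights[i])
  })
}

# Column-bind (C, k_i) matrices along the second axis.
ag_cbind <- function(nodes) {
  if (length(nodes) == 1L) return(nodes[[1]])
  vals <- do.call(cbind, lapply(nodes, function(n) n$val))
  ks <- vapply(nodes, function(n) ncol(n$val), 0L)
  ends <- cumsum(ks)
  ag_node(vals, nodes, function(g) {
    dim(g) <- dim(vals)
    for (i in seq_along(nodes))
      ag_accum(nodes[[i]], g[, (ends[i] - ks[i] + 1L):ends[i], drop = FALSE])
  })
}

# Select one sample from the batch axis: (H,W,C,N) -> (H,W,C,1).
ag_select_n <- function(x, n) {
  d <- dim4(x$val)
  v <- x$val[, , , n, drop = FALSE]
  ag_node(v, list(x), function(g) {
    dim(g) <- dim(v)
    gx <- array(0, d)
    gx[, , , n] <- g
    ag_accum(x, gx)
  })
}

ag_reshape <- function(x, newdim) {
  old <- dim(x$val)
  v <- x$val
  dim(v) <- newdim
  ag_node(v, list(x), function(g) {
    dim(g) <- old
    ag_accum(x, g)
  })
}

# Multiply (R,R,C,P) features by a (R,R,1,P) spatial map, broadcast over C.
ag_mul_bc_ch <- function(x, a) {
  d <- dim4(x$val)
  af <- array(0, d)
  for (p in seq_len(d[4])) af[, , , p] <- array(a$val[, , 1, p], c(d[1], d[2], d[3]))
  ag_node(x$val * af, list(x, a), function(g) {
    dim(g) <- d
    ag_accum(x, g * af)
    ga <- array(0, dim(a$val))
    gx <- g * x$val
    for (p in seq_len(d[4])) ga[, , 1, p] <- apply(gx[, , , p, drop = FALSE], c(1, 2), sum)
    ag_accum(a, ga)
  })
}

# ---- losses as scalar nodes ------------------------------------------------

# Binary cross-entropy with logits; `target` same shape; `norm` divides.
# `pos_weight` > 1 up-weights foreground pixels (thin structures fill only a
# small fraction of their box, so unweighted BCE favours all-background).
ag_bce_logits <- function(x, target, norm = length(target), pos_weight = 1) {
  z <- x$val
  p <- pmin(pmax(1 / (1 + exp(-z)), 1e-12), 1 - 1e-12)
  if (pos_weight == 1) {
    ll <- pmax(z, 0) - z * target + log1p(exp(-abs(z)))
    return(ag_node(sum(ll) / norm, list(x), function(g) {
      ag_accum(x, g * (p - target) / norm)
    }))
  }
  ll <- -(pos_weight * target * log(p) + (1 - target) * log(1 - p))
  ag_node(sum(ll) / norm, list(x), function(g) {
    grad <- (-pos_weight * target * (1 - p) + (1 - target) * p)
    ag_accum(x, g * grad / norm)
  })
}

# Sigmoid focal loss on logits with 0/1 targets, normalized by npos.
ag_focal_logits <- function(x, target, gamma = 2, npos = max(1, sum(target))) {
  p <- 1 / (1 + exp(-x$val))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(target == 1, p, 1 - p)
  modf <- (1 - pt)^gamma
  loss <- sum(-modf * log(pt)) / npos
  ag_node(loss, list(x), function(g) {
    dldpt <- gamma * (1 - pt)^(gamma - 1) * log(pt) - modf / pt
    dptdx <- p * (1 - p) * ifelse(target == 1, 1, -1)
    ag_accum(x, g * dldpt * dptdx / npos)
  })
}

# Mean (1 - IoU) over columns of predicted/target ltrb matrices (4 x P).
ag_iou_loss <- function(pred, gt) {
  P <- ncol(gt)
  pv <- pred$val
  lI <- pmin(pv[1, ], gt[1, ]); rI <- pmin(pv[3, ], gt[3, ])
  tI <- pmin(pv[2, ], gt[2, ]); bI <- pmin(pv[4, ], gt[4, ])
  wI <- lI + rI; hI <- tI + bI
  I <- wI * hI
  Ap <- (pv[1, ] + pv[3, ]) * (pv[2, ] + pv[4, ])
  Ag <- (gt[1, ] + gt[3, ]) * (gt[2, ] + gt[4, ])
  U <- pmax(Ap + Ag - I, 1e-9)
  iou <- I / U
  ag_node(mean(1 - iou), list(pred), function(g) {
    gp <- matrix(0, 4, P)
    wsum <- pv[2, ] + pv[4, ]  # heights for dAp/dl, dAp/dr
    hsum <- pv[1, ] + pv[3, ]
    dI <- list(hI * (pv[1, ] < gt[1, ]), wI * (pv[2, ] < gt[2, ]),
               hI * (pv[3, ] < gt[3, ]), wI * (pv[4, ] < gt[4, ]))
    dA <- list(wsum, hsum, wsum, hsum)
    for (k in 1:4) {
      dIoU <- (dI[[k]] * U - I * (dA[[k]] - dI[[k]])) / U^2
      gp[k, ] <- -dIoU * g / P
    }
    ag_accum(pred, gp)
  })
}

# Two-class softmax cross-entropy: logits (H,W,2,N), labels in {0,1} (H,W,N).
ag_softmax_ce2 <- function(x, labels) {
  d <- dim4(x$val)
  z0 <- x$val[, , 1, , drop = FALSE]; z1 <- x$val[, , 2, , drop = FALSE]
  m <- pmax(z0, z1)
  lse <- m + log(exp(z0 - m) + exp(z1 - m))
  lab <- array(labels, dim(z0))
  picked <- ifelse(lab == 1, z1, z0)
  n <- length(picked)
  ag_node(sum(lse - picked) / n, list(x), function(g) {
    p1 <- exp(z1 - lse)
    gx <- array(0, d)
    gx[, , 1, ] <- ((1 - p1) - (1 - lab)) * g / n
    gx[, , 2, ] <- (p1 - lab) * g / n
    ag_accum(x, gx)
  })
}

# Hybrid L2/L1 regression loss with threshold beta (see stage2_loss()).
ag_hybrid_l1l2 <- function(pred, target, beta = 1) {
  e <- pred$val - target
  ae <- abs(e)
  per <- ifelse(ae < beta, e^2 / (2 * beta), ae - beta / 2)
  n <- max(1, length(e))
  ag_node(sum(per) / n, list(pred), function(g) {
    d <- ifelse(ae < beta, e / beta, sign(e))
    ag_accum(pred, g * d / n)
  })
}
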