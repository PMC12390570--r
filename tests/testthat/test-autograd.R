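# Analytic gradients of every differentiable building block are checked
# against central finite differences on small tensors.

expect_grad <- function(loss_fn, params, tol = 1e-4) {
  zero_grads(params)
  loss <- loss_fn()
  ag_backward(loss)
  analytic <- lapply(params, function(p)
    if (is.null(p$grad)) 0 * p$val else p$grad)
  zero_grads(params)
  for (k in seq_along(params)) {
    ng <- numeric_grad(function() loss_fn()$val, params[[k]])
    denom <- max(1e-3, max(abs(ng)))
    expect_lt(max(abs(analytic[[k]] - ng)) / denom, tol)
  }
}

test_that("conv, bn, pooling and resize gradients are exact", {
  set.seed(30)
  x <- ag_param(array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2)))
  cv <- new_conv(3, 3, 3, 4, stride = 1L)
  cv2 <- new_conv(3, 3, 4, 2, stride = 2L)
  bn <- new_bn(4)
  tgt <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  loss_fn <- function() {
    bn$state$running_mean[] <- 0; bn$state$running_var[] <- 1
    # maxpool before resize/relu: conv+bn outputs are tie-free almost surely,
    # keeping the argmax (hence the finite-difference check) stable
    y <- fwd_bn(bn, ag_conv2d(x, cv$w, cv$b, 1L, 1L), TRUE)
    y <- ag_maxpool(y, 3L, 2L, 1L)
    y <- ag_relu(ag_resize(y, 8L, 8L))
    y <- ag_conv2d(y, cv2$w, cv2$b, 2L, 1L)
    d <- ag_add(y, ag_const(-tgt))
    ag_node(sum(d$val^2), list(d), function(g) ag_accum(d, 2 * g * d$val))
  }
  expect_grad(loss_fn, c(list(x), collect_params(cv), collect_params(cv2),
                         collect_params(bn)))
})

test_that("SE gating, gather, softmax and blending gradients are exact", {
  set.seed(31)
  x <- ag_param(array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2)))
  se <- new_se(4L, 2L)
  w <- ag_param(matrix(rnorm(49 * 4, 0, 0.4), 49, 4))
  idx <- rbind(c(2, 3, 1), c(1, 1, 2), c(4, 2, 2))
  loss_fn <- function() {
    f <- forward_se_level(se, x)
    g <- ag_gather_loc(f, idx)            # (4, 3)
    a <- ag_softmax_cols(ag_matmul(w, g)) # (49, 3)
    a4 <- ag_reshape(a, c(7, 7, 1, 3))
    up <- ag_resize(a4, 4L, 4L)
    crops <- ag_node(x$val[, , , c(1, 2, 1), drop = FALSE], list(x), function(gr) {
      gx <- array(0, dim(x$val))
      gx[, , , 1] <- gr[, , , 1] + gr[, , , 3]
      gx[, , , 2] <- gr[, , , 2]
      ag_accum(x, gx)
    })
    b <- ag_mul_bc_ch(crops, up)
    ag_node(sum(b$val^2), list(b), function(gr) ag_accum(b, 2 * gr * b$val))
  }
  expect_grad(loss_fn, c(list(x, w), collect_params(se)))
})

test_that("loss-node gradients (focal, IoU, BCE, CE, hybrid) are exact", {
  set.seed(32)
  z <- ag_param(array(rnorm(5 * 5 * 1 * 2), c(5, 5, 1, 2)))
  tgt <- array(rbinom(50, 1, 0.3), c(5, 5, 1, 2))
  expect_grad(function() ag_focal_logits(z, tgt, gamma = 2, npos = 4),
              list(z))
  expect_grad(function() ag_bce_logits(z, tgt), list(z))
  z2 <- ag_param(array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)))
  labs <- array(rbinom(32, 1, 0.5), c(4, 4, 2))
  expect_grad(function() ag_softmax_ce2(z2, labs), list(z2))
  raw <- ag_param(matrix(rnorm(4 * 6, 0, 0.3), 4, 6))
  gt <- matrix(runif(4 * 6, 2, 20), 4, 6)
  expect_grad(function()
    ag_iou_loss(ag_scalar_mul(ag_exp(raw), 8), gt), list(raw))
  pr <- ag_param(matrix(rnorm(6, 0, 2), 1, 6))
  expect_grad(function()
    ag_hybrid_l1l2(pr, matrix(seq(-2, 3, 1), 1), beta = 1), list(pr))
})

test_that("RoIAlign gradients are exact", {
  set.seed(33)
  f <- ag_param(array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))
  boxes <- rbind(c(4, 4, 40, 36), c(10, 2, 50, 60))
  loss_fn <- function() {
    cr <- ag_roi_align(f, boxes, 3L, 1 / 8)
    ag_node(sum(cr$val^2), list(cr), function(g) ag_accum(cr, 2 * g * cr$val))
  }
  expect_grad(loss_fn, list(f))
})

test_that("fully connected and GAP gradients are exact", {
  set.seed(34)
  x <- ag_param(array(rnorm(3 * 3 * 5 * 2), c(3, 3, 5, 2)))
  fc <- new_fc(5, 3)
  loss_fn <- function() {
    v <- ag_relu(fwd_fc(fc, ag_gap2d(x)))
    ag_node(sum(v$val^2), list(v), function(g) ag_accum(v, 2 * g * v$val))
  }
  expect_grad(loss_fn, c(list(x), collect_params(fc)))
})
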