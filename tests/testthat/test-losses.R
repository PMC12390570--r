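# Closed-form loss suite: hybrid L2/L1 regression loss, focal loss, IoU box
# loss, centerness targets, the combined stage-1 loss.

test_that("hybrid regression loss matches hand-computed values", {
  expect_equal(stage2_loss(10, 10), 0)
  # continuity at |e| = beta: both branches give beta/2
  for (beta in c(0.5, 1, 2)) {
    expect_equal(stage2_loss(0, beta - 1e-9, beta), beta / 2,
                 tolerance = 1e-6)
    expect_equal(stage2_loss(0, beta + 1e-9, beta), beta / 2,
                 tolerance = 1e-6)
  }
  expect_equal(stage2_loss(c(10, 20), c(10.5, 23), beta = 1),
               (0.125 + 2.5) / 2)
  expect_warning(z <- stage2_loss(numeric(0), numeric(0)), "empty batch")
  expect_identical(z, 0)
})

test_that("hybrid loss is nonnegative, continuous, and piecewise L2/L1", {
  for (beta in c(0.3, 1, 2.5)) {
    for (e in seq(-4, 4, by = 0.23)) {
      v <- stage2_loss(0, e, beta)
      expect_gte(v, 0)
      if (abs(e) < beta) expect_equal(v, e^2 / (2 * beta))
      else expect_equal(v, abs(e) - beta / 2)
    }
  }
})

test_that("focal loss matches its formula and collapses to CE at gamma 0", {
  expect_equal(focal_loss(rep(1 - 1e-15, 5), rep(1, 5)), 0, tolerance = 1e-9)
  expect_equal(focal_loss(0.5, 1, gamma = 2), 0.25 * log(2))
  set.seed(20)
  p <- runif(50, 0.05, 0.95); y <- rbinom(50, 1, 0.5)
  ce <- sum(-log(ifelse(y == 1, p, 1 - p))) / sum(y == 1)
  expect_equal(focal_loss(p, y, gamma = 0), ce, tolerance = 1e-6)
  expect_warning(z <- focal_loss(0.5, 0), "no positive")
  expect_identical(z, 0)
})

test_that("IoU box loss covers the perfect, disjoint and half-overlap cases", {
  a <- matrix(c(0, 0, 1, 1), 1)
  expect_equal(iou_box_loss(a, a), 0)
  expect_equal(iou_box_loss(a, matrix(c(5, 5, 6, 6), 1)), 1)
  expect_equal(iou_box_loss(matrix(c(0.5, 0, 1.5, 1), 1), a), 2 / 3)
  expect_warning(v <- iou_box_loss(rbind(a, a),
                                   rbind(a, c(0, 0, 0, 1))),
                 "degenerate")
  expect_equal(v, 0)
})

test_that("centerness targets follow the min/max edge-distance formula", {
  box <- c(0, 0, 10, 20)
  expect_equal(centerness_target(c(5, 10), box), 1)
  expect_equal(centerness_target(c(0, 10), box), 0)   # on an edge
  expect_equal(centerness_target(c(-1, 10), box), 0)  # outside
  # (l, t, r, b) = (1, 2, 3, 4)
  expect_equal(centerness_target(c(1, 2), c(0, 0, 4, 6)),
               sqrt((1 / 3) * (2 / 4)), tolerance = 1e-6)
})

test_that("stage-1 loss is the weighted sum of its components", {
  expect_equal(stage1_loss(c(a = 0, b = 0), c(c = 0)), 0)
  set.seed(21)
  px <- runif(2); inst <- runif(3)
  l1 <- runif(1, 0.5, 2); l2 <- runif(1, 0.5, 2)
  expect_equal(stage1_loss(px, inst, l1, l2), l1 * sum(px) + l2 * sum(inst))
  expect_equal(stage1_loss(px, inst), sum(px) + sum(inst))  # defaults 1.0
  expect_error(stage1_loss(c(ok = 1, bad = NaN), inst), "bad")
})

test_that("dense target assignment produces in-range positives", {
  gt <- rbind(c(10, 10, 60, 50), c(100, 100, 140, 150))
  asn <- assign_dense_targets(gt, list(c(24, 24)), 8L)
  lv <- asn[[1]]
  expect_gt(length(lv$positives), 0)
  for (p in lv$positives) {
    expect_true(all(p$ltrb > 0))
    expect_gte(p$centerness, 0)
    expect_lte(p$centerness, 1)
    expect_equal(lv$labels[p$i, p$j], 1)
  }
})
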