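# Length predictor: RoIAlign, attention blending, mask pasting, the
# 64-slot regressor.

test_that("RoIAlign preserves constants and the configured resolution", {
  feat <- array(3.7, c(16, 16, 5))
  crop <- roi_align(feat, c(8, 8, 72, 96), R = 14L, stride = 8)
  expect_equal(dim(crop), c(14, 14, 5, 1))
  expect_equal(max(abs(crop - 3.7)), 0)
  expect_error(roi_align(feat, c(10, 10, 10, 40)), "degenerate box")
  expect_error(roi_align(feat, c(0, 0, 32, 32), R = 1L), "R must be")
})

test_that("RoIAlign matches direct bilinear interpolation on a hand case", {
  feat <- array(0, c(4, 4, 1))
  feat[, , 1] <- matrix(1:16, 4, 4)          # f(y, x) = (y+1) + 4*x (0-based)
  box <- c(8, 8, 24, 24)                     # feature coords 1..3 at stride 8
  crop <- roi_align(feat, box, R = 2L, stride = 8)
  # oracle: average of 2x2 bilinear samples per bin
  bilin <- function(py, px) {
    x0 <- floor(px); y0 <- floor(py)
    x1 <- min(x0 + 1, 3); y1 <- min(y0 + 1, 3)
    ax <- px - x0; ay <- py - y0
    f <- function(y, x) feat[y + 1, x + 1, 1]
    f(y0, x0) * (1 - ay) * (1 - ax) + f(y1, x0) * ay * (1 - ax) +
      f(y0, x1) * (1 - ay) * ax + f(y1, x1) * ay * ax
  }
  for (oy in 0:1) for (ox in 0:1) {
    acc <- 0
    for (sy in 0:1) for (sx in 0:1)
      acc <- acc + bilin(1 + (oy + (sy + 0.5) / 2),
                         1 + (ox + (sx + 0.5) / 2))
    expect_equal(crop[oy + 1, ox + 1, 1, 1], acc / 4, tolerance = 1e-12)
  }
})

test_that("blending is exactly multiplicative", {
  set.seed(15)
  fi <- array(rnorm(14 * 14 * 6), c(14, 14, 6))
  ones <- matrix(1, 7, 7)
  expect_equal(blend(fi, ones)[, , , 1], fi, tolerance = 1e-12)
  expect_equal(max(abs(blend(fi, matrix(0, 7, 7)))), 0)
  A <- matrix(runif(49), 7, 7)
  out <- blend(fi, A)
  up <- matrix(cpp_resize_bilinear_fw(array(A, c(7, 7, 1, 1)), 14L, 14L), 14, 14)
  for (ch in 1:6) for (i in 1:14) for (j in 1:14)
    expect_equal(out[i, j, ch, 1], fi[i, j, ch] * up[i, j], tolerance = 1e-12)
})

test_that("instance masks fill their box for saturated logits and stay inside it", {
  m <- glen_model("tiny", seed = 16)
  m$mask_head$w$val[] <- 0
  m$mask_head$b$val[] <- 50           # uniformly large positive logits
  blended <- array(rnorm(14 * 14 * 64), c(14, 14, 64))
  box <- c(10, 20, 40, 52)
  mask <- predict_instance_mask(m, blended, box, c(96, 96))
  inside <- matrix(FALSE, 96, 96); inside[21:52, 11:40] <- TRUE
  expect_true(all(mask[inside]))
  expect_false(any(mask[!inside]))
  m$mask_head$b$val[] <- -50
  expect_false(any(predict_instance_mask(m, blended, box, c(96, 96))))
})

test_that("the length vector has 64 slots with zeros beyond the live count", {
  m <- glen_model("tiny", seed = 17)
  blended <- array(rnorm(14 * 14 * 64 * 3), c(14, 14, 64, 3))
  out <- regress_lengths(m, blended)
  expect_length(out$lengths, 64)
  expect_identical(out$live, 3L)
  expect_true(all(out$lengths[4:64] == 0))
  expect_warning(z <- regress_lengths(m, NULL), "no instances")
  expect_identical(z$lengths, numeric(64))
})

test_that("zeroed weights with a final bias b predict b in every live slot", {
  m <- glen_model("tiny", seed = 18)
  for (p in collect_params(m$len_head)) p$val[] <- 0
  m$len_head$fc2$b$val[] <- 42.5
  blended <- array(rnorm(14 * 14 * 64 * 2), c(14, 14, 64, 2))
  out <- regress_lengths(m, blended)
  expect_equal(out$lengths[1:2], c(42.5, 42.5))
})

test_that("length predictions follow instances, not slot order", {
  m <- glen_model("tiny", seed = 19)
  set.seed(19)
  blended <- array(rnorm(14 * 14 * 64 * 4), c(14, 14, 64, 4))
  out <- regress_lengths(m, blended)$lengths[1:4]
  perm <- c(3, 1, 4, 2)
  out_p <- regress_lengths(m, blended[, , , perm])$lengths[1:4]
  expect_equal(out_p, out[perm], tolerance = 1e-10)
})
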