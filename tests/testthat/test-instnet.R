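# Instance-level path: five-tuple box decoding, top-d + NMS selection,
# attention maps.

test_that("grid locations and box decoding follow the five-tuple convention", {
  loc <- head_locations(4, 4, 8)
  # cell (i=0, j=0) -> image point (4, 4); (i=2, j=1) -> (12, 20)
  expect_equal(loc[1, ], c(x = 4, y = 4))
  expect_equal(loc[3 + 4 * 1, ], c(x = 12, y = 20))
  dense <- list(score = matrix(0.9, 1, 1), centerness = matrix(1, 1, 1),
                ltrb = array(c(10, 10, 10, 10), c(1, 1, 4)),
                att = array(0, c(1, 1, 49)), stride = 200)
  bx <- decode_boxes_level(dense)
  expect_equal(as.numeric(bx), c(90, 90, 110, 110))
})

test_that("head outputs are nonnegative distances and probabilities", {
  m <- glen_model("tiny", seed = 11)
  Fl <- array(rnorm(24 * 24 * 64), c(24, 24, 64))
  dh <- dense_head_forward(m, Fl, 8)
  expect_true(all(dh$ltrb > 0))                   # exp parameterization
  expect_true(all(dh$score > 0 & dh$score < 1))
  expect_true(all(dh$centerness > 0 & dh$centerness < 1))
  expect_equal(dim(dh$att)[3], 49)
})

test_that("NMS keeps the expected winners", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(nms(b, c(0.9, 0.8), 0.3), 1L)
  expect_equal(nms(b[1, , drop = FALSE], 0.5, 0.3), 1L)
  # tie broken by lower index
  expect_equal(nms(b, c(0.7, 0.7), 0.3), 1L)
})

test_that("NMS equals the O(n^2) greedy oracle on random cases", {
  set.seed(12)
  for (rep in 1:100) {
    n <- 20
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    b <- cbind(x1, y1, x1 + runif(n, 5, 40), y1 + runif(n, 5, 40))
    s <- round(runif(n), 3)   # rounding invites ties
    thr <- runif(1, 0.2, 0.6)
    expect_identical(nms(b, s, thr), oracle_nms(b, s, thr))
  }
})

test_that("select_instances pools top-d, suppresses, and attaches attention", {
  m <- glen_model("tiny", seed = 13)
  set.seed(13)
  dense <- lapply(seq_along(m$strides), function(li) {
    hw <- max(2L, 32L %/% 2^(li - 1L))
    list(score = matrix(runif(hw * hw, 0, 0.5), hw, hw),
         centerness = matrix(runif(hw * hw), hw, hw),
         ltrb = array(runif(hw * hw * 4, 4, 30), c(hw, hw, 4L)),
         att = array(rnorm(hw * hw * 49), c(hw, hw, 49L)),
         stride = m$strides[li])
  })
  det <- select_instances(dense, M = 7L, d = 10L, nms_thr = 0.3)
  expect_s3_class(det, "detection_set")
  expect_lte(nrow(det$boxes), 50)
  expect_length(det$attention, nrow(det$boxes))
  for (A in det$attention) {
    expect_equal(dim(A), c(7, 7))
    expect_equal(sum(A), 1)
  }
  if (nrow(det$boxes) > 1) {
    iou <- box_iou(as.matrix(det$boxes[, 1:4]), as.matrix(det$boxes[, 1:4]))
    expect_true(all(iou[upper.tri(iou)] <= 0.3 + 1e-9))
  }
  # empty candidate set is not an error
  none <- lapply(dense, function(d) { d$score[] <- 0; d })
  expect_identical(nrow(select_instances(none)$boxes), 0L)
})

test_that("training mode reads one attention map per ground-truth box", {
  m <- glen_model("tiny", seed = 14)
  set.seed(14)
  dense <- lapply(seq_along(m$strides), function(li) {
    hw <- max(2L, 24L %/% 2^(li - 1L))
    list(score = matrix(0, hw, hw),
         att = array(rnorm(hw * hw * 49), c(hw, hw, 49L)),
         stride = m$strides[li])
  })
  gt <- rbind(c(10, 10, 60, 40), c(80, 80, 150, 170), c(5, 100, 180, 180))
  maps <- attention_for_instances(dense, gt, mode = "training", M = 7L)
  expect_length(maps, 3)
  for (A in maps) expect_equal(sum(A), 1)
  # maps at different assigned locations differ
  expect_false(identical(maps[[1]], maps[[2]]))
})
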