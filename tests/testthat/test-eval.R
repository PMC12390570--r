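# Evaluation: AP, matching, regression metrics, grouped reports, rank
# correlations.

mk_det <- function(box, score, mask = NULL) list(box = box, score = score, mask = mask)
mk_gt <- function(box, mask = NULL, length_mm = NA, n_dev = NA)
  list(box = box, mask = mask, length_mm = length_mm, n_dev = n_dev)

test_that("AP is 1 for a perfect detection and 0 for none", {
  gt <- list(list(mk_gt(c(0, 0, 10, 10))))
  perfect <- list(list(mk_det(c(0, 0, 10, 10), 0.9)))
  expect_equal(coco_ap(perfect, gt)$AP50, 1)
  expect_equal(coco_ap(list(list()), gt)$AP50, 0)
  # no ground truth -> undefined
  expect_true(is.na(coco_ap(perfect, list(list()))$AP50))
})

test_that("AP matches the exhaustive precision-recall oracle", {
  # hand case: 5 detections, 3 GT
  gt_boxes <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30), c(50, 50, 70, 70))
  det_boxes <- rbind(c(0, 0, 10, 10),      # perfect hit
                     c(1, 1, 11, 11),      # duplicate of GT 1
                     c(21, 21, 31, 31),    # good hit on GT 2
                     c(80, 80, 90, 90),    # false positive
                     c(50, 50, 69, 70))    # good hit on GT 3
  scores <- c(0.9, 0.85, 0.7, 0.6, 0.5)
  det <- list(lapply(1:5, function(i) mk_det(det_boxes[i, ], scores[i])))
  gt <- list(lapply(1:3, function(i) mk_gt(gt_boxes[i, ])))
  got <- coco_ap(det, gt)
  ious <- box_iou(det_boxes, gt_boxes)
  expect_equal(got$AP50, oracle_ap(scores, ious, 3, 0.5))
  expect_equal(got$AP75, oracle_ap(scores, ious, 3, 0.75))
  # randomized exhaustive comparison over many small cases
  set.seed(40)
  for (rep in 1:25) {
    ng <- sample(1:3, 1); nd <- sample(1:6, 1)
    gb <- cbind(runif(ng, 0, 50), runif(ng, 0, 50))
    gb <- cbind(gb, gb[, 1] + runif(ng, 8, 30), gb[, 2] + runif(ng, 8, 30))
    db <- gb[sample(ng, nd, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(nd * 4, 0, 4), nd)
    db[, 3] <- pmax(db[, 3], db[, 1] + 1); db[, 4] <- pmax(db[, 4], db[, 2] + 1)
    sc <- round(runif(nd), 2)
    got <- coco_ap(list(lapply(seq_len(nd), function(i) mk_det(db[i, ], sc[i]))),
                   list(lapply(seq_len(ng), function(i) mk_gt(gb[i, ]))))
    ious <- box_iou(db, gb)
    for (thr in c(0.5, 0.75))
      expect_equal(got[[if (thr == 0.5) "AP50" else "AP75"]],
                   oracle_ap(sc, ious, ng, thr))
  }
})

test_that("greedy matching pairs by score and respects the IoU threshold", {
  m1 <- matrix(FALSE, 20, 20); m1[2:10, 2:10] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[12:19, 12:19] <- TRUE
  identical_match <- match_instances(
    list(mk_det(c(1, 1, 10, 10), 0.9, m1)),
    list(mk_gt(c(1, 1, 10, 10), m1, 30, 1)))
  expect_equal(identical_match$pairs$iou, 1)
  # IoU 0.3 pair at threshold 0.5 stays unmatched
  m3 <- matrix(FALSE, 20, 20); m3[2:10, 2:6] <- TRUE   # ~0.55 overlap? no: subset
  m4 <- matrix(FALSE, 20, 20); m4[2:10, 5:14] <- TRUE
  iou <- sum(m3 & m4) / sum(m3 | m4)
  expect_lt(iou, 0.5)
  res <- match_instances(list(mk_det(c(1, 4, 10, 14), 0.8, m4)),
                         list(mk_gt(c(1, 1, 6, 10), m3, 20, 0)))
  expect_equal(nrow(res$pairs), 0)
  expect_equal(res$unmatched_gt, 1L)
  expect_equal(res$unmatched_pred, 1L)
})

test_that("greedy matching agrees with an exhaustive oracle on random cases", {
  set.seed(41)
  for (rep in 1:20) {
    gb <- cbind(runif(4, 0, 40), runif(4, 0, 40))
    gb <- cbind(gb, gb[, 1] + runif(4, 10, 25), gb[, 2] + runif(4, 10, 25))
    db <- gb + matrix(rnorm(16, 0, 3), 4)
    db[, 3] <- pmax(db[, 3], db[, 1] + 1); db[, 4] <- pmax(db[, 4], db[, 2] + 1)
    sc <- runif(4)
    preds <- lapply(1:4, function(i) mk_det(db[i, ], sc[i]))
    gts <- lapply(1:4, function(i) mk_gt(gb[i, ], length_mm = i, n_dev = 0))
    got <- match_instances(preds, gts, 0.5, on = "box")
    # oracle: same greedy definition, written independently
    ious <- box_iou(db, gb)
    used <- rep(FALSE, 4); exp_pairs <- list()
    for (q in order(-sc, 1:4)) {
      cand <- which(!used & ious[q, ] >= 0.5 &
                      ious[q, ] == max(ious[q, !used], -1))
      cand <- cand[ious[q, cand] >= 0.5]
      if (length(cand)) {
        g <- cand[1]; used[g] <- TRUE
        exp_pairs[[length(exp_pairs) + 1L]] <- c(q, g)
      }
    }
    expect_equal(nrow(got$pairs), length(exp_pairs))
    if (length(exp_pairs))
      expect_equal(unname(as.matrix(got$pairs[, c("pred", "gt")])),
                   do.call(rbind, exp_pairs))
  }
})

test_that("regression metrics match direct formulas", {
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect), c(MAE = 0, RMSE = 0, Pearson = 1, R2 = 1))
  off <- regression_metrics(c(10, 20, 30), c(12, 22, 32))
  expect_equal(off$MAE, 2); expect_equal(off$RMSE, 2)
  expect_equal(off$Pearson, 1)
  hand <- regression_metrics(c(10, 20, 30, 40), c(12, 18, 33, 37))
  e <- c(-2, 2, -3, 3)
  expect_equal(hand$MAE, mean(abs(e)))
  expect_equal(hand$RMSE, sqrt(mean(e^2)))
  expect_equal(hand$Pearson,
               cov(c(10, 20, 30, 40), c(12, 18, 33, 37)) /
                 (sd(c(10, 20, 30, 40)) * sd(c(12, 18, 33, 37))))
  expect_equal(hand$R2, 1 - sum(e^2) / sum((c(10, 20, 30, 40) - 25)^2))
  expect_true(is.na(regression_metrics(c(5, 5, 5), c(1, 2, 3))$Pearson))
})

test_that("RMSE never falls below MAE and R2 never exceeds 1", {
  set.seed(42)
  for (rep in 1:20) {
    y <- runif(15, 5, 50); p <- y + rnorm(15, 0, 4)
    m <- regression_metrics(y, p)
    expect_gte(m$RMSE, m$MAE)
    expect_lte(m$R2, 1)
  }
})

test_that("grouped reports partition the matched pairs", {
  set.seed(43)
  pairs <- data.frame(length_gt = runif(60, 11, 70),
                      length_pred = runif(60, 11, 70),
                      n_dev = sample(0:4, 60, replace = TRUE))
  rep1 <- grouped_report(pairs)
  dev_rows <- rep1[rep1$grouping == "n_dev", ]
  expect_equal(sum(dev_rows$n), 60)
  len_rows <- rep1[rep1$grouping == "length_mm", ]
  expect_equal(sum(len_rows$n), 60)
  # all pairs in one group reproduce the overall metrics
  one <- pairs; one$n_dev <- 1
  m_all <- regression_metrics(one$length_gt, one$length_pred)
  r_one <- grouped_report(one)
  expect_equal(r_one$MAE[r_one$grouping == "n_dev"], m_all$MAE)
})

test_that("rank correlations are tie-aware and match textbook formulas", {
  expect_equal(rank_correlation(1:10, 1:10, n_perm = 9)$rho, 1)
  expect_equal(rank_correlation(1:10, 10:1, n_perm = 9)$tau, -1)
  # 6-point tied example, tau-b and tie-corrected Spearman by hand
  x <- c(1, 2, 2, 3, 4, 4); y <- c(1, 1, 2, 3, 3, 4)
  got <- rank_correlation(x, y, n_perm = 199)
  C <- 0; D <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- 15
  t1 <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  t2 <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  expect_equal(got$tau, (C - D) / sqrt((n0 - t1) * (n0 - t2)))
  rx <- rank(x); ry <- rank(y)
  expect_equal(got$rho,
               sum((rx - mean(rx)) * (ry - mean(ry))) /
                 sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2)))
  expect_lt(got$p_rho, 0.05)
  expect_true(is.na(rank_correlation(1:5, rep(2, 5), n_perm = 9)$rho))
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
})
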