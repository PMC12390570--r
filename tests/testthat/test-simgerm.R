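# Generator: length law, curvature categories, centerline geometry.

test_that("configuration invariants are enforced", {
  expect_error(germ_config(category_weights = c(0.5, 0.5, 0.1, 0.1)),
               "summing to 1")
  expect_error(germ_config(px_per_mm = -1), "px_per_mm")
  expect_error(germ_config(length_law = list(meanlog = 1, sdlog = 1,
                                             min_mm = 50, max_mm = 10)),
               "ordered")
  expect_silent(validate_germ_config(germ_config()))
})

test_that("degenerate length law collapses to a point mass", {
  cfg <- germ_config(length_law = list(meanlog = log(25), sdlog = 0,
                                       min_mm = 10, max_mm = 80))
  set.seed(1)
  sp <- sample_radicle_spec(cfg, 200)
  expect_equal(sp$length_mm, rep(25, 200))
})

test_that("sampled lengths and categories reproduce the target statistics", {
  set.seed(42)
  sp <- sample_radicle_spec(germ_config(), 10000)
  # binomial noise at n = 10,000 is ~0.5 percentage points
  expect_lt(abs(mean(sp$n_dev == 1) - 0.545), 0.015)
  expect_lt(abs(mean(sp$n_dev > 2) - 0.078), 0.010)
  expect_lt(mean(sp$n_dev == 0), 0.09 + 0.015)
  expect_lt(abs(stats::median(sp$length_mm) - 28), 0.5)
  expect_lt(abs(mean(sp$length_mm) - 30), 0.5)
  expect_true(all(sp$length_mm >= 10 & sp$length_mm <= 80))
})

test_that("category marginals converge to the configured weights", {
  w <- c(0.2, 0.3, 0.4, 0.1)
  set.seed(7)
  sp <- sample_radicle_spec(germ_config(category_weights = w), 10000)
  cat4 <- pmin(sp$n_dev, 3L)
  obs <- tabulate(cat4 + 1L, 4L) / nrow(sp)
  # three-sigma binomial bands
  for (k in 1:4)
    expect_lt(abs(obs[k] - w[k]), 3 * sqrt(w[k] * (1 - w[k]) / 10000) + 1e-9)
})

test_that("length and deviation count are strongly rank-coupled", {
  set.seed(3)
  sp <- sample_radicle_spec(germ_config(), 1000)
  expect_gte(cor(sp$length_mm, sp$n_dev, method = "spearman"), 0.7)
})

test_that("centerlines realize the requested arc length and lift maxima", {
  cfg <- germ_config()
  set.seed(5)
  for (nd in 0:3) {
    sp <- sample_radicle_spec(cfg, 1)
    sp$n_dev <- nd
    sp$length_mm <- max(sp$length_mm, 12 + 8 * nd)
    cl <- build_centerline(sp, cfg)
    al <- arc_length(cl)
    expect_lt(abs(al - sp$length_mm) / sp$length_mm, 0.005)
    expect_identical(count_deviation_points(cl), nd)
    if (nd == 0L) {
      expect_true(all(cl$z == 0))
      expect_lt(abs(projected_length(cl) - al), 0.02)
    } else {
      expect_lt(projected_length(cl), al)
    }
  }
})

test_that("out-of-bounds specs are rejected", {
  cfg <- germ_config()
  sp <- sample_radicle_spec(cfg, 1)
  sp$length_mm <- 200
  expect_error(build_centerline(sp, cfg), "truncation bounds")
  sp2 <- sample_radicle_spec(cfg, 1)
  sp2$anchor_x <- 44; sp2$anchor_y <- 0; sp2$heading <- 0  # pointing out
  sp2$length_mm <- 60
  expect_error(build_centerline(sp2, cfg, max_retry = 3L),
               "unreachable geometry")
})

test_that("arc length agrees with a dense-polyline oracle", {
  set.seed(9)
  for (rep in 1:3) {
    tg <- seq(0, 1, length.out = 9)
    cl <- structure(list(
      t = tg, x = cumsum(runif(9, 0, 5)), y = cumsum(rnorm(9, 0, 2)),
      z = pmax(0, rnorm(9, 1, 0.5)), z_threshold = 1), class = "centerline3d")
    cl$sx <- splinefun(tg, cl$x, method = "natural")
    cl$sy <- splinefun(tg, cl$y, method = "natural")
    cl$sz <- splinefun(tg, cl$z, method = "natural")
    td <- seq(0, 1, length.out = 1e5)
    poly <- cbind(cl$sx(td), cl$sy(td), cl$sz(td))
    oracle <- sum(sqrt(rowSums(diff(poly)^2)))
    expect_lt(abs(arc_length(cl) - oracle) / oracle, 0.001)
  }
})

test_that("straight and circular reference curves have known lengths", {
  tg <- seq(0, 1, length.out = 101)
  straight <- structure(list(t = tg, x = 30 * tg, y = 0 * tg, z = 0 * tg,
                             sx = splinefun(tg, 30 * tg),
                             sy = splinefun(tg, 0 * tg),
                             sz = splinefun(tg, 0 * tg), z_threshold = 1),
                        class = "centerline3d")
  expect_equal(arc_length(straight), 30, tolerance = 1e-6)
  semi <- structure(list(t = tg, x = 10 * cos(pi * tg), y = 10 * sin(pi * tg),
                         z = 0 * tg,
                         sx = splinefun(tg, 10 * cos(pi * tg)),
                         sy = splinefun(tg, 10 * sin(pi * tg)),
                         sz = splinefun(tg, 0 * tg), z_threshold = 1),
                    class = "centerline3d")
  expect_equal(arc_length(semi), pi * 10, tolerance = 1e-4)
  bad <- straight; bad$x[5] <- NaN
  expect_error(arc_length(bad), "non-finite")
})

test_that("deviation points are strict above-threshold lift maxima", {
  tg <- seq(0, 1, length.out = 401)
  mk <- function(z) {
    structure(list(t = tg, x = 50 * tg, y = 0 * tg, z = z,
                   sx = splinefun(tg, 50 * tg), sy = splinefun(tg, 0 * tg),
                   sz = splinefun(tg, z), z_threshold = 1),
              class = "centerline3d")
  }
  expect_identical(count_deviation_points(mk(rep(0, 401))), 0L)
  bump <- 3 * exp(-((tg - 0.5) / 0.08)^2)
  expect_identical(count_deviation_points(mk(bump)), 1L)
  tri <- pmax(0, 2.5 * sin(3 * 2 * pi * tg))
  expect_identical(count_deviation_points(mk(tri)), 3L)
  low <- 0.5 * exp(-((tg - 0.5) / 0.08)^2)  # below visibility threshold
  expect_identical(count_deviation_points(mk(low)), 0L)
})
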