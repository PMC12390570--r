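# Pixel-level path: backbone strides, pyramid construction, SE
# recalibration, basis decoder.

test_that("backbone strides follow the 8/16/32 ladder", {
  m <- glen_model("tiny", seed = 1)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  C <- backbone_forward(m, img)
  expect_equal(dim(C$C3)[1:2], c(32, 32))
  expect_equal(dim(C$C4)[1:2], c(16, 16))
  expect_equal(dim(C$C5)[1:2], c(8, 8))
  expect_equal(sapply(C, function(x) dim(x)[3]), c(C3 = 64, C4 = 128, C5 = 256))
  expect_error(backbone_forward(m, array(0, c(16, 16, 3))), "stride-32")
})

test_that("a zero image yields zero feature maps", {
  m <- glen_model("tiny", seed = 2)   # conv biases are zero-initialized
  C <- backbone_forward(m, array(0, c(64, 64, 3)))
  for (x in C) expect_equal(max(abs(x)), 0)
})

test_that("the full-scale profile carries a five-level 256-channel pyramid", {
  m <- glen_model("resnet50", seed = 3)
  C <- backbone_forward(m, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(sapply(C, function(x) dim(x)[3]),
               c(C3 = 512, C4 = 1024, C5 = 2048))
  P <- build_pyramid(m, C)
  expect_length(P, 5)
  expect_true(all(sapply(P, function(x) dim(x)[3]) == 256))
  sizes <- sapply(P, function(x) dim(x)[1])
  expect_equal(unname(sizes), c(8, 4, 2, 1, 1))
})

test_that("levels halve in spatial size and P4 equals up(P5) with zeroed laterals", {
  m <- glen_model("tiny", seed = 4)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  C <- backbone_forward(m, img)
  P <- build_pyramid(m, C)
  expect_equal(unname(sapply(P, function(x) dim(x)[1])), c(32, 16, 8, 4, 2))
  m$fpn$lat4$w$val[] <- 0; m$fpn$lat4$b$val[] <- 0
  m$fpn$lat3$w$val[] <- 0; m$fpn$lat3$b$val[] <- 0
  P0 <- build_pyramid(m, C)
  up5 <- array(cpp_resize_bilinear_fw(array(P0$P5, c(dim(P0$P5), 1L)), 16L, 16L),
               c(16, 16, dim(P0$P5)[3]))
  expect_equal(P0$P4, up5, tolerance = 1e-12)
})

test_that("SE recalibration matches a scalar-loop oracle and is pure scaling", {
  set.seed(5)
  c_ch <- 4L
  P <- array(rnorm(3 * 3 * c_ch), c(3, 3, c_ch))
  se <- list(W1 = matrix(rnorm(1 * c_ch, 0, 0.5), 1, c_ch),
             W2 = matrix(rnorm(c_ch * 1, 0, 0.5), c_ch, 1))
  Fo <- se_recalibrate(P, se)
  # independent scalar-loop evaluation
  z <- numeric(c_ch)
  for (ch in 1:c_ch) for (i in 1:3) for (j in 1:3)
    z[ch] <- z[ch] + P[i, j, ch] / 9
  hidden <- max(sum(se$W1[1, ] * z), 0)
  s <- 1 / (1 + exp(-(se$W2[, 1] * hidden)))
  for (ch in 1:c_ch) for (i in 1:3) for (j in 1:3)
    expect_equal(Fo[i, j, ch], s[ch] * P[i, j, ch], tolerance = 1e-12)
  expect_equal(attr(Fo, "z"), z)
  expect_true(all(attr(Fo, "s") > 0 & attr(Fo, "s") < 1))
})

test_that("SE degenerate weights behave per the gating formula", {
  P <- array(7, c(5, 5, 8))          # constant map
  se <- list(W1 = matrix(0.1, 2, 8), W2 = matrix(0, 8, 2))
  Fo <- se_recalibrate(P, se)
  expect_equal(attr(Fo, "z"), rep(7, 8))      # squeeze of a constant map
  expect_equal(attr(Fo, "s"), rep(0.5, 8))    # sigmoid(0) with W2 = 0
  expect_equal(Fo[1, 1, 1], 3.5)
  expect_error(new_se(10L, 16L), "divide")
})

test_that("the decoder emits a k-channel stride-4 basis tensor", {
  m <- glen_model("tiny", seed = 6)
  img <- array(runif(256 * 256 * 3), c(256, 256, 3))
  C <- backbone_forward(m, img)
  P <- build_pyramid(m, C)
  Fm <- lapply(1:3, function(i) se_recalibrate(P[[i]], m$se[[i]]))
  B <- decode_bases(m, list(F3 = Fm[[1]], F4 = Fm[[2]], F5 = Fm[[3]]))
  expect_equal(dim(B), c(64, 64, 4))
  # zero inputs, bias-free -> zero basis
  zero <- lapply(Fm, function(x) array(0, dim(x)))
  B0 <- decode_bases(m, list(F3 = zero[[1]], F4 = zero[[2]], F5 = zero[[3]]))
  expect_equal(max(abs(B0)), 0)
  m1 <- glen_model("tiny", k = 1L, seed = 6)
  B1 <- decode_bases(m1, list(F3 = Fm[[1]], F4 = Fm[[2]], F5 = Fm[[3]]))
  expect_equal(dim(B1)[3], 1L)
  expect_error(glen_model("tiny", n = 0L), "n and k")
})

test_that("eval-mode forward passes are deterministic", {
  m <- glen_model("tiny", seed = 7)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  a <- forward_glen(m, img, training = FALSE)
  b <- forward_glen(m, img, training = FALSE)
  expect_identical(a$B$val, b$B$val)
  expect_identical(a$heads[[1]]$cls$val, b$heads[[1]]$cls$val)
})
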