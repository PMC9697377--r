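test_that("bilinear sampling matches the tent-kernel definition", {
  g <- array(c(0, 2, 1, 3), c(2, 2, 1))  # rows y, cols x: x(0,0)=0 x(1,1)=3
  expect_equal(bilinear_sample(g, c(0.5, 0.5)), 1.5)
  # integer grid points return stored pixels exactly
  expect_equal(bilinear_sample(g, c(0, 0)), 0)
  expect_equal(bilinear_sample(g, c(1, 1)), 3)
  expect_equal(bilinear_sample(g, c(1, 0)), 1)
  # more than one pixel outside the grid on both axes -> 0
  expect_equal(bilinear_sample(g, c(-1.5, -2)), 0)
  expect_equal(bilinear_sample(g, c(3.1, 4)), 0)
  expect_error(bilinear_sample(g, c(NaN, 0)), "finite")

  set.seed(5)
  x <- array(rnorm(7 * 9 * 2), c(7, 9, 2))
  # 10,000 random fractional locations vs the literal full-grid sum,
  # plus exactness at integer locations
  n <- 10000
  lx <- runif(n, -2, 10)
  ly <- runif(n, -2, 8)
  ch <- sample(1:2, n, replace = TRUE)
  got <- bilinear_sample(x, cbind(lx, ly), channel = ch)
  idx <- sample(n, 300)  # full-grid oracle is O(HW) per point; spot-check
  want <- vapply(idx, function(i) oracle_bilinear(x, lx[i], ly[i], ch[i]), 0)
  expect_equal(got[idx], want, tolerance = 1e-12)
  ints_x <- sample(0:8, 500, replace = TRUE)
  ints_y <- sample(0:6, 500, replace = TRUE)
  chans <- sample(1:2, 500, replace = TRUE)
  got_i <- bilinear_sample(x, cbind(ints_x, ints_y), channel = chans)
  expect_identical(got_i, x[cbind(ints_y + 1, ints_x + 1, chans)])
  # in-grid weights sum to 1: sampling a constant map gives the constant
  ones <- array(1, c(7, 9, 1))
  inx <- runif(200, 0, 8)
  iny <- runif(200, 0, 6)
  expect_equal(bilinear_sample(ones, cbind(inx, iny)), rep(1, 200))
  # linearity in the input map
  x2 <- array(rnorm(7 * 9 * 2), c(7, 9, 2))
  a <- 1.7; b <- -0.3
  expect_equal(bilinear_sample(a * x + b * x2, cbind(lx, ly), ch),
               a * bilinear_sample(x, cbind(lx, ly), ch) +
                 b * bilinear_sample(x2, cbind(lx, ly), ch),
               tolerance = 1e-10)
})

test_that("offset prediction is an ordinary same-size 3x3 convolution", {
  set.seed(9)
  x <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  oc <- list(w = array(rnorm(3 * 3 * 3 * 18, 0, 0.2), c(3, 3, 3, 18)),
             b = rnorm(18))
  off <- predict_offsets(x, oc)
  expect_equal(dim(off)[1:2], dim(x)[1:2])
  expect_equal(dim(off)[3], 18)
  expect_equal(off, oracle_conv2d(x, oc$w, oc$b, pad = 1), tolerance = 1e-12)
  # zero weights and bias -> all-zero offset field
  zc <- list(w = array(0, c(3, 3, 3, 18)), b = numeric(18))
  expect_true(all(predict_offsets(x, zc) == 0))
  expect_error(predict_offsets(x, list(w = array(0, c(3, 3, 2, 18)),
                                       b = NULL)), "channels")
})

test_that("deformable convolution reduces to standard convolution at zero offset", {
  set.seed(13)
  # 200 random draws on 16x16x8 inputs
  worst <- 0
  for (i in 1:200) {
    x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
    w <- array(rnorm(3 * 3 * 8 * 2, 0, 0.3), c(3, 3, 8, 2))
    b <- rnorm(2)
    off <- array(0, c(16, 16, 18))
    got <- deformable_conv2d(x, w, off, bias = b)
    want <- oracle_conv2d(x, w, b, pad = 1)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-5)
})

test_that("deformable convolution handles degenerate weights and shifts", {
  set.seed(17)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  off0 <- array(0, c(8, 8, 18))
  # all-zero weights -> all-zero output
  w0 <- array(0, c(3, 3, 2, 2))
  expect_true(all(deformable_conv2d(x, w0, off0) == 0))
  # identity tap (center weight 1) with zero offsets -> input on interior
  wi <- array(0, c(3, 3, 2, 2))
  wi[2, 2, 1, 1] <- 1
  wi[2, 2, 2, 2] <- 1
  y <- deformable_conv2d(x, wi, off0)
  expect_equal(y, x, tolerance = 1e-12)
  # integer offset of one pixel shifts the sampled content
  off1 <- off0
  off1[, , 1:18] <- 0
  off1[, , seq(2, 18, 2)] <- 1  # +1 column shift for every tap
  y1 <- deformable_conv2d(x, wi, off1)
  expect_equal(y1[, 1:7, ], x[, 2:8, ], tolerance = 1e-12)
  expect_error(deformable_conv2d(x, array(0, c(3, 3, 3, 2)), off0),
               "mismatch")
  expect_error(deformable_conv2d(x, wi, off0[, , 1:16]), "channels")
})

test_that("backbone stages come out at strides 4, 8, 16, 32", {
  set.seed(21)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  bb <- build_backbone(backbone_config("tiny", deformable = FALSE))
  fs <- forward_backbone(bb, img)
  expect_named(fs, c("C2", "C3", "C4", "C5"))
  expect_equal(vapply(fs, function(f) dim(f$values)[1], 0),
               c(C2 = 16, C3 = 8, C4 = 4, C5 = 2))
  expect_equal(vapply(fs, function(f) f$stride, 0L),
               c(C2 = 4L, C3 = 8L, C4 = 16L, C5 = 32L))
})

test_that("freshly initialized deformable backbone equals its regular twin", {
  P <- asNamespace("pestdetectr")
  set.seed(25)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mk <- function(deformable) {
    withr::with_seed(123, build_backbone(
      backbone_config("tiny", deformable_stages = c("C3", "C4", "C5"),
                      deformable = deformable)))
  }
  bd <- mk(TRUE)
  bp <- mk(FALSE)
  # offset convs are zero-initialized extras; shared weights must agree, so
  # copy the regular net's weights into the deformable one's main taps
  wd <- P$collect_params(bd)
  wp <- P$collect_params(bp)
  nm_d <- vapply(wd, function(p) p$name, "")
  for (p in wp) {
    tgt <- wd[[match(p$name, nm_d)]]
    tgt$v <- p$v
  }
  fd <- forward_backbone(bd, img)
  fp <- forward_backbone(bp, img)
  for (nm in names(fd)) {
    expect_lt(max(abs(fd[[nm]]$values - fp[[nm]]$values)), 1e-5)
  }
  # offset convolutions add parameters
  expect_gt(P$n_params(bd), P$n_params(bp))
  expect_error(build_backbone(backbone_config("resnet101")), "supported")
  expect_error(backbone_config("tiny", deformable_stages = character(),
                               deformable = TRUE), "at least one")
})

test_that("offset gradients pass a finite-difference check", {
  P <- asNamespace("pestdetectr")
  set.seed(29)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  w <- array(rnorm(3 * 3 * 2 * 2, 0, 0.4), c(3, 3, 2, 2))
  off_v <- array(rnorm(5 * 5 * 18, 0, 0.6), c(5, 5, 18))
  gy <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  loss_of <- function(vec, field) {
    xx <- x; ww <- w; oo <- off_v
    if (field == "off") oo <- array(vec, dim(off_v))
    if (field == "x") xx <- array(vec, dim(x))
    if (field == "w") ww <- array(vec, dim(w))
    sum(P$cpp_deform_fwd(xx, ww, numeric(0), oo, 1L, 1L, 1L) * gy)
  }
  gr <- P$cpp_deform_bwd(x, w, off_v, gy, 1L, 1L, 1L)
  for (field in c("off", "x", "w")) {
    v0 <- switch(field, off = off_v, x = x, w = w)
    idx <- sample(length(v0), min(40, length(v0)))
    num <- numeric_grad(function(v) loss_of(v, field), as.vector(v0))[idx]
    ana <- as.vector(switch(field, off = gr$goff, x = gr$gx, w = gr$gw))[idx]
    expect_lt(rel_err(num, ana), 1e-3)
  }
})
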