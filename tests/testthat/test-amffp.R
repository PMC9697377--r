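test_that("lateral projection is a per-pixel channel mix", {
  set.seed(3)
  x <- array(rnorm(6 * 7 * 4), c(6, 7, 4))
  # identity 1x1 with d = input channels reproduces the input
  wi <- array(0, c(1, 1, 4, 4))
  for (c in 1:4) wi[1, 1, c, c] <- 1
  expect_equal(lateral_project(x, list(w = wi, b = NULL)), x)
  # random projection equals an independent per-pixel matrix multiply
  w <- array(rnorm(1 * 1 * 4 * 3), c(1, 1, 4, 3))
  b <- rnorm(3)
  got <- lateral_project(x, list(w = w, b = b))
  expect_equal(dim(got), c(6, 7, 3))
  M <- matrix(w, 4, 3)
  want <- array(0, c(6, 7, 3))
  for (i in 1:6) for (j in 1:7) want[i, j, ] <- x[i, j, ] %*% M + b
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(lateral_project(x, list(w = array(0, c(3, 3, 4, 3)),
                                       b = NULL)), "1x1")
  expect_error(lateral_project(x, list(w = array(0, c(1, 1, 5, 3)),
                                       b = NULL)), "channel")
})

test_that("nearest upsampling replicates pixels into 2x2 blocks", {
  one <- array(7, c(1, 1, 1))
  up <- upsample2x_nearest(one)
  expect_equal(dim(up), c(2, 2, 1))
  expect_true(all(up == 7))
  set.seed(4)
  x <- array(rnorm(5 * 3 * 2), c(5, 3, 2))
  up <- upsample2x_nearest(x)
  expect_equal(sum(up), 4 * sum(x))
  # top-left subsampling inverts the replication exactly
  expect_identical(up[seq(1, 10, 2), seq(1, 6, 2), ], x)
  fm <- feature_map(x, stride = 8L)
  up_fm <- upsample2x_nearest(fm)
  expect_s3_class(up_fm, "feature_map")
  expect_equal(up_fm$stride, 4L)
})

test_that("attention weights are a sigmoid-bounded generator output", {
  P <- asNamespace("pestdetectr")
  set.seed(6)
  d <- 8
  x <- array(rnorm(6 * 6 * d), c(6, 6, d))
  gen <- withr::with_seed(1, P$weight_generator(d, 4, 1, "wg"))
  a <- attention_weights(x, gen)
  expect_equal(dim(a), c(6, 6, 1))
  expect_true(all(a > 0 & a < 1))
  # zero parameters -> uniform sigmoid(0) = 0.5
  zg <- P$weight_generator(d, 4, 1, "z")
  for (p in P$collect_params(zg)) p$v <- p$v * 0
  expect_true(all(attention_weights(x, zg) == 0.5))
  # equals the three primitives composed independently
  w1 <- gen$c1$w$v; b1 <- gen$c1$b$v
  w3 <- gen$c3$w$v; b3 <- gen$c3$b$v
  h <- oracle_conv2d(x, w1, b1, pad = 0)
  h <- h * (h > 0)
  want <- 1 / (1 + exp(-oracle_conv2d(h, w3, b3, pad = 1)))
  expect_equal(a, want, tolerance = 1e-12)
})

test_that("level fusion weights the upsampled upper pathway", {
  set.seed(8)
  lat <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  upper <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  up <- upsample2x_nearest(upper)
  # alpha = 1 is the plain FPN sum
  expect_equal(fuse_level(lat, upper, 1), lat + up)
  # alpha = 0 returns the lateral untouched
  expect_equal(fuse_level(lat, upper, 0), lat)
  # spatial alpha map, elementwise oracle
  alpha <- array(runif(36), c(6, 6, 1))
  got <- fuse_level(lat, upper, alpha)
  want <- lat + array(alpha, c(6, 6, 3)) * up
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(fuse_level(lat, array(0, c(4, 4, 3)), 1), "mismatch")
})

test_that("the pyramid has five levels at halving resolutions", {
  set.seed(10)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  bb <- build_backbone(backbone_config("tiny", deformable = FALSE))
  fs <- forward_backbone(bb, img)
  neck <- build_neck(list(C2 = 8, C3 = 16, C4 = 24, C5 = 32),
                     neck_config(d = 16, hidden = 4))
  pyr <- build_pyramid(fs, neck)
  expect_named(pyr$levels, c("P2", "P3", "P4", "P5", "P6"))
  expect_equal(vapply(pyr$levels, function(f) dim(f$values)[1], 0),
               c(P2 = 16, P3 = 8, P4 = 4, P5 = 2, P6 = 1))
  expect_true(all(vapply(pyr$levels,
                         function(f) dim(f$values)[3] == 16, TRUE)))
  # attention maps recorded for the fused levels, strictly inside (0, 1)
  expect_named(pyr$alpha_maps, c("P4", "P3", "P2"))
  for (a in pyr$alpha_maps) expect_true(all(a > 0 & a < 1))
  # deterministic: same input, same maps, bitwise
  pyr2 <- build_pyramid(fs, neck)
  expect_identical(pyr$alpha_maps, pyr2$alpha_maps)
  expect_error(build_pyramid(fs[1:3], neck), "C5")
})

test_that("alpha bypass reduces the pyramid to a plain FPN", {
  P <- asNamespace("pestdetectr")
  set.seed(12)
  d <- 8
  in_ch <- list(C2 = 4, C3 = 6, C4 = 8, C5 = 10)
  neck <- build_neck(in_ch, neck_config(d = d, hidden = 4))
  lat_w <- lapply(neck$laterals, function(l) l$w$v)
  lat_b <- lapply(neck$laterals, function(l) l$b$v)
  sm_w <- lapply(neck$smooth, function(l) l$w$v)
  sm_b <- lapply(neck$smooth, function(l) l$b$v)
  names(sm_w) <- names(sm_b) <- names(neck$smooth)
  worst <- 0
  for (rep in 1:100) {
    feats <- list(C2 = array(rnorm(16 * 16 * 4), c(16, 16, 4)),
                  C3 = array(rnorm(8 * 8 * 6), c(8, 8, 6)),
                  C4 = array(rnorm(4 * 4 * 8), c(4, 4, 8)),
                  C5 = array(rnorm(2 * 2 * 10), c(2, 2, 10)))
    pyr <- build_pyramid(feats, neck, bypass = TRUE)
    ref <- oracle_fpn(feats, lat_w, lat_b, sm_w, sm_b)
    for (nm in names(ref)) {
      worst <- max(worst, max(abs(pyr$levels[[nm]]$values - ref[[nm]])))
    }
    expect_length(pyr$alpha_maps, 0)
  }
  expect_lt(worst, 1e-5)
})

test_that("the literal twice-subsampling layout also yields five levels", {
  set.seed(14)
  feats <- list(C2 = array(rnorm(16 * 16 * 4), c(16, 16, 4)),
                C3 = array(rnorm(8 * 8 * 6), c(8, 8, 6)),
                C4 = array(rnorm(4 * 4 * 8), c(4, 4, 8)),
                C5 = array(rnorm(2 * 2 * 10), c(2, 2, 10)))
  neck <- build_neck(list(C2 = 4, C3 = 6, C4 = 8, C5 = 10),
                     neck_config(d = 8, hidden = 4,
                                 literal_subsample_variant = TRUE))
  pyr <- build_pyramid(feats, neck)
  expect_equal(vapply(pyr$levels, function(f) dim(f$values)[1], 0),
               c(P2 = 16, P3 = 8, P4 = 4, P5 = 2, P6 = 1))
  expect_named(pyr$alpha_maps, c("P3", "P2"))
})
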