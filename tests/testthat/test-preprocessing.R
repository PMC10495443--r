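test_that("discrete Gaussian kernels are normalised and symmetric", {
  for (sp in list(gaussianFilterSpec(1, 1L), gaussianFilterSpec(1, 2L),
                  gaussianFilterSpec(2.5, 3L),
                  gaussianFilterSpec(0.5, 4L))) {
    k <- gaussianKernel2d(sp)
    expect_equal(dim(k), rep(2L * sp@radius + 1L, 2L))
    expect_lt(abs(sum(k) - 1), 1e-12)
    expect_identical(k, t(k))
    rot90 <- t(k[nrow(k):1L, ])
    expect_identical(k, rot90)
  }
  # analytic 3x3 evaluation: centre weight 1 / (1 + 4 e^-1/2 + 4 e^-1)
  k <- gaussianKernel2d(gaussianFilterSpec(1, 1L))
  centerOracle <- 1 / (1 + 4 * exp(-0.5) + 4 * exp(-1))
  expect_equal(k[2L, 2L], centerOracle, tolerance = 1e-12)
  expect_equal(k[2L, 2L], 0.2042, tolerance = 1e-4)
  expect_error(gaussianFilterSpec(-1, 1L), "sigma")
})

test_that("denoising matches the direct-convolution oracle", {
  # constant image is a fixed point (weights sum to 1)
  const <- matrix(3.7, 6L, 6L)
  expect_equal(denoiseImage(const, gaussianFilterSpec(1, 2L)), const)
  # unit impulse reproduces the kernel in the central window
  imp <- matrix(0, 5L, 5L); imp[3L, 3L] <- 1
  sp <- gaussianFilterSpec(1, 1L)
  out <- denoiseImage(imp, sp)
  expect_equal(out[2:4, 2:4], gaussianKernel2d(sp), tolerance = 1e-14)
  # random images vs the nested-loop oracle (edge replication)
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(runif(7L * 9L), 7L, 9L)
    spec <- gaussianFilterSpec(runif(1L, 0.5, 2), sample(1:2, 1L))
    expect_equal(denoiseImage(img, spec),
                 oracleConv2d(img, gaussianKernel2d(spec)),
                 tolerance = 1e-12)
    # convexity: output never leaves the input range
    sm <- denoiseImage(img, spec)
    expect_gte(min(sm), min(img) - 1e-12)
    expect_lte(max(sm), max(img) + 1e-12)
  }
  # full 2-D convolution equals the separable two-pass computation
  img <- matrix(runif(12L * 12L), 12L)
  expect_equal(denoiseImage(img, gaussianFilterSpec(1.3, 2L)),
               oracleSeparableConv(img, 1.3, 2L), tolerance = 1e-10)
  # colour input is filtered per channel
  rgb <- array(runif(6L * 6L * 3L), dim = c(6L, 6L, 3L))
  den <- denoiseImage(rgb, sp)
  expect_equal(den[, , 2L], denoiseImage(rgb[, , 2L], sp))
  expect_error(denoiseImage(numeric(0L)), "non-empty")
})

test_that("standardisation converts, normalises and resizes", {
  set.seed(4)
  rgb <- array(runif(40L * 50L * 3L) * 255, dim = c(40L, 50L, 3L))
  out <- standardizeImage(rgb, 30L)
  expect_equal(dim(out), c(30L, 30L))
  expect_true(all(out >= 0 & out <= 1))
  # constant RGB collapses to all zeros under min-max
  flat <- array(128, dim = c(10L, 10L, 3L))
  expect_equal(standardizeImage(flat, 30L), matrix(0, 30L, 30L))
  # luminance weights
  lum <- array(0, dim = c(4L, 4L, 3L)); lum[, , 1L] <- 100
  lum[1L, 1L, 1L] <- 200   # non-constant so min-max is informative
  g <- 0.299 * lum[, , 1L]
  expect_equal(standardizeImage(lum, 4L), (g - min(g)) / diff(range(g)))
  expect_error(standardizeImage(array(1, dim = c(4L, 4L, 2L))),
               "channel")
  # bilinear resize agrees with the nearest-of-four oracle
  grad <- outer(seq_len(60L), seq_len(60L),
                function(i, j) i / 60 + (j / 60)^2)
  expect_equal(bilinearResize(grad, 30L, 30L), oracleBilinear(grad, 30L, 30L),
               tolerance = 1e-6)
  # idempotence for already-30x30 grayscale input: the first pass pins
  # the range to [0, 1] exactly and the identity resize preserves it
  grad30 <- outer(seq_len(30L), seq_len(30L),
                  function(i, j) i / 30 + (j / 30)^2)
  once <- standardizeImage(grad30, 30L)
  expect_equal(standardizeImage(once, 30L), once, tolerance = 1e-10)
})

test_that("augmentation is seeded, label-preserving and optional", {
  set.seed(8)
  x <- array(runif(6L * 12L * 12L), dim = c(6L, 12L, 12L))
  stack <- new("ImageStack", x = x, labels = rep(0:2, 2L),
               classNames = tumorClasses())
  offCfg <- preprocessConfig(targetSize = 12L, augment = TRUE,
                             flags = c(rescale = FALSE, zoom = FALSE,
                                       horizontal_flip = FALSE,
                                       vertical_flip = FALSE,
                                       sharpness = FALSE))
  expect_identical(augmentImages(stack, offCfg), stack)  # identity

  cfg <- preprocessConfig(targetSize = 12L, augment = TRUE, seed = 9L)
  a <- augmentImages(stack, cfg)
  b <- augmentImages(stack, cfg)
  expect_identical(stackArray(a), stackArray(b))         # determinism
  expect_length(a, 12L)
  expect_equal(imageLabels(a), rep(imageLabels(stack), 2L))
  expect_true(all(stackArray(a) >= 0 & stackArray(a) <= 1))

  m <- matrix(c(1, 3, 2, 4), 2L)   # [[1,2],[3,4]] row-wise
  expect_equal(flipHorizontal(m), matrix(c(2, 4, 1, 3), 2L))
  expect_equal(flipVertical(m), matrix(c(3, 1, 4, 2), 2L))
})

test_that("the pipeline composes denoise, standardise and augment", {
  cfg <- phantomConfig(nPerClass = 3L, imageSize = 24L, seed = 2L)
  ds <- generatePhantomDataset(cfg, "training")
  pc <- preprocessConfig(targetSize = 30L)
  stack <- preprocessPipeline(ds, pc)
  expect_equal(dim(stackArray(stack)), c(12L, 30L, 30L))
  expect_true(all(stackArray(stack) >= 0 & stackArray(stack) <= 1))
  # stage composition, element-wise
  manual <- standardizeImage(denoiseImage(images(ds)[[5L]], pc@filter),
                             30L)
  expect_equal(stackArray(stack)[5L, , ], manual)
  # deterministic under a fixed seed, and augmentation doubles the count
  aug <- preprocessConfig(targetSize = 30L, augment = TRUE, seed = 77L)
  s1 <- preprocessPipeline(ds, aug)
  s2 <- preprocessPipeline(ds, aug)
  expect_identical(stackArray(s1), stackArray(s2))
  expect_length(s1, 24L)
})
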