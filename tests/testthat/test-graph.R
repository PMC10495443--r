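test_that("adjacency kernels honour their contracts", {
  for (fam in c("gaussian", "uniform", "lognormal")) {
    k <- makeAdjacencyKernel(fam, "iid", 12L, 31L)
    expect_equal(dim(kernelEntries(k)), c(12L, 12L))
    expect_true(all(kernelEntries(k) >= 0 & kernelEntries(k) <= 1))
    k2 <- makeAdjacencyKernel(fam, "iid", 12L, 31L)
    expect_identical(kernelEntries(k), kernelEntries(k2))
    k3 <- makeAdjacencyKernel(fam, "iid", 12L, 32L)
    expect_false(identical(kernelEntries(k), kernelEntries(k3)))
  }
  expect_error(makeAdjacencyKernel("uniform", "radial", 5L),
               "gaussian")
})

test_that("the radial gaussian kernel matches its closed form", {
  k <- makeAdjacencyKernel("gaussian", "radial", 5L)
  e <- kernelEntries(k)
  # formula oracle on the 5x5 grid: s = n/4, centre at (3, 3)
  s <- 5 / 4
  oracle <- outer(1:5, 1:5, function(i, j)
    exp(-((i - 3)^2 + (j - 3)^2) / (2 * s^2)))
  expect_equal(e, oracle, tolerance = 1e-14)
  expect_equal(e[3L, 3L], 1)
  expect_equal(sum(e == max(e)), 1L)        # unique maximum at the centre
  expect_equal(which(e == max(e)), 13L)
})

test_that("superposition overlays the kernel element-wise", {
  img <- matrix(c(1, 3, 2, 4), 2L)          # [[1,2],[3,4]] row-wise
  ker <- onesKernel(2L)
  expect_equal(nodeFeatures(superposeKernel(img, ker)), img)
  zer <- ker; zer@entries <- matrix(0, 2L, 2L)
  expect_equal(nodeFeatures(superposeKernel(img, zer)),
               matrix(0, 2L, 2L))
  half <- ker; half@entries <- matrix(c(0.5, 1, 1, 0.5), 2L)
  g <- superposeKernel(img, half)
  expect_equal(nodeFeatures(g), matrix(c(0.5, 3, 2, 2), 2L))
  expect_equal(hopsApplied(g), 0L)
  # matmul mode is a true matrix product
  gm <- superposeKernel(img, half, mode = "matmul")
  expect_equal(nodeFeatures(gm), img %*% half@entries)
  expect_error(superposeKernel(matrix(1, 3L, 3L), ker), "side")
})

test_that("the pixel lattice adjacency is symmetric with correct degrees", {
  for (conn in c(4L, 8L)) {
    lat <- pixelLattice(5L, conn)
    A <- adjacencyMatrix(lat)
    expect_equal(dim(A), c(25L, 25L))
    expect_equal(as.matrix(A), t(as.matrix(A)))
    expect_true(all(Matrix::diag(A) == 0))
    deg <- Matrix::rowSums(A)
    center <- 13L                            # interior node (3, 3)
    expect_equal(deg[center], conn)
    expect_equal(deg[1L], if (conn == 4L) 2 else 3)   # corner
  }
})

test_that("graph convolution reproduces the hand-worked example exactly", {
  f <- matrix(as.numeric(1:9), 3L, 3L, byrow = TRUE)  # 1..9 row-major
  out <- nodeFeatures(graphConvolve(f, pixelLattice(3L, 4L), 1L))
  expect_identical(out[2L, 2L], 5)          # (2+4+6+8)/4
  expect_identical(out[1L, 1L], 3)          # (2+4)/2
  # zero hops is the identity, constants are fixed points
  expect_identical(nodeFeatures(graphConvolve(f, pixelLattice(3L), 0L)),
                   f)
  cst <- matrix(2.5, 4L, 4L)
  expect_equal(nodeFeatures(graphConvolve(cst, pixelLattice(4L), 3L)),
               cst)
  expect_error(graphConvolve(f, pixelLattice(3L), -1L), "hops")
})

test_that("graph convolution matches the nested-loop oracle exactly", {
  set.seed(55)
  for (rep in 1:25) {
    f <- matrix(runif(25L), 5L, 5L)
    for (conn in c(4L, 8L)) {
      for (hops in 1:3) {
        got <- nodeFeatures(graphConvolve(f, pixelLattice(5L, conn),
                                          hops))
        expect_identical(got, oracleGraphConvolve(f, conn, hops))
      }
    }
    # includeSelf ablation agrees with the oracle too
    got <- nodeFeatures(graphConvolve(f, pixelLattice(5L, 4L), 2L,
                                      includeSelf = TRUE))
    expect_identical(got, oracleGraphConvolve(f, 4L, 2L,
                                              includeSelf = TRUE))
  }
})

test_that("graph convolution contracts the range and respects symmetry", {
  set.seed(66)
  for (rep in 1:10) {
    f <- matrix(rnorm(49L), 7L, 7L)
    lat <- pixelLattice(7L, 4L)
    out <- nodeFeatures(graphConvolve(f, lat, 1L))
    expect_gte(min(out), min(f))
    expect_lte(max(out), max(f))
    # equivariance under flips of the feature grid
    fh <- f[, 7:1]
    expect_equal(nodeFeatures(graphConvolve(fh, lat, 2L)),
                 nodeFeatures(graphConvolve(f, lat, 2L))[, 7:1])
    fv <- f[7:1, ]
    expect_equal(nodeFeatures(graphConvolve(fv, lat, 2L)),
                 nodeFeatures(graphConvolve(f, lat, 2L))[7:1, ])
    # repeated hops never widen the feature range
    rng <- diff(range(f))
    g <- new("GraphImage", features = f, hopsApplied = 0L)
    for (h in 1:5) {
      g <- graphConvolve(g, lat, 1L)
      newRng <- diff(range(nodeFeatures(g)))
      expect_lte(newRng, rng + 1e-12)
      rng <- newRng
    }
    expect_equal(hopsApplied(g), 5L)
  }
})

test_that("kernels round-trip through CSV + JSON sidecar", {
  k <- makeAdjacencyKernel("lognormal", "iid", 9L, 17L)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeKernel(k, csv)
  expect_true(file.exists(sub("csv$", "json", csv)))
  back <- readKernel(csv)
  expect_equal(kernelEntries(back), kernelEntries(k), tolerance = 1e-15)
  expect_identical(kernelFamily(back), "lognormal")
  expect_identical(kernelSeed(back), 17L)
})
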