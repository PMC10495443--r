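# Independent brute-force oracles used across the suite.  These are
# deliberately naive (nested loops, direct formulas) and share no code
# with the package implementation.

# neighbor-averaging by double loop: for each node scan every other
# node in increasing column-major index and average the lattice
# neighbours' previous-round values
oracleGraphConvolve <- function(f, connectivity = 4L, hops = 1L,
                                includeSelf = FALSE) {
  n <- nrow(f)
  for (h in seq_len(hops)) {
    out <- matrix(0, n, n)
    for (cj in seq_len(n)) {
      for (ri in seq_len(n)) {
        s <- 0; cnt <- 0L
        for (cv in seq_len(n)) {
          for (rv in seq_len(n)) {
            dr <- abs(rv - ri); dc <- abs(cv - cj)
            isNb <- if (connectivity == 4L) dr + dc == 1L
                    else max(dr, dc) == 1L
            if (includeSelf && dr == 0L && dc == 0L) isNb <- TRUE
            if (isNb) { s <- s + f[rv, cv]; cnt <- cnt + 1L }
          }
        }
        out[ri, cj] <- s / cnt
      }
    }
    f <- out
  }
  f
}

# direct 2-D convolution with edge-replication padding, by loops
oracleConv2d <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (dy in -r:r) {
        for (dx in -r:r) {
          ii <- min(max(i + dy, 1L), h)
          jj <- min(max(j + dx, 1L), w)
          acc <- acc + kernel[dy + r + 1L, dx + r + 1L] * img[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# two sequential 1-D convolutions (rows then columns), replication pad
oracleSeparableConv <- function(img, sigma, radius) {
  off <- seq(-radius, radius)
  k1 <- exp(-off^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  convRow <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n))
      for (d in seq_along(off))
        out[i] <- out[i] + k1[d] * v[min(max(i + off[d], 1L), n)]
    out
  }
  tmp <- t(apply(img, 1L, convRow))
  apply(tmp, 2L, convRow)
}

# nearest-of-four bilinear resampling by loops (half-pixel centres)
oracleBilinear <- function(img, outR, outC) {
  out <- matrix(0, outR, outC)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(outR)) {
    for (j in seq_len(outC)) {
      sr <- (i - 0.5) * nr / outR + 0.5
      sc <- (j - 0.5) * nc / outC + 0.5
      r0 <- floor(sr); c0 <- floor(sc)
      fr <- sr - r0; fc <- sc - c0
      if (r0 < 1) { r0 <- 1; fr <- 0 }
      if (c0 < 1) { c0 <- 1; fc <- 0 }
      r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
      r0 <- min(r0, nr); c0 <- min(c0, nc)
      out[i, j] <- (1 - fr) * (1 - fc) * img[r0, c0] +
        (1 - fr) * fc * img[r0, c1] +
        fr * (1 - fc) * img[r1, c0] +
        fr * fc * img[r1, c1]
    }
  }
  out
}

# nearest-class-centroid classifier on flattened pixels
centroidAccuracy <- function(trainX, trainY, testX, testY) {
  classes <- sort(unique(trainY))
  centroids <- t(vapply(classes, function(cl)
    colMeans(trainX[trainY == cl, , drop = FALSE]),
    numeric(ncol(trainX))))
  pred <- apply(testX, 1L, function(v) {
    d <- rowSums((centroids - matrix(v, nrow(centroids), length(v),
                                     byrow = TRUE))^2)
    classes[which.min(d)]
  })
  mean(pred == testY)
}

# flatten an ImageStack into a samples x pixels matrix
stackToMatrix <- function(stack) {
  x <- stackArray(stack)
  matrix(x, nrow = dim(x)[1L])
}

# per-sample tally oracle for the metric suite
oracleMetrics <- function(truth, pred) {
  prec <- rec <- numeric(4L)
  for (cl in 0:3) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec[cl + 1L] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[cl + 1L] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  list(precision = prec, recall = rec, a3 = mean(truth == pred),
       a4 = mean(rec))
}

# build a small PNG fixture tree in the class-folder layout
makePngTree <- function(root, split = "Training", nPerClass = 2L,
                        seed = 7L) {
  set.seed(seed)
  for (cls in tumorClasses()) {
    d <- file.path(root, split, cls)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nPerClass)) {
      img <- matrix(runif(16 * 16), 16L, 16L)
      png::writePNG(img, file.path(d, sprintf("img_%02d.png", i)))
    }
  }
  root
}

# a constant all-ones adjacency kernel (degenerate superposition)
onesKernel <- function(n) {
  methods::new("AdjacencyKernel", family = "uniform", mode = "iid",
               n = as.integer(n), entries = matrix(1, n, n), seed = 0L)
}
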