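# Weighted adjacency-kernel construction, superposition on images, and
# the neighbor-averaging graph convolution over the pixel lattice.

#' Build a weighted adjacency kernel
#'
#' In `"iid"` mode the `n x n` entries are independent draws from the
#' named distribution -- standard normal (`gaussian`), uniform(0, 1)
#' (`uniform`) or log-normal with meanlog 0 / sdlog 1 (`lognormal`) --
#' drawn under the given seed and then min-max rescaled to `[0, 1]`.
#' In `"radial"` mode (Gaussian family only) entry `(i, j)` equals
#' `exp(-d^2 / (2 s^2))` where `d` is the Euclidean distance from
#' `(i, j)` to the matrix centre and `s = n / 4`; the centre cell (odd
#' `n`) attains the maximum value 1.  Deterministic given
#' `(family, mode, n, seed)`.
#'
#' @param family `"gaussian"`, `"uniform"` or `"lognormal"`
#' @param mode `"iid"` or `"radial"`
#' @param n integer image side, >= 2
#' @param seed integer seed (used in `"iid"` mode)
#' @return an [AdjacencyKernel-class]
#' @export
makeAdjacencyKernel <- function(family = c("gaussian", "uniform",
                                           "lognormal"),
                                mode = c("iid", "radial"), n = 30L,
                                seed = 1L) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (mode == "radial") {
    if (family != "gaussian")
      stop("radial mode is defined for the gaussian family only")
    ctr <- (n + 1) / 2
    idx <- seq_len(n)
    d2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
    s <- n / 4
    entries <- exp(-d2 / (2 * s^2))
  } else {
    draws <- withSeed(seed, switch(family,
      gaussian = stats::rnorm(n * n),
      uniform = stats::runif(n * n),
      lognormal = stats::rlnorm(n * n, meanlog = 0, sdlog = 1)))
    rng <- range(draws)
    entries <- if (rng[2] > rng[1]) (draws - rng[1]) / (rng[2] - rng[1])
               else rep(0, n * n)
    entries <- matrix(entries, n, n)
  }
  new("AdjacencyKernel", family = family, mode = mode, n = n,
      entries = entries, seed = as.integer(seed))
}

#' Superpose an adjacency kernel on an image
#'
#' Default `"hadamard"` mode overlays the kernel by element-wise
#' multiplication, turning the image into a weighted graph of node
#' features; `"matmul"` mode performs a true matrix product of image
#' and kernel for comparison.
#'
#' @param image numeric `n x n` matrix (or a [GraphImage-class])
#' @param kernel an [AdjacencyKernel-class] with matching side
#' @param mode `"hadamard"` (default) or `"matmul"`
#' @return a [GraphImage-class] with `hopsApplied = 0`
#' @export
superposeKernel <- function(image, kernel,
                            mode = c("hadamard", "matmul")) {
  mode <- match.arg(mode)
  stopifnot(is(kernel, "AdjacencyKernel"))
  if (is(image, "GraphImage")) image <- image@features
  if (!is.matrix(image) || !identical(dim(image), dim(kernel@entries)))
    stop("image side must equal the kernel side")
  feat <- if (mode == "hadamard") image * kernel@entries
          else image %*% kernel@entries
  new("GraphImage", features = feat, hopsApplied = 0L)
}

#' Construct a pixel lattice
#'
#' @param n integer image side, >= 2
#' @param connectivity 4 (edge-adjacent) or 8 (edge + corner adjacent)
#' @return a [PixelLattice-class]
#' @export
pixelLattice <- function(n, connectivity = 4L) {
  new("PixelLattice", n = as.integer(n),
      connectivity = as.integer(connectivity))
}

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "PixelLattice", function(x) {
  n <- x@n
  idx <- matrix(seq_len(n * n), n, n)        # column-major node ids
  from <- integer(); to <- integer()
  addEdges <- function(dr, dc) {
    rs <- seq_len(n - abs(dr)); cs <- seq_len(n - abs(dc))
    a <- idx[rs + max(0L, -dr), cs + max(0L, -dc), drop = FALSE]
    b <- idx[rs + max(0L, dr), cs + max(0L, dc), drop = FALSE]
    from <<- c(from, as.integer(a)); to <<- c(to, as.integer(b))
  }
  addEdges(1L, 0L)            # vertical neighbours
  addEdges(0L, 1L)            # horizontal neighbours
  if (x@connectivity == 8L) {
    addEdges(1L, 1L)
    addEdges(-1L, 1L)
  }
  Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                       dims = c(n * n, n * n))
})

# neighbour offsets (dr, dc) in increasing column-major node-index
# order; 0 marks the node itself (used when includeSelf = TRUE)
neighborOffsets <- function(connectivity, includeSelf = FALSE) {
  offs <- if (connectivity == 4L)
    list(c(0L, -1L), c(-1L, 0L), c(1L, 0L), c(0L, 1L))
  else
    list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L), c(1L, 0L),
         c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  if (includeSelf) {
    pos <- if (connectivity == 4L) 2L else 4L   # just before (+1, 0)... after (-1,0)
    offs <- append(offs, list(c(0L, 0L)), after = pos)
  }
  offs
}

#' Neighbor-averaging graph convolution
#'
#' Performs `hops` synchronous rounds in which every node's feature is
#' replaced by the arithmetic mean of its lattice neighbours' current
#' features (self excluded by default; border nodes average over their
#' existing neighbours only).  All updates within a round use the
#' previous round's values, so the result is independent of any
#' traversal order.
#'
#' @param gimage a [GraphImage-class] (a plain matrix is promoted)
#' @param lattice a [PixelLattice-class] with side matching the image
#' @param hops integer >= 0 number of rounds
#' @param includeSelf include the node's own value in the average?
#' @return a [GraphImage-class] with `hopsApplied` incremented by
#'   `hops`
#' @export
graphConvolve <- function(gimage, lattice = pixelLattice(30L), hops = 1L,
                          includeSelf = FALSE) {
  if (is.matrix(gimage))
    gimage <- new("GraphImage", features = gimage, hopsApplied = 0L)
  stopifnot(is(gimage, "GraphImage"), is(lattice, "PixelLattice"))
  if (hops < 0L) stop("hops must be >= 0")
  f <- gimage@features
  if (nrow(f) != lattice@n || ncol(f) != lattice@n)
    stop("feature grid side must equal the lattice side")
  offs <- neighborOffsets(lattice@connectivity, includeSelf)
  n <- lattice@n
  cnt <- matrix(0, n, n)
  for (o in offs) {
    rs <- seq_len(n - abs(o[1])); cs <- seq_len(n - abs(o[2]))
    cnt[rs + max(0L, -o[1]), cs + max(0L, -o[2])] <-
      cnt[rs + max(0L, -o[1]), cs + max(0L, -o[2])] + 1
  }
  for (h in seq_len(hops)) {
    acc <- matrix(0, n, n)
    for (o in offs) {              # accumulate in fixed neighbour order
      rs <- seq_len(n - abs(o[1])); cs <- seq_len(n - abs(o[2]))
      dst <- list(rs + max(0L, -o[1]), cs + max(0L, -o[2]))
      src <- list(rs + max(0L, o[1]), cs + max(0L, o[2]))
      acc[dst[[1]], dst[[2]]] <- acc[dst[[1]], dst[[2]]] +
        f[src[[1]], src[[2]], drop = FALSE]
    }
    f <- acc / cnt
  }
  new("GraphImage", features = f,
      hopsApplied = gimage@hopsApplied + as.integer(hops))
}

#' Apply the graph input stage to a whole image stack
#'
#' Superposes the adjacency kernel on every image and applies `hops`
#' rounds of neighbor-averaging graph convolution; this is the input
#' transformation shared by the graph-mode network variants.
#'
#' @param stack an [ImageStack-class]
#' @param kernel an [AdjacencyKernel-class] matching the image side
#' @param connectivity 4 or 8
#' @param hops integer >= 0
#' @param superposeMode `"hadamard"` or `"matmul"`
#' @param includeSelf include each node's own value in the average?
#' @return an [ImageStack-class] of transformed features
#' @export
applyGraphStage <- function(stack, kernel, connectivity = 4L, hops = 1L,
                            superposeMode = c("hadamard", "matmul"),
                            includeSelf = FALSE) {
  stopifnot(is(stack, "ImageStack"), is(kernel, "AdjacencyKernel"))
  superposeMode <- match.arg(superposeMode)
  s <- dim(stack@x)[2L]
  lattice <- pixelLattice(s, connectivity)
  out <- stack@x
  for (i in seq_len(dim(out)[1L])) {
    g <- superposeKernel(out[i, , ], kernel, superposeMode)
    g <- graphConvolve(g, lattice, hops, includeSelf)
    out[i, , ] <- g@features
  }
  new("ImageStack", x = out, labels = stack@labels,
      classNames = stack@classNames)
}

#' Export / import adjacency kernels
#'
#' `writeKernel` stores the entries as a full-precision CSV (`n` rows
#' by `n` columns, no header) plus a JSON sidecar
#' `{family, mode, n, seed}` next to it; `readKernel` reconstructs the
#' kernel from the pair.
#'
#' @param kernel an [AdjacencyKernel-class]
#' @param csvPath path of the CSV file; the sidecar uses the same stem
#'   with extension `.json`
#' @return `writeKernel`: `csvPath`, invisibly; `readKernel`: an
#'   [AdjacencyKernel-class]
#' @export
writeKernel <- function(kernel, csvPath) {
  stopifnot(is(kernel, "AdjacencyKernel"))
  utils::write.table(
    format(kernel@entries, digits = 17, scientific = TRUE, trim = TRUE),
    csvPath, sep = ",", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  side <- paste0(tools::file_path_sans_ext(csvPath), ".json")
  jsonlite::write_json(list(family = kernel@family, mode = kernel@mode,
                            n = kernel@n, seed = kernel@seed),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' @rdname writeKernel
#' @export
readKernel <- function(csvPath) {
  entries <- as.matrix(utils::read.table(csvPath, sep = ","))
  dimnames(entries) <- NULL
  side <- paste0(tools::file_path_sans_ext(csvPath), ".json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("AdjacencyKernel", family = meta$family, mode = meta$mode,
      n = as.integer(meta$n), entries = entries,
      seed = as.integer(meta$seed))
}
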