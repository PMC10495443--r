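# The preprocessing chain: Gaussian denoising, grayscale conversion,
# min-max normalisation to [0, 1], bilinear resize to a small square
# lattice, and seeded augmentation.

#' GaussianFilterSpec: a discrete 2-D Gaussian smoothing kernel
#'
#' The kernel covers offsets `x, y` in `[-radius, radius]` with weights
#' proportional to `exp(-(x^2 + y^2) / (2 sigma^2))`, renormalised to
#' sum exactly 1 (so any analytic prefactor is irrelevant).
#'
#' @slot sigma positive numeric bandwidth, in pixels
#' @slot radius integer >= 1 half-width of the kernel
#' @export
setClass("GaussianFilterSpec",
         representation(sigma = "numeric", radius = "integer"))

setValidity("GaussianFilterSpec", function(object) {
  if (!is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be a positive finite number")
  if (object@radius < 1L) return("radius must be >= 1")
  TRUE
})

#' Construct a GaussianFilterSpec
#'
#' @param sigma positive bandwidth in pixels
#' @param radius integer half-width; the kernel is
#'   `(2*radius+1) x (2*radius+1)`
#' @return a [GaussianFilterSpec-class]
#' @export
gaussianFilterSpec <- function(sigma = 1, radius = 2L) {
  new("GaussianFilterSpec", sigma = sigma, radius = as.integer(radius))
}

#' Discrete 2-D Gaussian kernel
#'
#' Evaluates `exp(-(x^2 + y^2) / (2 sigma^2))` on the integer grid
#' `[-radius, radius]^2` and renormalises the result to sum exactly 1.
#' The kernel is symmetric under reflection and 90-degree rotation.
#'
#' @param spec a [GaussianFilterSpec-class]
#' @return a `(2*radius+1) x (2*radius+1)` numeric matrix summing to 1
#' @export
gaussianKernel2d <- function(spec) {
  stopifnot(is(spec, "GaussianFilterSpec"))
  validObject(spec)
  off <- seq(-spec@radius, spec@radius)
  k <- exp(-outer(off^2, off^2, "+") / (2 * spec@sigma^2))
  k / sum(k)
}

#' Gaussian denoising by 2-D convolution
#'
#' Convolves the image with the discrete Gaussian kernel of `spec`,
#' using edge-replication padding so the output has the same shape as
#' the input.  Colour images (`h x w x 3`) are filtered per channel.
#' Because the kernel weights are positive and sum to 1, the output is
#' a convex combination of input pixels: constant images are unchanged
#' and no value leaves the input's `[min, max]` range.
#'
#' @param image numeric matrix or `h x w x 3` array with finite values
#' @param spec a [GaussianFilterSpec-class]
#' @return array of the same shape as `image`
#' @export
denoiseImage <- function(image, spec = gaussianFilterSpec()) {
  if (length(image) == 0L) stop("image must be non-empty")
  if (!all(is.finite(image))) stop("image must contain finite values")
  if (length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3L]))
      out[, , ch] <- denoiseImage(image[, , ch], spec)
    return(out)
  }
  if (is.null(dim(image))) image <- as.matrix(image)
  k <- gaussianKernel2d(spec)
  r <- spec@radius
  h <- nrow(image); w <- ncol(image)
  # edge-replication padding
  ri <- pmin(pmax(seq(1L - r, h + r), 1L), h)
  ci <- pmin(pmax(seq(1L - r, w + r), 1L), w)
  pad <- image[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (dx in seq_len(2L * r + 1L)) {
    for (dy in seq_len(2L * r + 1L)) {
      out <- out + k[dy, dx] *
        pad[seq(dy, dy + h - 1L), seq(dx, dx + w - 1L), drop = FALSE]
    }
  }
  out
}

#' Bilinear resize of a grayscale image
#'
#' Resamples with the half-pixel-centre convention: output pixel centre
#' `j` maps to input coordinate `(j - 0.5) * n_in / n_out + 0.5` and the
#' value is the bilinear blend of the four (edge-clamped) nearest input
#' pixels.
#'
#' @param image numeric matrix
#' @param targetRows,targetCols output dimensions
#' @return a `targetRows x targetCols` matrix
#' @export
bilinearResize <- function(image, targetRows, targetCols = targetRows) {
  stopifnot(is.matrix(image), targetRows >= 1L, targetCols >= 1L)
  interpMat <- function(nIn, nOut) {
    src <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
    i0 <- pmin(pmax(floor(src), 1L), nIn)
    i1 <- pmin(i0 + 1L, nIn)
    fr <- pmin(pmax(src - floor(src), 0), 1)
    fr[floor(src) < 1L] <- 0          # clamped below: weight on pixel 1
    W <- matrix(0, nOut, nIn)
    W[cbind(seq_len(nOut), i0)] <- W[cbind(seq_len(nOut), i0)] + (1 - fr)
    W[cbind(seq_len(nOut), i1)] <- W[cbind(seq_len(nOut), i1)] + fr
    W
  }
  Wr <- interpMat(nrow(image), targetRows)
  Wc <- interpMat(ncol(image), targetCols)
  Wr %*% image %*% t(Wc)
}

#' Standardise one image: grayscale, normalise, resize
#'
#' Converts 3-channel input to luminance grayscale
#' (`0.299 R + 0.587 G + 0.114 B`), min-max normalises the intensities
#' to `[0, 1]` (a constant image maps to all zeros), and bilinearly
#' resizes to `targetSize x targetSize`.
#'
#' @param image numeric matrix (grayscale) or `h x w x 3` array
#' @param targetSize integer output side (default 30)
#' @return a `targetSize x targetSize` matrix with values in `[0, 1]`
#' @export
standardizeImage <- function(image, targetSize = 30L) {
  nd <- length(dim(image))
  if (nd == 3L) {
    if (dim(image)[3L] != 3L)
      stop(sprintf("unsupported channel count: %d", dim(image)[3L]))
    image <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
      0.114 * image[, , 3L]
  } else if (nd != 2L) {
    if (is.null(dim(image)) && is.numeric(image)) image <- as.matrix(image)
    else stop("image must have 1 or 3 channels")
  }
  rng <- range(image)
  image <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
           else matrix(0, nrow(image), ncol(image))
  out <- bilinearResize(image, targetSize, targetSize)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' PreprocessConfig: parameters of the preprocessing pipeline
#'
#' @slot targetSize integer output side (>= 8)
#' @slot filter a [GaussianFilterSpec-class]
#' @slot augment logical, whether to append augmented copies
#' @slot flags named logical vector with elements `rescale`, `zoom`,
#'   `horizontal_flip`, `vertical_flip`, `sharpness`
#' @slot zoomRange numeric in `[0, 1)`, maximal zoom-in fraction
#' @slot fillMode `"nearest"` (edge values fill geometry-induced gaps)
#' @slot seed integer seed for the stochastic transforms
#' @export
setClass("PreprocessConfig",
         representation(targetSize = "integer",
                        filter = "GaussianFilterSpec",
                        augment = "logical", flags = "logical",
                        zoomRange = "numeric", fillMode = "character",
                        seed = "integer"))

setValidity("PreprocessConfig", function(object) {
  if (object@targetSize < 8L) return("targetSize must be >= 8")
  if (object@zoomRange < 0 || object@zoomRange >= 1)
    return("zoomRange must lie in [0, 1)")
  need <- c("rescale", "zoom", "horizontal_flip", "vertical_flip",
            "sharpness")
  if (!all(need %in% names(object@flags)))
    return("flags must name rescale, zoom, horizontal_flip, vertical_flip, sharpness")
  if (object@fillMode != "nearest") return("fillMode must be 'nearest'")
  TRUE
})

#' Construct a PreprocessConfig
#'
#' @param targetSize output image side
#' @param sigma,radius Gaussian denoising parameters
#' @param augment append one augmented copy per image?
#' @param flags named logical vector enabling individual transforms
#' @param zoomRange maximal zoom-in fraction, in `[0, 1)`
#' @param seed integer seed
#' @return a [PreprocessConfig-class]
#' @export
preprocessConfig <- function(targetSize = 30L, sigma = 1, radius = 2L,
                             augment = FALSE,
                             flags = c(rescale = FALSE, zoom = TRUE,
                                       horizontal_flip = TRUE,
                                       vertical_flip = TRUE,
                                       sharpness = TRUE),
                             zoomRange = 0.1, seed = 42L) {
  new("PreprocessConfig", targetSize = as.integer(targetSize),
      filter = gaussianFilterSpec(sigma, radius),
      augment = isTRUE(augment), flags = flags, zoomRange = zoomRange,
      fillMode = "nearest", seed = as.integer(seed))
}

#' Horizontal / vertical flips of an image matrix
#'
#' `flipHorizontal` reverses columns (mirror about the vertical axis);
#' `flipVertical` reverses rows.
#'
#' @param image numeric matrix
#' @return flipped matrix
#' @export
flipHorizontal <- function(image) image[, rev(seq_len(ncol(image))),
                                        drop = FALSE]

#' @rdname flipHorizontal
#' @export
flipVertical <- function(image) image[rev(seq_len(nrow(image))), ,
                                      drop = FALSE]

# one stochastic augmentation pass over a single standardized image;
# consumes the current RNG stream
augmentOne <- function(im, flags, zoomRange) {
  if (isTRUE(flags[["horizontal_flip"]]) && stats::runif(1L) < 0.5)
    im <- flipHorizontal(im)
  if (isTRUE(flags[["vertical_flip"]]) && stats::runif(1L) < 0.5)
    im <- flipVertical(im)
  if (isTRUE(flags[["zoom"]]) && zoomRange > 0) {
    s <- nrow(im)
    z <- stats::runif(1L, 0, zoomRange)
    crop <- max(2L, round(s * (1 - z)))
    off <- (s - crop) %/% 2L
    im <- bilinearResize(im[(off + 1L):(off + crop),
                            (off + 1L):(off + crop), drop = FALSE], s, s)
  }
  if (isTRUE(flags[["sharpness"]])) {
    alpha <- stats::runif(1L, 0.1, 0.5)
    blur <- denoiseImage(im, gaussianFilterSpec(1, 1L))
    im <- im + alpha * (im - blur)
  }
  if (isTRUE(flags[["rescale"]])) im <- im * stats::runif(1L, 0.9, 1.1)
  im[im < 0] <- 0
  im[im > 1] <- 1
  im
}

#' Seeded augmentation of a preprocessed image stack
#'
#' Returns the original images plus one augmented copy per original,
#' produced by a single seeded pass combining the enabled transforms
#' (random flips, centre zoom-in with bilinear resampling, sharpness
#' boost, intensity rescale).  Labels are preserved.  With every flag
#' disabled the input is returned unchanged.
#'
#' @param stack an [ImageStack-class] of standardized images
#' @param config a [PreprocessConfig-class]
#' @return an [ImageStack-class]
#' @export
augmentImages <- function(stack, config = preprocessConfig(augment = TRUE)) {
  stopifnot(is(stack, "ImageStack"), is(config, "PreprocessConfig"))
  validObject(config)
  if (!any(config@flags)) return(stack)
  x <- stack@x
  n <- dim(x)[1L]; s <- dim(x)[2L]
  out <- array(0, dim = c(2L * n, s, s))
  out[seq_len(n), , ] <- x
  withSeed(config@seed, {
    for (i in seq_len(n))
      out[n + i, , ] <- augmentOne(x[i, , ], config@flags,
                                   config@zoomRange)
  })
  new("ImageStack", x = out, labels = c(stack@labels, stack@labels),
      classNames = stack@classNames)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: Gaussian denoising, standardisation (grayscale +
#' min-max normalisation + bilinear resize) and, when enabled in the
#' configuration, one seeded augmentation pass.  With augmentation off
#' the output count equals the input count.
#'
#' @param dataset an [ImageSet-class]
#' @param config a [PreprocessConfig-class]
#' @return an [ImageStack-class] of `targetSize x targetSize` images in
#'   `[0, 1]`
#' @export
preprocessPipeline <- function(dataset, config = preprocessConfig()) {
  stopifnot(is(dataset, "ImageSet"), is(config, "PreprocessConfig"))
  validObject(config)
  n <- length(dataset@images)
  s <- config@targetSize
  x <- array(0, dim = c(n, s, s))
  for (i in seq_len(n)) {
    im <- denoiseImage(dataset@images[[i]], config@filter)
    x[i, , ] <- standardizeImage(im, s)
  }
  stack <- new("ImageStack", x = x, labels = dataset@labels,
               classNames = dataset@classNames)
  if (config@augment) stack <- augmentImages(stack, config)
  stack
}
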