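#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib graphTumorNet, .registration = TRUE
NULL

#' Canonical class names of the four-way tumor classification
#'
#' The four classes recognised by the workflow, in sorted order.  Class
#' ids are the 0-based index of a class name in this vector, so
#' `glioma_tumor` = 0, `meningioma_tumor` = 1, `no_tumor` = 2 and
#' `pituitary_tumor` = 3.
#'
#' @export
tumorClasses <- function() {
  c("glioma_tumor", "meningioma_tumor", "no_tumor", "pituitary_tumor")
}

#' ImageSet: a labelled collection of images
#'
#' Container for a set of grayscale (matrix) or colour (3-d array)
#' images together with their 0-based class labels, the class-name
#' dictionary, per-image source identifiers (file path or phantom tag)
#' and the split they belong to (`"training"` or `"testing"`).
#'
#' @slot images list of numeric matrices (grayscale) or
#'   height x width x 3 arrays (colour)
#' @slot labels integer vector of class ids in `0:(nClasses-1)`
#' @slot classNames character vector of class names, sorted; a label is
#'   the 0-based index into this vector
#' @slot sourceIds character vector, one opaque id per image
#' @slot split length-1 character, `"training"` or `"testing"`
#' @export
setClass("ImageSet",
         representation(images = "list", labels = "integer",
                        classNames = "character", sourceIds = "character",
                        split = "character"))

setValidity("ImageSet", function(object) {
  n <- length(object@images)
  if (length(object@labels) != n || length(object@sourceIds) != n)
    return("images, labels and sourceIds must have equal length")
  if (length(object@split) != 1L ||
      !object@split %in% c("training", "testing"))
    return("split must be 'training' or 'testing'")
  if (n > 0L) {
    if (any(object@labels < 0L) ||
        any(object@labels >= length(object@classNames)))
      return("labels must be 0-based indices into classNames")
    ok <- vapply(object@images, function(im) {
      is.numeric(im) && length(im) > 0L && all(is.finite(im))
    }, logical(1L))
    if (!all(ok)) return("every image must be a non-empty finite array")
  }
  TRUE
})

#' ImageStack: a preprocessed, uniformly sized image batch
#'
#' The dense output of the preprocessing pipeline: an `n x s x s` array
#' of grayscale intensities in `[0, 1]` plus the 0-based labels.
#'
#' @slot x numeric array, `n x s x s`
#' @slot labels integer vector of class ids
#' @slot classNames character vector of class names
#' @export
setClass("ImageStack",
         representation(x = "array", labels = "integer",
                        classNames = "character"))

setValidity("ImageStack", function(object) {
  d <- dim(object@x)
  if (length(d) != 3L) return("x must be an n x s x s array")
  if (d[2] != d[3]) return("images must be square")
  if (d[1] != length(object@labels))
    return("number of images must match number of labels")
  if (length(object@x) && !all(is.finite(object@x)))
    return("pixel values must be finite")
  TRUE
})

#' AdjacencyKernel: a pre-computed weighted kernel matrix
#'
#' An `n x n` matrix of weights in `[0, 1]` that is superposed
#' (element-wise) on every image before graph convolution.  In `"iid"`
#' mode the entries are independent draws from the named distribution
#' (standard normal, uniform(0,1) or log-normal(0,1)), min-max rescaled
#' to `[0, 1]`; in `"radial"` mode (Gaussian family only) entry `(i, j)`
#' is `exp(-d^2 / (2 s^2))` with `d` the Euclidean distance to the
#' matrix centre and `s = n / 4`.
#'
#' @slot family `"gaussian"`, `"uniform"` or `"lognormal"`
#' @slot mode `"iid"` or `"radial"`
#' @slot n integer image side
#' @slot entries numeric `n x n` matrix in `[0, 1]`
#' @slot seed integer seed the entries were drawn with
#' @export
setClass("AdjacencyKernel",
         representation(family = "character", mode = "character",
                        n = "integer", entries = "matrix",
                        seed = "integer"))

setValidity("AdjacencyKernel", function(object) {
  if (!object@family %in% c("gaussian", "uniform", "lognormal"))
    return("family must be gaussian, uniform or lognormal")
  if (!object@mode %in% c("iid", "radial"))
    return("mode must be iid or radial")
  if (!identical(dim(object@entries), c(object@n, object@n)))
    return("entries must be an n x n matrix")
  if (any(object@entries < 0) || any(object@entries > 1))
    return("entries must lie in [0, 1]")
  TRUE
})

#' PixelLattice: lattice connectivity over the pixels of a square image
#'
#' Describes the binary pixel graph of an `n x n` image: nodes are
#' pixels and edges connect 4- or 8-neighbouring lattice cells.  The
#' full `N x N` binary adjacency matrix (`N = n^2`, symmetric, zero
#' diagonal) is materialised on demand by [adjacencyMatrix()].
#'
#' @slot n integer image side
#' @slot connectivity integer, 4 or 8
#' @export
setClass("PixelLattice",
         representation(n = "integer", connectivity = "integer"))

setValidity("PixelLattice", function(object) {
  if (object@n < 2L) return("n must be at least 2")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  TRUE
})

#' GraphImage: node features on the pixel lattice
#'
#' Holds the node-feature matrix H of one image viewed as a graph,
#' together with the number of neighbour-averaging hops already applied.
#'
#' @slot features numeric `n x n` matrix of node features
#' @slot hopsApplied integer, number of graph-convolution rounds applied
#' @export
setClass("GraphImage",
         representation(features = "matrix", hopsApplied = "integer"))

setValidity("GraphImage", function(object) {
  if (!all(is.finite(object@features))) return("features must be finite")
  if (object@hopsApplied < 0L) return("hopsApplied must be >= 0")
  TRUE
})

#' LayerSpec: one parameterised layer of a network architecture
#'
#' @slot kind `"conv"`, `"batchnorm"`, `"maxpool"`, `"dropout"`,
#'   `"flatten"` or `"dense"`
#' @slot params named list of kind-specific parameters (conv:
#'   `out_channels`, `kernel_size`, `activation`; maxpool: `window`;
#'   dropout: `rate`; dense: `units`, `activation`)
#' @export
setClass("LayerSpec", representation(kind = "character", params = "list"))

setValidity("LayerSpec", function(object) {
  kinds <- c("conv", "batchnorm", "maxpool", "dropout", "flatten", "dense")
  if (!object@kind %in% kinds)
    return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
  p <- object@params
  ok <- switch(object@kind,
    conv = is.numeric(p$out_channels) && p$out_channels >= 1 &&
      is.numeric(p$kernel_size) && p$kernel_size %% 2 == 1 &&
      is.character(p$activation),
    maxpool = is.numeric(p$window) && p$window >= 2,
    dropout = is.numeric(p$rate) && p$rate >= 0 && p$rate < 1,
    dense = is.numeric(p$units) && p$units >= 1 &&
      is.character(p$activation),
    TRUE)
  if (!isTRUE(ok)) return(sprintf("invalid params for kind '%s'",
                                  object@kind))
  TRUE
})

#' ArchitectureSpec: an ordered layer list defining a network variant
#'
#' The five comparable variants: Net-0 and Net-1 are 15-layer baseline
#' CNNs without batch normalisation or dropout (Net-0 on raw input,
#' Net-1 on graph-processed input with a Gaussian adjacency kernel);
#' Net-2, Net-3 and Net-4 are 26-layer networks with batch
#' normalisation and exactly two dropout layers, fed with
#' graph-processed input under Gaussian, uniform and log-normal
#' adjacency kernels respectively.
#'
#' @slot variant `"Net-0"` .. `"Net-4"`
#' @slot layers ordered list of [LayerSpec-class] objects
#' @slot inputMode `"raw"` or `"graph"`
#' @slot kernelFamily `"none"`, `"gaussian"`, `"uniform"` or
#'   `"lognormal"`
#' @export
setClass("ArchitectureSpec",
         representation(variant = "character", layers = "list",
                        inputMode = "character", kernelFamily = "character"))

setValidity("ArchitectureSpec", function(object) {
  v <- object@variant
  if (!v %in% paste0("Net-", 0:4)) return("unknown variant")
  kinds <- vapply(object@layers, function(l) l@kind, character(1L))
  nlay <- length(kinds)
  nbn <- sum(kinds == "batchnorm")
  ndo <- sum(kinds == "dropout")
  if (v %in% c("Net-0", "Net-1")) {
    if (nlay != 15L) return("Net-0/Net-1 must have exactly 15 layers")
    if (nbn > 0L || ndo > 0L)
      return("Net-0/Net-1 must contain no batchnorm or dropout")
  } else {
    if (nlay != 26L) return("Net-2/3/4 must have exactly 26 layers")
    if (ndo != 2L) return("Net-2/3/4 must contain exactly 2 dropout layers")
  }
  if (v == "Net-0" && object@inputMode != "raw")
    return("Net-0 must have raw input mode")
  expectedFam <- c("Net-0" = "none", "Net-1" = "gaussian",
                   "Net-2" = "gaussian", "Net-3" = "uniform",
                   "Net-4" = "lognormal")
  if (object@kernelFamily != expectedFam[[v]])
    return(sprintf("%s must have kernel family '%s'", v, expectedFam[[v]]))
  last <- object@layers[[nlay]]
  if (last@kind != "dense" || last@params$units != 4L ||
      last@params$activation != "softmax")
    return("final layer must be a 4-unit dense softmax")
  TRUE
})

#' TrainedNet: a fitted network with its history
#'
#' @slot spec the [ArchitectureSpec-class] that was trained
#' @slot weights list of per-layer weight matrices (engine layout)
#' @slot classNames character vector of class names
#' @slot history data.frame with per-epoch `loss`, `accuracy`,
#'   `val_loss`, `val_accuracy`
#' @slot inputSize integer side length of the training images
#' @slot config list, the training configuration used
#' @export
setClass("TrainedNet",
         representation(spec = "ArchitectureSpec", weights = "list",
                        classNames = "character", history = "data.frame",
                        inputSize = "integer", config = "list"))

#' MetricsReport: per-class precision/recall and overall accuracies
#'
#' Field naming follows the report notation a1.1--a4: `a1.x` is the
#' precision for class `x-1`, `a2.x` the recall for class `x-1`, `a3`
#' the testing accuracy (confusion-matrix trace over total) and `a4`
#' the average testing accuracy (macro-averaged recall by default).
#'
#' @slot precision numeric(4), one-vs-rest precision per class
#' @slot recall numeric(4), one-vs-rest recall per class
#' @slot accuracy length-1 numeric, overall accuracy (a3)
#' @slot avgAccuracy length-1 numeric, average testing accuracy (a4)
#' @slot a4Mode `"macro_recall"` or `"micro_accuracy"`
#' @export
setClass("MetricsReport",
         representation(precision = "numeric", recall = "numeric",
                        accuracy = "numeric", avgAccuracy = "numeric",
                        a4Mode = "character"))

setValidity("MetricsReport", function(object) {
  vals <- c(object@precision, object@recall, object@accuracy,
            object@avgAccuracy)
  if (length(object@precision) != 4L || length(object@recall) != 4L)
    return("precision and recall must have length 4")
  if (any(vals < 0) || any(vals > 1))
    return("all metrics must lie in [0, 1]")
  TRUE
})

#' DatasetManifest: per-class image counts for one split
#'
#' @slot split `"training"` or `"testing"`
#' @slot counts named integer vector, images per class
#' @slot total integer, sum of counts
#' @slot seed integer seed for generated datasets, `NA` for loaded ones
#' @export
setClass("DatasetManifest",
         representation(split = "character", counts = "integer",
                        total = "integer", seed = "integer"))

setValidity("DatasetManifest", function(object) {
  if (sum(object@counts) != object@total)
    return("total must equal the sum of counts")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})

#' PhantomConfig: parameters of the synthetic phantom generator
#'
#' @slot nPerClass integer >= 0, images generated per class
#' @slot imageSize integer >= 8, square image side (default 30)
#' @slot noiseSigma numeric >= 0, std of the additive Gaussian noise on
#'   the `[0, 1]` intensity scale
#' @slot lesionContrast numeric in (0, 1], intensity added by a lesion
#' @slot seed integer seed
#' @export
setClass("PhantomConfig",
         representation(nPerClass = "integer", imageSize = "integer",
                        noiseSigma = "numeric", lesionContrast = "numeric",
                        seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (object@nPerClass < 0L) return("nPerClass must be >= 0")
  if (object@imageSize < 8L) return("imageSize must be >= 8")
  if (!is.finite(object@noiseSigma) || object@noiseSigma < 0)
    return("noiseSigma must be finite and >= 0")
  if (!is.finite(object@lesionContrast) || object@lesionContrast <= 0 ||
      object@lesionContrast > 1)
    return("lesionContrast must lie in (0, 1]")
  TRUE
})

#' Construct a PhantomConfig
#'
#' @param nPerClass images per class
#' @param imageSize square image side
#' @param noiseSigma std of additive Gaussian noise ([0, 1] scale)
#' @param lesionContrast lesion intensity increment, in (0, 1]
#' @param seed integer seed
#' @return a [PhantomConfig-class] object
#' @export
phantomConfig <- function(nPerClass = 50L, imageSize = 30L,
                          noiseSigma = 0.05, lesionContrast = 0.5,
                          seed = 1L) {
  new("PhantomConfig", nPerClass = as.integer(nPerClass),
      imageSize = as.integer(imageSize), noiseSigma = noiseSigma,
      lesionContrast = lesionContrast, seed = as.integer(seed))
}
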