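#' @rdname ImageSet-class
#' @param x an object
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname ImageSet-class
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @rdname ImageSet-class
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname ImageSet-class
#' @export
setGeneric("imageSplit", function(x) standardGeneric("imageSplit"))

#' @rdname ImageSet-class
#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))

#' @rdname ImageStack-class
#' @param x an object
#' @export
setGeneric("stackArray", function(x) standardGeneric("stackArray"))

#' @rdname AdjacencyKernel-class
#' @param x an object
#' @export
setGeneric("kernelEntries", function(x) standardGeneric("kernelEntries"))

#' @rdname AdjacencyKernel-class
#' @export
setGeneric("kernelFamily", function(x) standardGeneric("kernelFamily"))

#' @rdname AdjacencyKernel-class
#' @export
setGeneric("kernelMode", function(x) standardGeneric("kernelMode"))

#' @rdname AdjacencyKernel-class
#' @export
setGeneric("kernelSeed", function(x) standardGeneric("kernelSeed"))

#' Binary adjacency matrix of a pixel lattice
#'
#' Materialises the `N x N` (`N = n^2`) sparse binary adjacency matrix
#' of the lattice, with nodes indexed column-major over the image grid.
#'
#' @param x a [PixelLattice-class]
#' @return a symmetric sparse `Matrix::sparseMatrix` with zero diagonal
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname GraphImage-class
#' @param x an object
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname GraphImage-class
#' @export
setGeneric("hopsApplied", function(x) standardGeneric("hopsApplied"))

#' @rdname ArchitectureSpec-class
#' @param x an object
#' @export
setGeneric("networkLayers", function(x) standardGeneric("networkLayers"))

#' @rdname ArchitectureSpec-class
#' @export
setGeneric("variantName", function(x) standardGeneric("variantName"))

#' @rdname ArchitectureSpec-class
#' @export
setGeneric("inputMode", function(x) standardGeneric("inputMode"))

#' Total trainable-parameter count of an architecture
#'
#' Counts the weights and biases of the convolutional and dense layers
#' plus the scale/shift parameters of each batch-normalisation layer for
#' a given square grayscale input size.  The count is a deterministic
#' function of the architecture.
#'
#' @param x an [ArchitectureSpec-class]
#' @param inputSize integer square input side (default 30)
#' @return integer parameter count
#' @export
setGeneric("parameterCount",
           function(x, inputSize = 30L) standardGeneric("parameterCount"))

#' @rdname TrainedNet-class
#' @param x an object
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname MetricsReport-class
#' @param x an object
#' @export
setGeneric("metricsAsList", function(x) standardGeneric("metricsAsList"))
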