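# Accessors and show methods for the package's S4 classes.

#' @rdname ImageSet-class
#' @export
setMethod("images", "ImageSet", function(x) x@images)

#' @rdname ImageSet-class
#' @export
setMethod("imageLabels", "ImageSet", function(x) x@labels)

#' @rdname ImageSet-class
#' @export
setMethod("classNames", "ImageSet", function(x) x@classNames)

#' @rdname ImageSet-class
#' @export
setMethod("imageSplit", "ImageSet", function(x) x@split)

#' @rdname ImageSet-class
#' @export
setMethod("sourceIds", "ImageSet", function(x) x@sourceIds)

#' @rdname ImageSet-class
#' @export
setMethod("length", "ImageSet", function(x) length(x@images))

setMethod("show", "ImageSet", function(object) {
  cat(sprintf("ImageSet with %d image(s) [%s split]\n",
              length(object@images), object@split))
  if (length(object@images)) {
    tab <- table(factor(object@classNames[object@labels + 1L],
                        levels = object@classNames))
    for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
  }
})

#' @rdname ImageStack-class
#' @export
setMethod("stackArray", "ImageStack", function(x) x@x)

#' @rdname ImageStack-class
#' @export
setMethod("imageLabels", "ImageStack", function(x) x@labels)

#' @rdname ImageStack-class
#' @export
setMethod("classNames", "ImageStack", function(x) x@classNames)

#' @rdname ImageStack-class
#' @export
setMethod("length", "ImageStack", function(x) dim(x@x)[1L])

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@x)
  cat(sprintf("ImageStack: %d image(s) of %d x %d, range [%.3f, %.3f]\n",
              d[1], d[2], d[3],
              if (length(object@x)) min(object@x) else NA_real_,
              if (length(object@x)) max(object@x) else NA_real_))
})

#' @rdname AdjacencyKernel-class
#' @export
setMethod("kernelEntries", "AdjacencyKernel", function(x) x@entries)

#' @rdname AdjacencyKernel-class
#' @export
setMethod("kernelFamily", "AdjacencyKernel", function(x) x@family)

#' @rdname AdjacencyKernel-class
#' @export
setMethod("kernelMode", "AdjacencyKernel", function(x) x@mode)

#' @rdname AdjacencyKernel-class
#' @export
setMethod("kernelSeed", "AdjacencyKernel", function(x) x@seed)

setMethod("show", "AdjacencyKernel", function(object) {
  cat(sprintf("AdjacencyKernel: %s (%s), %d x %d, seed %d\n",
              object@family, object@mode, object@n, object@n, object@seed))
  cat(sprintf("  entries in [%.4f, %.4f]\n", min(object@entries),
              max(object@entries)))
})

setMethod("show", "PixelLattice", function(object) {
  cat(sprintf("PixelLattice: %d x %d grid (%d nodes), %d-connectivity\n",
              object@n, object@n, object@n^2, object@connectivity))
})

#' @rdname GraphImage-class
#' @export
setMethod("nodeFeatures", "GraphImage", function(x) x@features)

#' @rdname GraphImage-class
#' @export
setMethod("hopsApplied", "GraphImage", function(x) x@hopsApplied)

setMethod("show", "GraphImage", function(object) {
  d <- dim(object@features)
  cat(sprintf("GraphImage: %d x %d node features, %d hop(s) applied\n",
              d[1], d[2], object@hopsApplied))
})

#' @rdname ArchitectureSpec-class
#' @export
setMethod("networkLayers", "ArchitectureSpec", function(x) x@layers)

#' @rdname ArchitectureSpec-class
#' @export
setMethod("variantName", "ArchitectureSpec", function(x) x@variant)

#' @rdname ArchitectureSpec-class
#' @export
setMethod("inputMode", "ArchitectureSpec", function(x) x@inputMode)

#' @rdname ArchitectureSpec-class
#' @export
setMethod("length", "ArchitectureSpec", function(x) length(x@layers))

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec %s: %d layers, %s input, kernel family %s\n",
              object@variant, length(object@layers), object@inputMode,
              object@kernelFamily))
  for (l in object@layers) {
    p <- l@params
    desc <- switch(l@kind,
      conv = sprintf("conv(%d, %dx%d, %s)", p$out_channels, p$kernel_size,
                     p$kernel_size, p$activation),
      maxpool = sprintf("maxpool(%d)", p$window),
      dropout = sprintf("dropout(%.2f)", p$rate),
      dense = sprintf("dense(%d, %s)", p$units, p$activation),
      l@kind)
    cat("  -", desc, "\n")
  }
})

#' @rdname TrainedNet-class
#' @export
setMethod("trainingHistory", "TrainedNet", function(x) x@history)

setMethod("show", "TrainedNet", function(object) {
  h <- object@history
  cat(sprintf("TrainedNet (%s), %d epoch(s)\n", object@spec@variant,
              nrow(h)))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final: loss %.4f, accuracy %.4f, val_loss %.4f, val_accuracy %.4f\n",
                last$loss, last$accuracy, last$val_loss, last$val_accuracy))
  }
})

#' @rdname MetricsReport-class
#' @export
setMethod("metricsAsList", "MetricsReport", function(x) {
  out <- as.list(c(x@precision, x@recall, x@accuracy, x@avgAccuracy))
  names(out) <- c(paste0("a1_", 1:4), paste0("a2_", 1:4), "a3", "a4")
  out
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  for (i in 1:4)
    cat(sprintf("  a1.%d (precision class %d) %.4f   a2.%d (recall class %d) %.4f\n",
                i, i - 1L, object@precision[i], i, i - 1L,
                object@recall[i]))
  cat(sprintf("  a3 (testing accuracy)        %.4f\n", object@accuracy))
  cat(sprintf("  a4 (average testing accuracy) %.4f [%s]\n",
              object@avgAccuracy, object@a4Mode))
})

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest [%s split], total %d\n", object@split,
              object@total))
  for (nm in names(object@counts))
    cat(sprintf("  %-18s %d\n", nm, object@counts[[nm]]))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %d/class at %dx%d, noise sd %.3f, contrast %.2f, seed %d\n",
    object@nPerClass, object@imageSize, object@imageSize,
    object@noiseSigma, object@lesionContrast, object@seed))
})
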