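# The five comparable network variants and their training/prediction
# interface over the compiled CNN engine.

#' Construct a LayerSpec
#'
#' @param kind layer kind (`"conv"`, `"batchnorm"`, `"maxpool"`,
#'   `"dropout"`, `"flatten"`, `"dense"`)
#' @param ... kind-specific parameters (see [LayerSpec-class])
#' @return a [LayerSpec-class]
#' @export
layerSpec <- function(kind, ...) new("LayerSpec", kind = kind,
                                     params = list(...))

convL <- function(out) layerSpec("conv", out_channels = as.integer(out),
                                 kernel_size = 3L, activation = "relu")
bnL <- function() layerSpec("batchnorm")
poolL <- function() layerSpec("maxpool", window = 2L)
dropL <- function(rate) layerSpec("dropout", rate = rate)

#' Build the canonical architecture of a network variant
#'
#' The 15-layer baseline (Net-0/Net-1) is a sequential CNN for 30 x 30
#' grayscale input: four conv-conv-pool blocks with 32/64/128/256
#' channels of 3 x 3 relu convolutions (same padding; spatial sizes
#' 30 -> 15 -> 7 -> 3 -> 1), then flatten, dense(128, relu) and
#' dense(4, softmax) -- 8 conv + 4 pool + flatten + 2 dense = 15
#' layers, with no batch normalisation or dropout.  The 26-layer
#' networks (Net-2/3/4) add a batchnorm after each of the 8
#' convolutions and after the dense(128), plus two dropout layers
#' (rate 0.25 after the last pool, rate 0.5 after the dense batchnorm):
#' 15 + 8 + 1 + 2 = 26.  Activations are attributes of the conv/dense
#' layers, not separate layers.
#'
#' @param variant `"Net-0"`, `"Net-1"`, `"Net-2"`, `"Net-3"` or
#'   `"Net-4"`
#' @return an [ArchitectureSpec-class]
#' @export
buildArchitecture <- function(variant = c("Net-0", "Net-1", "Net-2",
                                          "Net-3", "Net-4")) {
  variant <- match.arg(variant)
  deep <- variant %in% c("Net-2", "Net-3", "Net-4")
  channels <- c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L)
  layers <- list()
  for (blk in 1:4) {
    for (j in 1:2) {
      layers <- c(layers, list(convL(channels[2 * (blk - 1) + j])))
      if (deep) layers <- c(layers, list(bnL()))
    }
    layers <- c(layers, list(poolL()))
  }
  if (deep) layers <- c(layers, list(dropL(0.25)))
  layers <- c(layers, list(layerSpec("flatten"),
                           layerSpec("dense", units = 128L,
                                     activation = "relu")))
  if (deep) layers <- c(layers, list(bnL(), dropL(0.5)))
  layers <- c(layers, list(layerSpec("dense", units = 4L,
                                     activation = "softmax")))
  fam <- c("Net-0" = "none", "Net-1" = "gaussian", "Net-2" = "gaussian",
           "Net-3" = "uniform", "Net-4" = "lognormal")[[variant]]
  new("ArchitectureSpec", variant = variant, layers = layers,
      inputMode = if (variant == "Net-0") "raw" else "graph",
      kernelFamily = fam)
}

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "ArchitectureSpec", function(x, inputSize = 30L) {
  h <- as.integer(inputSize); w <- h; c <- 1L
  total <- 0
  for (l in x@layers) {
    p <- l@params
    if (l@kind == "conv") {
      total <- total + (p$kernel_size^2 * c + 1L) * p$out_channels
      c <- p$out_channels
    } else if (l@kind == "batchnorm") {
      total <- total + 2L * c
    } else if (l@kind == "maxpool") {
      h <- h %/% p$window; w <- w %/% p$window
    } else if (l@kind == "flatten") {
      c <- h * w * c; h <- 1L; w <- 1L
    } else if (l@kind == "dense") {
      total <- total + (c + 1L) * p$units
      c <- p$units
    }
  }
  as.integer(total)
})

#' Export an architecture as JSON
#'
#' @param spec an [ArchitectureSpec-class]
#' @param path optional file; when `NULL` the JSON string is returned
#' @return the JSON string, invisibly when written to a file
#' @export
architectureToJSON <- function(spec, path = NULL) {
  stopifnot(is(spec, "ArchitectureSpec"))
  obj <- list(variant = spec@variant, input_mode = spec@inputMode,
              kernel_family = spec@kernelFamily,
              layers = lapply(spec@layers, function(l)
                c(list(kind = l@kind), l@params)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' TrainConfig: training hyperparameters
#'
#' @slot epochs integer >= 1
#' @slot batchSize integer >= 1
#' @slot learningRate positive numeric
#' @slot optimizer `"adam"` or `"sgd"`
#' @slot loss `"categorical_crossentropy"`
#' @slot seed integer seed governing weight initialisation, shuffling
#'   and dropout masks
#' @slot deterministic logical; the engine is single-threaded and fully
#'   seeded, so seeded runs reproduce identical weights and history
#' @export
setClass("TrainConfig",
         representation(epochs = "integer", batchSize = "integer",
                        learningRate = "numeric", optimizer = "character",
                        loss = "character", seed = "integer",
                        deterministic = "logical"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (!is.finite(object@learningRate) || object@learningRate <= 0)
    return("learningRate must be positive")
  if (!object@optimizer %in% c("adam", "sgd"))
    return("optimizer must be 'adam' or 'sgd'")
  if (object@loss != "categorical_crossentropy")
    return("loss must be 'categorical_crossentropy'")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param epochs training epochs
#' @param batchSize minibatch size
#' @param learningRate optimizer step size
#' @param optimizer `"adam"` or `"sgd"`
#' @param seed integer seed
#' @param deterministic logical, see [TrainConfig-class]
#' @return a [TrainConfig-class]
#' @export
trainConfig <- function(epochs = 50L, batchSize = 32L,
                        learningRate = 1e-3, optimizer = "adam",
                        seed = 42L, deterministic = TRUE) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      optimizer = optimizer, loss = "categorical_crossentropy",
      seed = as.integer(seed), deterministic = deterministic)
}

# LayerSpec list -> plain list form consumed by the compiled engine
engineLayers <- function(spec) {
  lapply(spec@layers, function(l) c(list(kind = l@kind), l@params))
}

# stratified split of 0-based labels; returns validation indices
stratifiedValIdx <- function(labels, fraction, seed) {
  withSeed(seed, {
    idx <- integer()
    for (cl in sort(unique(labels))) {
      cls <- which(labels == cl)
      nVal <- max(1L, round(fraction * length(cls)))
      idx <- c(idx, sample(cls, min(nVal, length(cls))))
    }
    sort(idx)
  })
}

#' Train a network variant
#'
#' Minimises categorical cross-entropy with the configured optimizer.
#' When no validation stack is given, a seeded stratified 10% slice of
#' the training data is held out for the per-epoch validation series.
#' For graph-mode variants the stack is expected to have already passed
#' [applyGraphStage()].
#'
#' @param spec an [ArchitectureSpec-class]
#' @param trainStack an [ImageStack-class] of training images
#' @param valStack optional [ImageStack-class] used for validation
#' @param config a [TrainConfig-class]
#' @return a [TrainedNet-class] whose history has one row per epoch
#' @export
trainNetwork <- function(spec, trainStack, valStack = NULL,
                         config = trainConfig()) {
  stopifnot(is(spec, "ArchitectureSpec"), is(trainStack, "ImageStack"),
            is(config, "TrainConfig"))
  validObject(spec); validObject(config)
  x <- trainStack@x
  y <- trainStack@labels
  if (any(y < 0L) || any(y > 3L))
    stop("labels must lie in 0..3")
  if (dim(x)[1L] == 0L) stop("training stack is empty")
  if (is.null(valStack)) {
    vi <- stratifiedValIdx(y, 0.1, config@seed + 7L)
    valStack <- new("ImageStack", x = x[vi, , , drop = FALSE],
                    labels = y[vi], classNames = trainStack@classNames)
    keep <- setdiff(seq_along(y), vi)
    x <- x[keep, , , drop = FALSE]
    y <- y[keep]
  }
  s <- dim(x)[2L]
  layers <- engineLayers(spec)
  w0 <- cnn_init_weights(layers, s, s, 1L, config@seed)
  fit <- cnn_train(layers, w0, aperm(x, c(2L, 3L, 1L)), y,
                   aperm(valStack@x, c(2L, 3L, 1L)), valStack@labels,
                   config@epochs, config@batchSize, config@learningRate,
                   config@optimizer, config@seed)
  hist <- data.frame(epoch = seq_len(config@epochs), loss = fit$loss,
                     accuracy = fit$accuracy, val_loss = fit$val_loss,
                     val_accuracy = fit$val_accuracy)
  new("TrainedNet", spec = spec, weights = fit$weights,
      classNames = trainStack@classNames, history = hist,
      inputSize = as.integer(s),
      config = list(epochs = config@epochs, batchSize = config@batchSize,
                    learningRate = config@learningRate,
                    optimizer = config@optimizer, seed = config@seed,
                    deterministic = config@deterministic))
}

#' Predict class probabilities and labels
#'
#' Probability rows are non-negative and sum to 1 over the four
#' classes; the predicted label is the argmax, ties broken towards the
#' lowest class id.  Inputs must have been preprocessed (and, for
#' graph-mode variants, graph-transformed) identically to the training
#' data.
#'
#' @param object a [TrainedNet-class]
#' @param newdata an [ImageStack-class] or `n x s x s` array
#' @param ... unused
#' @return a list with elements `probabilities` (`n x 4` matrix) and
#'   `labels` (integer vector of 0-based class ids)
#' @export
setMethod("predict", "TrainedNet", function(object, newdata, ...) {
  x <- if (is(newdata, "ImageStack")) newdata@x else newdata
  if (length(dim(x)) != 3L || dim(x)[2L] != object@inputSize ||
      dim(x)[3L] != object@inputSize)
    stop("newdata shape does not match the trained input size")
  probs <- cnn_predict_probs(engineLayers(object@spec), object@weights,
                             aperm(x, c(2L, 3L, 1L)), 64L)
  labels <- max.col(probs, ties.method = "first") - 1L
  colnames(probs) <- object@classNames
  list(probabilities = probs, labels = as.integer(labels))
})
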