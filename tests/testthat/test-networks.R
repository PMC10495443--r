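test_that("the five variants satisfy the layer-count law", {
  for (v in c("Net-0", "Net-1")) {
    spec <- buildArchitecture(v)
    kinds <- vapply(networkLayers(spec), function(l) l@kind,
                    character(1L))
    expect_length(kinds, 15L)
    expect_equal(sum(kinds == "batchnorm"), 0L)
    expect_equal(sum(kinds == "dropout"), 0L)
  }
  for (v in c("Net-2", "Net-3", "Net-4")) {
    spec <- buildArchitecture(v)
    kinds <- vapply(networkLayers(spec), function(l) l@kind,
                    character(1L))
    expect_length(kinds, 26L)
    expect_equal(sum(kinds == "dropout"), 2L)
    expect_equal(sum(kinds == "batchnorm"), 9L)
  }
  expect_equal(inputMode(buildArchitecture("Net-0")), "raw")
  expect_equal(buildArchitecture("Net-1")@kernelFamily, "gaussian")
  # Net-2 and Net-3 differ only in kernel family
  n2 <- buildArchitecture("Net-2"); n3 <- buildArchitecture("Net-3")
  expect_identical(networkLayers(n2), networkLayers(n3))
  expect_identical(inputMode(n2), inputMode(n3))
  expect_false(identical(n2@kernelFamily, n3@kernelFamily))
  # final layer is a 4-unit softmax dense
  last <- networkLayers(n2)[[26L]]
  expect_equal(last@kind, "dense")
  expect_equal(last@params$units, 4L)
  expect_equal(last@params$activation, "softmax")
  expect_error(buildArchitecture("Net-9"))
})

test_that("trainable-parameter counts are build-stable integers", {
  for (v in paste0("Net-", 0:4)) {
    c1 <- parameterCount(buildArchitecture(v))
    c2 <- parameterCount(buildArchitecture(v))
    expect_true(is.integer(c1) && c1 > 0L)
    expect_identical(c1, c2)
  }
  # independent hand count for the 15-layer backbone at 30x30 input:
  # conv weights sum_i (9 c_in + 1) c_out + dense (256+1)*128 + (128+1)*4
  convs <- rbind(c(1, 32), c(32, 32), c(32, 64), c(64, 64), c(64, 128),
                 c(128, 128), c(128, 256), c(256, 256))
  hand15 <- sum((9 * convs[, 1] + 1) * convs[, 2]) + 257 * 128 + 129 * 4
  expect_equal(parameterCount(buildArchitecture("Net-0")), hand15)
  # 26-layer adds 2 * (8 conv channels + dense 128) batchnorm params
  hand26 <- hand15 + 2 * (sum(convs[, 2]) + 128)
  expect_equal(parameterCount(buildArchitecture("Net-2")), hand26)
  expect_equal(parameterCount(buildArchitecture("Net-2")),
               parameterCount(buildArchitecture("Net-4")))
})

test_that("analytic gradients match finite differences on a tiny net", {
  layers <- list(
    layerSpec("conv", out_channels = 3L, kernel_size = 3L,
              activation = "relu"),
    layerSpec("batchnorm"),
    layerSpec("maxpool", window = 2L),
    layerSpec("flatten"),
    layerSpec("dense", units = 5L, activation = "relu"),
    layerSpec("batchnorm"),
    layerSpec("dense", units = 4L, activation = "softmax"))
  eng <- lapply(layers, function(l) c(list(kind = l@kind), l@params))
  ns <- asNamespace("graphTumorNet")
  set.seed(10)
  X <- array(runif(8L * 8L * 6L), dim = c(8L, 8L, 6L))
  y <- c(0L, 1L, 2L, 3L, 0L, 1L)
  w <- ns$cnn_init_weights(eng, 8L, 8L, 1L, 123L)
  lg <- ns$cnn_loss_grad(eng, w, X, y)
  expect_true(is.finite(lg$loss))
  worst <- 0
  for (li in seq_along(w)) {
    for (j in seq_along(w[[li]])) {
      if (eng[[li]]$kind == "batchnorm" && j > 2L) next  # running stats
      if (!length(w[[li]][[j]])) next
      for (ii in sample(length(w[[li]][[j]]),
                        min(3L, length(w[[li]][[j]])))) {
        eps <- 1e-6
        wp <- w; wp[[li]][[j]][ii] <- wp[[li]][[j]][ii] + eps
        wm <- w; wm[[li]][[j]][ii] <- wm[[li]][[j]][ii] - eps
        num <- (ns$cnn_loss_only(eng, wp, X, y) -
                  ns$cnn_loss_only(eng, wm, X, y)) / (2 * eps)
        ana <- lg$gradients[[li]][[j]][ii]
        worst <- max(worst, abs(num - ana) /
                       max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

makeTrainStack <- function(nPerClass, seed = 99L, noise = 0.02) {
  ds <- generatePhantomDataset(
    phantomConfig(nPerClass = nPerClass, noiseSigma = noise,
                  seed = seed), "training")
  preprocessPipeline(ds)
}

test_that("training honours its contracts and overfits a small set", {
  stack <- makeTrainStack(10L)
  cfg <- trainConfig(epochs = 3L, batchSize = 16L, seed = 1L)
  net <- trainNetwork(buildArchitecture("Net-0"), stack, config = cfg)
  h <- trainingHistory(net)
  expect_equal(nrow(h), 3L)
  expect_true(all(c("loss", "accuracy", "val_loss", "val_accuracy")
                  %in% names(h)))
  # seeded determinism: identical history and weights across runs
  net2 <- trainNetwork(buildArchitecture("Net-0"), stack, config = cfg)
  expect_identical(trainingHistory(net), trainingHistory(net2))
  expect_identical(net@weights, net2@weights)
  # low-noise overfitting sanity run
  over <- trainNetwork(buildArchitecture("Net-0"), stack,
                       valStack = stack,
                       config = trainConfig(epochs = 30L,
                                            batchSize = 8L, seed = 2L))
  expect_gte(utils::tail(trainingHistory(over)$accuracy, 1L), 0.9)
  # a model overfitted on 8 images reproduces their labels exactly
  small <- makeTrainStack(2L, seed = 3L, noise = 0.01)
  memo <- trainNetwork(buildArchitecture("Net-0"), small,
                       valStack = small,
                       config = trainConfig(epochs = 60L, batchSize = 8L,
                                            seed = 4L))
  expect_identical(predict(memo, small)$labels, imageLabels(small))
  expect_error(trainNetwork(buildArchitecture("Net-0"),
                            new("ImageStack",
                                x = array(0, dim = c(0L, 30L, 30L)),
                                labels = integer(),
                                classNames = tumorClasses())),
               "empty")
})

test_that("predictions are calibrated softmax rows", {
  stack <- makeTrainStack(5L, seed = 12L)
  net <- trainNetwork(buildArchitecture("Net-0"), stack,
                      config = trainConfig(epochs = 2L, seed = 6L))
  p <- predict(net, stack)
  expect_equal(dim(p$probabilities), c(20L, 4L))
  expect_true(all(p$probabilities >= 0))
  expect_true(all(abs(rowSums(p$probabilities) - 1) < 1e-6))
  expect_true(all(p$labels %in% 0:3))
  expect_error(predict(net, array(0, dim = c(2L, 16L, 16L))), "shape")
})

test_that("an all-ones kernel with zero hops degenerates to raw input", {
  stack <- makeTrainStack(3L, seed = 31L)
  staged <- applyGraphStage(stack, onesKernel(30L), connectivity = 4L,
                            hops = 0L)
  expect_identical(stackArray(staged), stackArray(stack))
})
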