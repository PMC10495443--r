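test_that("the confusion matrix tallies and conserves counts", {
  truth <- c(0L, 0L, 1L, 2L, 3L)
  pred <- c(0L, 1L, 1L, 2L, 3L)
  cm <- confusionMatrix(truth, pred)
  expect_equal(diag(cm), c(`0` = 1L, `1` = 1L, `2` = 1L, `3` = 1L))
  expect_equal(cm[1L, 2L], 1L)
  expect_equal(sum(cm), length(truth))
  off <- cm; diag(off) <- 0L
  expect_equal(sum(off), 1L)
  # perfect predictions give a diagonal matrix of class counts
  y <- rep(0:3, times = c(3L, 1L, 4L, 2L))
  cmP <- confusionMatrix(y, y)
  expect_equal(unname(diag(cmP)), c(3L, 1L, 4L, 2L))
  expect_equal(sum(cmP) - sum(diag(cmP)), 0L)
  expect_error(confusionMatrix(0:2, 0:3), "length")
  expect_error(confusionMatrix(c(0L, 4L), c(0L, 1L)), "0..3")
})

test_that("metrics match the worked example and perfect case", {
  y <- rep(0:3, each = 5L)
  perfect <- computeMetrics(confusionMatrix(y, y))
  expect_equal(perfect@precision, rep(1, 4L))
  expect_equal(perfect@recall, rep(1, 4L))
  expect_equal(perfect@accuracy, 1)
  expect_equal(perfect@avgAccuracy, 1)
  # class 0 with TP = 5, FP = 3, FN = 5
  cm <- matrix(0L, 4L, 4L)
  cm[1L, 1L] <- 5L; cm[2L, 1L] <- 3L; cm[1L, 2L] <- 5L
  cm[2L, 2L] <- 4L; cm[3L, 3L] <- 6L; cm[4L, 4L] <- 6L
  rep1 <- computeMetrics(cm)
  expect_equal(rep1@precision[1L], 0.625)
  expect_equal(rep1@recall[1L], 0.5)
  expect_equal(rep1@accuracy, sum(diag(cm)) / sum(cm))
  # report exposes exactly the ten documented fields
  lst <- metricsAsList(rep1)
  expect_named(lst, c("a1_1", "a1_2", "a1_3", "a1_4", "a2_1", "a2_2",
                      "a2_3", "a2_4", "a3", "a4"))
  # zero-denominator classes report 0 with a warning
  cm0 <- matrix(0L, 4L, 4L)
  cm0[1L, 1L] <- 10L
  warns <- testthat::capture_warnings(rep0 <- computeMetrics(cm0))
  expect_true(any(grepl("recall set to 0", warns)))
  expect_equal(rep0@recall[2L], 0)
  expect_error(computeMetrics(matrix(0L, 4L, 4L)), "empty")
})

test_that("metrics equal a per-sample tally oracle on random labels", {
  set.seed(77)
  for (rep in 1:100) {
    truth <- sample(0:3, 200L, replace = TRUE)
    pred <- sample(0:3, 200L, replace = TRUE)
    got <- suppressWarnings(computeMetrics(confusionMatrix(truth, pred)))
    want <- oracleMetrics(truth, pred)
    expect_equal(got@precision, want$precision)
    expect_equal(got@recall, want$recall)
    expect_equal(got@accuracy, want$a3)
    expect_equal(got@avgAccuracy, want$a4)
  }
  # permutation invariance of every metric
  truth <- sample(0:3, 120L, replace = TRUE)
  pred <- sample(0:3, 120L, replace = TRUE)
  perm <- sample(120L)
  a <- suppressWarnings(computeMetrics(confusionMatrix(truth, pred)))
  b <- suppressWarnings(computeMetrics(confusionMatrix(truth[perm],
                                                       pred[perm])))
  expect_identical(metricsAsList(a), metricsAsList(b))
  # a3 is 1 iff the confusion matrix is diagonal
  expect_lt(a@accuracy, 1)
  # micro mode reports a3 as a4
  micro <- suppressWarnings(
    computeMetrics(confusionMatrix(truth, pred), a4Mode = "micro_accuracy"))
  expect_equal(micro@avgAccuracy, micro@accuracy)
})

test_that("the comparison table mirrors the 10-row report layout", {
  set.seed(5)
  mkReport <- function() suppressWarnings(computeMetrics(
    confusionMatrix(sample(0:3, 40L, TRUE), sample(0:3, 40L, TRUE))))
  reports <- stats::setNames(lapply(1:5, function(i) mkReport()),
                             paste0("Net-", 0:4))
  tab <- comparisonTable(reports)
  expect_equal(dim(tab), c(10L, 6L))
  expect_equal(tab$metric, c(paste0("a1.", 1:4), paste0("a2.", 1:4),
                             "a3", "a4"))
  expect_equal(names(tab)[-1L], paste0("Net-", 0:4))
  # a single report yields a 10 x 1 table without error
  tab1 <- comparisonTable(reports["Net-2"])
  expect_equal(dim(tab1), c(10L, 2L))
  # CSV round trip preserves full precision
  csv <- withr::local_tempfile(fileext = ".csv")
  comparisonTable(reports, csvPath = csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  for (nm in names(reports))
    expect_equal(back[[nm]], tab[[nm]], tolerance = 1e-12)
  # rendered view rounds to 2 decimals
  out <- capture.output(print(tab))
  expect_false(any(grepl("[0-9]\\.[0-9]{3,}", out)))
})

test_that("metric reports serialise to JSON and CSV", {
  y <- rep(0:3, each = 6L)
  p <- y; p[c(1L, 8L)] <- c(1L, 2L)
  repA <- computeMetrics(confusionMatrix(y, p))
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  writeMetrics(repA, jsonPath = js, csvPath = cs)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$a3, repA@accuracy)
  expect_equal(back$a1_2, repA@precision[2L])
  csvBack <- utils::read.csv(cs)
  expect_equal(csvBack$value, unlist(metricsAsList(repA)),
               ignore_attr = TRUE)
  cmFile <- withr::local_tempfile(fileext = ".csv")
  writeConfusionCSV(confusionMatrix(y, p), cmFile)
  cmBack <- utils::read.csv(cmFile, row.names = 1L)
  expect_equal(sum(cmBack), length(y))
})
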