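# The metric suite: multiclass confusion matrix, per-class one-vs-rest
# precision/recall, overall and average testing accuracy, and the
# cross-network comparison table.

#' Multiclass confusion matrix
#'
#' Tallies a 4 x 4 count matrix with rows indexed by the true class and
#' columns by the predicted class (0-based class ids 0..3).  Per-class
#' TP/FP/FN/TN follow from the one-vs-rest marginals.
#'
#' @param trueLabels integer vector of true class ids in 0..3
#' @param predictedLabels integer vector of predicted class ids in 0..3
#' @return an integer 4 x 4 matrix with dimnames `true` x `predicted`
#' @export
confusionMatrix <- function(trueLabels, predictedLabels) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  if (length(trueLabels) &&
      (any(trueLabels < 0L) || any(trueLabels > 3L) ||
       any(predictedLabels < 0L) || any(predictedLabels > 3L)))
    stop("labels must lie in 0..3")
  lv <- 0:3
  cm <- table(factor(trueLabels, levels = lv),
              factor(predictedLabels, levels = lv))
  cm <- matrix(as.integer(cm), 4L, 4L,
               dimnames = list(true = as.character(lv),
                               predicted = as.character(lv)))
  cm
}

#' Compute the metric suite from a confusion matrix
#'
#' For every class `c` (one-vs-rest): precision = TP / (TP + FP) and
#' recall = TP / (TP + FN).  Overall accuracy a3 is the matrix trace
#' over the total count (the multiclass form of the binary
#' TP+TN / total definition).  The average testing accuracy a4 is the
#' macro-averaged recall by default (`"macro_recall"`), with
#' `"micro_accuracy"` (= a3) available for comparison.  A class with a
#' zero denominator reports 0 with a warning so tables stay numeric.
#'
#' @param cm a 4 x 4 count matrix from [confusionMatrix()]
#' @param a4Mode `"macro_recall"` or `"micro_accuracy"`
#' @return a [MetricsReport-class]
#' @export
computeMetrics <- function(cm, a4Mode = c("macro_recall",
                                          "micro_accuracy")) {
  a4Mode <- match.arg(a4Mode)
  if (!is.matrix(cm) || !identical(dim(cm), c(4L, 4L)))
    stop("cm must be a 4 x 4 matrix")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  colSum <- colSums(cm)   # TP + FP per predicted class
  rowSum <- rowSums(cm)   # TP + FN per true class
  precision <- recall <- numeric(4L)
  for (i in 1:4) {
    if (colSum[i] == 0) {
      warning(sprintf("class %d has no positive predictions; precision set to 0",
                      i - 1L))
      precision[i] <- 0
    } else precision[i] <- tp[i] / colSum[i]
    if (rowSum[i] == 0) {
      warning(sprintf("class %d has no true samples; recall set to 0",
                      i - 1L))
      recall[i] <- 0
    } else recall[i] <- tp[i] / rowSum[i]
  }
  a3 <- sum(tp) / total
  a4 <- if (a4Mode == "macro_recall") mean(recall) else a3
  new("MetricsReport", precision = precision, recall = recall,
      accuracy = a3, avgAccuracy = a4, a4Mode = a4Mode)
}

#' Cross-network comparison table
#'
#' Assembles the reports into a table with one row per metric (a1.1 ..
#' a1.4, a2.1 .. a2.4, a3, a4) and one column per network variant, in
#' the order the reports are given.  `print`ing rounds to 2 decimals;
#' the optional CSV keeps full precision.
#'
#' @param reports named list of [MetricsReport-class] objects (names
#'   are the variant labels)
#' @param csvPath optional path; when given the full-precision table is
#'   written as CSV
#' @return a data.frame with a `metric` column plus one column per
#'   variant
#' @export
comparisonTable <- function(reports, csvPath = NULL) {
  stopifnot(length(reports) >= 1L)
  if (is.null(names(reports)) || any(!nzchar(names(reports))))
    stop("reports must be a named list (variant labels)")
  metric <- c(paste0("a1.", 1:4), paste0("a2.", 1:4), "a3", "a4")
  tab <- data.frame(metric = metric, stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    r <- reports[[nm]]
    stopifnot(is(r, "MetricsReport"))
    tab[[nm]] <- c(r@precision, r@recall, r@accuracy, r@avgAccuracy)
  }
  if (!is.null(csvPath))
    utils::write.csv(tab, csvPath, row.names = FALSE, quote = FALSE)
  class(tab) <- c("gtnComparison", "data.frame")
  tab
}

#' @export
print.gtnComparison <- function(x, ...) {
  y <- as.data.frame(x)
  for (j in seq(2L, ncol(y))) y[[j]] <- round(y[[j]], 2L)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a MetricsReport to JSON and/or CSV
#'
#' JSON uses the field names `a1_1` .. `a1_4`, `a2_1` .. `a2_4`, `a3`,
#' `a4`; the CSV has columns `metric,value` at full precision.
#'
#' @param report a [MetricsReport-class]
#' @param jsonPath,csvPath optional output paths
#' @return the metric list, invisibly
#' @export
writeMetrics <- function(report, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(report, "MetricsReport"))
  lst <- metricsAsList(report)
  if (!is.null(jsonPath))
    jsonlite::write_json(lst, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath))
    utils::write.csv(data.frame(metric = names(lst),
                                value = unlist(lst)),
                     csvPath, row.names = FALSE, quote = FALSE)
  invisible(lst)
}

#' Write a confusion matrix as CSV
#'
#' @param cm a 4 x 4 count matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
writeConfusionCSV <- function(cm, path) {
  utils::write.csv(as.data.frame.matrix(cm), path, row.names = TRUE,
                   quote = FALSE)
  invisible(path)
}
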