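# Reading class-foldered image datasets and generating synthetic
# phantoms with the statistical structure the method assumes.

#' Error condition for missing or empty data directories
#' @noRd
missingDataError <- function(msg) {
  structure(class = c("gtn_missing_data", "error", "condition"),
            list(message = msg, call = sys.call(-1L)))
}

# evaluate expr under a fixed RNG seed, preserving the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Load a class-foldered image dataset
#'
#' Reads every JPEG/PNG under `<root>/<Split>/<class_name>/` where the
#' class folders are `glioma_tumor`, `meningioma_tumor`, `no_tumor` and
#' `pituitary_tumor`.  Class ids are assigned by sorted class-folder
#' name (glioma = 0, meningioma = 1, no_tumor = 2, pituitary = 3).
#' Files are visited in sorted path order; unreadable files are skipped
#' with a warning; unrecognised class folders are ignored with a
#' warning.  Pixels are returned on the 0--255 intensity scale (colour
#' images as height x width x 3 arrays).
#'
#' @param root dataset root containing `Training/` and/or `Testing/`
#' @param split `"training"` or `"testing"`
#' @return an [ImageSet-class]
#' @export
loadImageFolder <- function(root, split = c("training", "testing")) {
  split <- match.arg(split)
  if (!dir.exists(root))
    stop(missingDataError(sprintf("dataset root '%s' does not exist", root)))
  candidates <- file.path(root, c(tools::toTitleCase(split), split))
  splitDir <- candidates[dir.exists(candidates)][1L]
  if (is.na(splitDir))
    stop(missingDataError(sprintf("no '%s' split directory under '%s'",
                                  split, root)))
  classes <- tumorClasses()
  present <- list.dirs(splitDir, recursive = FALSE, full.names = FALSE)
  extra <- setdiff(present, classes)
  if (length(extra))
    warning(sprintf("ignoring unrecognised class folder(s): %s",
                    paste(extra, collapse = ", ")))
  found <- intersect(classes, present)
  if (!length(found))
    stop(missingDataError(sprintf("no recognised class folders under '%s'",
                                  splitDir)))
  imgs <- list(); labs <- integer(); ids <- character()
  for (cls in found) {
    files <- sort(list.files(file.path(splitDir, cls), full.names = TRUE,
                             pattern = "\\.(jpg|jpeg|png)$",
                             ignore.case = TRUE))
    if (!length(files))
      warning(sprintf("class folder '%s' contains no images", cls))
    for (f in files) {
      px <- tryCatch(readImageFile(f), error = function(e) {
        warning(sprintf("skipping unreadable image '%s': %s", f,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(px)) next
      imgs[[length(imgs) + 1L]] <- px
      labs <- c(labs, match(cls, classes) - 1L)
      ids <- c(ids, f)
    }
  }
  new("ImageSet", images = imgs, labels = labs, classNames = classes,
      sourceIds = ids, split = split)
}

# read one JPEG/PNG via EBImage; returns rows x cols (x 3) numeric array
# on the 0..255 scale
readImageFile <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) {
    px <- t(d)                       # EBImage stores x (column) first
  } else {
    if (dim(d)[3L] > 3L) d <- d[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(d)[3L] == 1L) px <- t(d[, , 1L])
    else px <- aperm(d, c(2L, 1L, 3L))
  }
  px * 255
}

#' Generate a seeded synthetic phantom dataset
#'
#' Produces `4 * nPerClass` square grayscale images in `[0, 1]` that
#' emulate four visually separable classes on a brain-like elliptical
#' background: `glioma_tumor` carries an irregular ragged blob inside
#' one hemisphere, `meningioma_tumor` a bright lesion attached to the
#' ellipse boundary, `no_tumor` the noisy ellipse only and
#' `pituitary_tumor` a small compact lesion in the lower-central
#' region.  Additive Gaussian noise (sd `noiseSigma`) is applied last
#' and intensities are clipped to `[0, 1]`.  Output is fully
#' reproducible from the configuration seed and split.
#'
#' @param config a [PhantomConfig-class]
#' @param split `"training"` or `"testing"` (each split has its own
#'   deterministic stream derived from the seed)
#' @return an [ImageSet-class]
#' @export
generatePhantomDataset <- function(config,
                                   split = c("training", "testing")) {
  split <- match.arg(split)
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  classes <- tumorClasses()
  s <- config@imageSize
  n <- config@nPerClass
  seed <- config@seed + if (split == "training") 0L else 104729L
  imgs <- vector("list", 4L * n)
  labs <- integer(4L * n)
  ids <- character(4L * n)
  if (n > 0L) withSeed(seed, {
    k <- 0L
    for (ci in seq_along(classes)) {
      for (i in seq_len(n)) {
        k <- k + 1L
        imgs[[k]] <- phantomImage(classes[ci], s, config@noiseSigma,
                                  config@lesionContrast)
        labs[k] <- ci - 1L
        ids[k] <- sprintf("phantom_%s_%s_seed%d_%04d", split,
                          classes[ci], config@seed, i)
      }
    }
  })
  new("ImageSet", images = imgs, labels = labs, classNames = classes,
      sourceIds = ids, split = split)
}

# one phantom image; consumes the current RNG stream
phantomImage <- function(class, s, noiseSigma, contrast) {
  xs <- (seq_len(s) - 0.5) / s
  x <- matrix(xs, s, s, byrow = TRUE)    # column coordinate
  y <- matrix(xs, s, s)                  # row coordinate
  a <- 0.38; b <- 0.45                   # brain-ellipse semi-axes
  inside <- ((x - 0.5) / a)^2 + ((y - 0.5) / b)^2 <= 1
  bg <- 0.4 + stats::runif(1L, -0.03, 0.03)
  im <- matrix(0.05, s, s)
  im[inside] <- bg
  if (class == "glioma_tumor") {
    # ragged blob inside the left hemisphere
    cx <- 0.35 + stats::runif(1L, -0.04, 0.04)
    cy <- 0.45 + stats::runif(1L, -0.06, 0.06)
    ph <- stats::runif(2L, 0, 2 * pi)
    th <- atan2(y - cy, x - cx)
    rad <- 0.12 * (1 + 0.35 * sin(3 * th + ph[1]) +
                     0.25 * sin(5 * th + ph[2]))
    blob <- inside & ((x - cx)^2 + (y - cy)^2 <= rad^2)
    im[blob] <- pmin(1, im[blob] + 0.8 * contrast)
  } else if (class == "meningioma_tumor") {
    # bright lesion attached to the ellipse boundary; the attachment
    # angle avoids the lower-central arc so the class stays visually
    # distinct from the pituitary phantoms that live there
    th <- (3 * pi / 4 + stats::runif(1L, 0, 3 * pi / 2)) %% (2 * pi)
    cx <- 0.5 + 0.95 * a * cos(th)
    cy <- 0.5 + 0.95 * b * sin(th)
    les <- (x - cx)^2 + (y - cy)^2 <= 0.10^2
    im[les] <- pmin(1, im[les] + contrast)
  } else if (class == "pituitary_tumor") {
    # small compact lesion, lower-central region
    cx <- 0.5 + stats::runif(1L, -0.02, 0.02)
    cy <- 0.72 + stats::runif(1L, -0.03, 0.03)
    les <- (x - cx)^2 + (y - cy)^2 <= 0.06^2
    im[les] <- pmin(1, im[les] + contrast)
  }
  im <- im + stats::rnorm(s * s, 0, noiseSigma)
  im[im < 0] <- 0
  im[im > 1] <- 1
  im
}

#' Summarise the class distribution of a dataset
#'
#' @param dataset an [ImageSet-class]
#' @param seed optional integer recorded in the manifest (e.g. the
#'   phantom seed); `NA` for datasets loaded from disk
#' @return a [DatasetManifest-class]
#' @export
summarizeDistribution <- function(dataset, seed = NA_integer_) {
  stopifnot(is(dataset, "ImageSet"))
  classes <- if (length(dataset@classNames)) dataset@classNames
             else tumorClasses()
  tab <- table(factor(classes[dataset@labels + 1L], levels = classes))
  counts <- stats::setNames(as.integer(tab), classes)
  new("DatasetManifest", split = dataset@split, counts = counts,
      total = sum(counts), seed = as.integer(seed))
}

#' Write a DatasetManifest to JSON
#'
#' Serialises with keys `split`, `counts`, `total` and (when present)
#' `seed`.
#'
#' @param manifest a [DatasetManifest-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "DatasetManifest"))
  out <- list(split = manifest@split,
              counts = as.list(manifest@counts),
              total = manifest@total)
  if (!is.na(manifest@seed)) out$seed <- manifest@seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
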