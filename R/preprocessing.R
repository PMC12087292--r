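# colour-to-grayscale conversion, contrast enhancement, datastore assembly

#' Convert a colour cell image to grayscale by NTSC luminance
#'
#' Combines the red, green and blue channels into a single 8-bit luminance
#' plane, \code{round(cR * R + cG * G + cB * B)}, with the NTSC weights
#' (0.299, 0.587, 0.114) by default. Rounding is to the nearest integer,
#' half away from zero.
#'
#' @param img numeric H x W x 3 array with channel values in [0, 255].
#' @param cfg a \code{\link{PreprocessConfig}}.
#' @return Integer-valued H x W matrix of intensities in [0, 255].
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))  # pure red pixel
#' rgbToGrayscaleNtsc(img)                        # 76
#' @export
rgbToGrayscaleNtsc <- function(img, cfg = PreprocessConfig()) {
  stopifnot(is(cfg, "PreprocessConfig"))
  validObject(cfg)
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("img must be an H x W x 3 array")
  bad <- which(img < 0 | img > 255 | !is.finite(img))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(img))
    stop(sprintf("invalid image: channel value %s outside [0, 255] at pixel (row %d, col %d, channel %d)",
                 format(img[bad[1]]), idx[1], idx[2], idx[3]))
  }
  w <- cfg@grayCoefficients
  g <- w[1] * img[, , 1] + w[2] * img[, , 2] + w[3] * img[, , 3]
  .clip(.roundHalfUp(g), 0, 255)
}

#' Enhance grayscale contrast by percentile stretching
#'
#' Linearly maps the \code{lowerPercentile} intensity to 0 and the
#' \code{upperPercentile} intensity to 255, clipping outside values. The map
#' is monotone non-decreasing in input intensity. A degenerate image whose
#' stretch anchors coincide (e.g. all pixels equal) returns an all-zero
#' image with a warning rather than dividing by zero.
#'
#' @param img numeric H x W matrix of intensities in [0, 255].
#' @param cfg a \code{\link{PreprocessConfig}}.
#' @return Integer-valued matrix of the same dimensions, values in [0, 255].
#' @examples
#' m <- matrix(seq(50, 100, length.out = 100), 10, 10)
#' range(enhanceContrast(m))
#' @export
enhanceContrast <- function(img, cfg = PreprocessConfig()) {
  stopifnot(is(cfg, "PreprocessConfig"))
  validObject(cfg)
  if (!is.matrix(img)) stop("img must be a grayscale matrix")
  if (any(img < 0 | img > 255 | !is.finite(img)))
    stop("invalid image: intensities must lie in [0, 255]")
  q <- quantile(img, c(cfg@lowerPercentile, cfg@upperPercentile) / 100,
                names = FALSE, type = 7)
  if (q[2] - q[1] < 1e-12) {
    warning("degenerate image (constant within stretch percentiles); returning all-zero image")
    return(matrix(0, nrow(img), ncol(img)))
  }
  .clip(.roundHalfUp(255 * (img - q[1]) / (q[2] - q[1])), 0, 255)
}

# read one image file into a [0,255] array (H x W x 3) or matrix (H x W)
.readImageArray <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  a <- EBImage::imageData(im)
  if (length(d) == 2L) {
    out <- t(a)                     # EBImage stores x (width) first
  } else {
    nch <- d[3]
    if (nch >= 3L) {
      out <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
    } else {
      out <- aperm(array(rep(a[, , 1], 3), c(d[1], d[2], 3)), c(2, 1, 3))
    }
  }
  .roundHalfUp(.clip(out, 0, 1) * 255)
}

# write a [0,255] array/matrix as an image file (PNG unless extension says otherwise)
.writeImageArray <- function(img, path) {
  if (is.matrix(img)) {
    EBImage::writeImage(EBImage::Image(t(img / 255)), path)
  } else {
    EBImage::writeImage(EBImage::Image(aperm(img / 255, c(2, 1, 3)),
                                       colormode = "Color"), path)
  }
  invisible(path)
}

#' Build a labeled datastore from a class-per-directory image tree
#'
#' Scans \code{rootDir} for class subdirectories (one per class label) of
#' single-cell crop images (PNG/TIFF/JPEG), reads each image, optionally
#' applies NTSC grayscale conversion and contrast enhancement, and assembles
#' a \code{\link{CellImageSet}}. Record order is deterministic (sorted by
#' path); class names are the sorted subdirectory names. Unreadable files
#' are skipped with a warning and counted; an empty class directory is an
#' error.
#'
#' @param rootDir directory containing one subdirectory per class.
#' @param cfg a \code{\link{PreprocessConfig}}.
#' @param applyPreprocessing if TRUE (default), images are converted to
#'   grayscale and contrast-enhanced; otherwise raw colour arrays are kept.
#' @return A \code{CellImageSet}; the number of skipped files is attached as
#'   attribute \code{"skipped"}.
#' @seealso \code{\link{writeManifest}} to persist the datastore manifest.
#' @export
buildDatastore <- function(rootDir, cfg = PreprocessConfig(),
                           applyPreprocessing = TRUE) {
  if (!dir.exists(rootDir)) stop("rootDir does not exist: ", rootDir)
  classDirs <- sort(list.dirs(rootDir, recursive = FALSE))
  if (length(classDirs) == 0L)
    stop("rootDir contains no class subdirectories: ", rootDir)
  pat <- "\\.(png|tif|tiff|jpg|jpeg)$"
  imgs <- list(); labels <- character(); paths <- character()
  skipped <- 0L
  for (cd in classDirs) {
    cls <- basename(cd)
    files <- sort(list.files(cd, pattern = pat, ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      stop(sprintf("class directory '%s' contains no readable images", cls))
    ok <- 0L
    for (f in files) {
      a <- tryCatch(.readImageArray(f), error = function(e) NULL)
      if (is.null(a)) {
        warning(sprintf("skipping unreadable image: %s", f))
        skipped <- skipped + 1L
        next
      }
      if (applyPreprocessing) {
        if (!is.matrix(a)) a <- rgbToGrayscaleNtsc(a, cfg)
        a <- suppressWarnings(enhanceContrast(a, cfg))
      }
      imgs[[length(imgs) + 1L]] <- a
      labels <- c(labels, cls)
      paths <- c(paths, f)
      ok <- ok + 1L
    }
    if (ok == 0L)
      stop(sprintf("class directory '%s' contains no readable images", cls))
  }
  ds <- new("CellImageSet", images = imgs, labels = labels,
            sourcePaths = paths, classNames = basename(classDirs))
  attr(ds, "skipped") <- skipped
  ds
}

#' Write a datastore manifest to CSV
#'
#' Persists provenance for auditability: one row per record with its source
#' path, label and (optionally) the fold it was assigned to by
#' \code{\link{splitDataset}}.
#'
#' @param ds a \code{CellImageSet}.
#' @param file output CSV path.
#' @param split optional named list of \code{CellImageSet} folds (as returned
#'   by \code{splitDataset}) used to fill the \code{split_assignment} column.
#' @return The file path, invisibly.
#' @export
writeManifest <- function(ds, file, split = NULL) {
  assign <- rep(NA_character_, length(ds))
  if (!is.null(split)) {
    for (nm in names(split))
      assign[match(sourcePaths(split[[nm]]), sourcePaths(ds))] <- nm
  }
  df <- data.frame(source_path = sourcePaths(ds), label = imageLabels(ds),
                   split_assignment = assign, stringsAsFactors = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
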