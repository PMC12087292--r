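# seeded synthetic Giemsa-Wright-style single-cell image generator

# draw one cell instance from the phenotype distributions; this must be the
# FIRST use of the RNG after seeding so that drawPhenotypes() and
# renderCellImage() agree on the manifest values
.drawInstance <- function(p) {
  list(radius = max(4, rnorm(1, p@cellRadiusMean, p@cellRadiusSd)),
       nucleusRatio = .clip(rnorm(1, p@nucleusRatioMean, p@nucleusRatioSd),
                            0.08, 0.92),
       eccentricity = .clip(rnorm(1, p@eccentricityMean, p@eccentricitySd),
                            0, 0.85),
       orientation = runif(1, 0, pi),
       hueShift = rnorm(1, 0, p@stainHueJitter))
}

# separable Gaussian smoothing of a square matrix, correlation length sigma
.gaussBlur <- function(m, sigma) {
  s <- nrow(m)
  K <- outer(seq_len(s), seq_len(s),
             function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
  K <- K / rowSums(K)
  K %*% m %*% t(K)
}

#' Render one synthetic single-cell image
#'
#' Draws an instance from the phenotype distributions and renders a single
#' elliptical mononuclear cell — pink-grey cytoplasm ring around a darker
#' purple-blue nucleus with band-limited chromatin texture — on a pale,
#' near-uniform background, mimicking a Giemsa-Wright-stained crop. The
#' result is deterministic given \code{(params, seed)}.
#'
#' @param params a \code{\link{CellPhenotypeParams}}.
#' @param seed integer seed for this image.
#' @param imageSize square canvas side in pixels.
#' @param withMask if TRUE, also return the ground-truth cell and nucleus
#'   masks used for rendering.
#' @return An H x W x 3 array in [0, 255] with the drawn instance values in
#'   attribute \code{"instance"}; if \code{withMask}, a list
#'   \code{(image, cellMask, nucleusMask)}.
#' @examples
#' img <- renderCellImage(CellPhenotypeParams(), seed = 1, imageSize = 48)
#' dim(img)
#' @export
renderCellImage <- function(params, seed, imageSize = 64L, withMask = FALSE) {
  stopifnot(is(params, "CellPhenotypeParams"))
  validObject(params)
  S <- as.integer(imageSize)
  .withSeed(seed, {
    inst <- .drawInstance(params)
    e <- inst$eccentricity
    a <- inst$radius / (1 - e^2)^0.25       # area-preserving semi-axes
    b <- inst$radius * (1 - e^2)^0.25
    if (a > S / 2 - 2)
      stop(sprintf("cell (semi-major axis %.1f px) larger than the %d px canvas", a, S))
    cx <- S / 2 + runif(1, -2, 2)
    cy <- S / 2 + runif(1, -2, 2)
    col <- matrix(rep(seq_len(S), each = S), nrow = S)   # x coordinate
    row <- matrix(rep(seq_len(S), times = S), nrow = S)  # y coordinate
    dx <- col - cx; dy <- row - cy
    ct <- cos(inst$orientation); st <- sin(inst$orientation)
    u <- dx * ct + dy * st; v <- -dx * st + dy * ct
    fCell <- (u / a)^2 + (v / b)^2
    aCell <- .clip((1.12 - fCell) / 0.24, 0, 1)          # soft edge
    # concentric nucleus scaled to the target area ratio, slight offset
    sc <- sqrt(inst$nucleusRatio)
    off <- runif(2, -1, 1) * (1 - sc) * inst$radius * 0.35
    un <- (dx - off[1]) * ct + (dy - off[2]) * st
    vn <- -(dx - off[1]) * st + (dy - off[2]) * ct
    fNuc <- (un / (a * sc))^2 + (vn / (b * sc))^2
    aNuc <- .clip((1.12 - fNuc) / 0.24, 0, 1) * aCell
    # chromatin texture: band-limited noise inside the nucleus
    tex <- 0
    if (params@chromatinTextureScale > 0.05) {
      tex <- .gaussBlur(matrix(rnorm(S * S), S, S),
                        params@chromatinTextureScale)
      tex <- tex / max(sd(tex), 1e-12) * 16
    }
    h <- inst$hueShift
    bg <- params@backgroundLevel
    bgNoise <- matrix(rnorm(S * S, 0, 2), S, S)
    cytoNoise <- matrix(rnorm(S * S, 0, 4), S, S)
    base <- list(r = bg + 6 + bgNoise, g = bg + bgNoise, b = bg + 2 + bgNoise)
    cyto <- list(r = (206 + cytoNoise) * (1 + h),
                 g = 170 + cytoNoise,
                 b = (190 + cytoNoise) * (1 - 0.7 * h))
    nuc <- list(r = (118 + tex) * (1 + h),
                g = 94 + tex,
                b = (168 + tex) * (1 - 0.7 * h))
    img <- array(0, c(S, S, 3))
    for (k in 1:3) {
      ch <- c("r", "g", "b")[k]
      plane <- base[[ch]] * (1 - aCell) + cyto[[ch]] * aCell
      plane <- plane * (1 - aNuc) + nuc[[ch]] * aNuc
      img[, , k] <- plane + matrix(rnorm(S * S, 0, 1.5), S, S)
    }
    img <- .clip(.roundHalfUp(img), 0, 255)
    attr(img, "instance") <- inst
    if (withMask) {
      list(image = img, cellMask = fCell <= 1, nucleusMask = fNuc <= 1)
    } else img
  })
}

#' Build a synthetic dataset specification from a separation parameter
#'
#' Places class phenotype means on a circle in the (nucleus-to-cell area
#' ratio, chromatin texture scale) plane, at distance proportional to
#' \code{separationDelta} from a shared baseline. These two axes carry the
#' class signal because they are classic cytomorphology discriminators and
#' remain subtle relative to staining and illumination variation at small
#' delta. \code{separationDelta = 0} makes all classes identically
#' distributed.
#'
#' @param nClasses number of classes (>= 2); labels are
#'   \code{class_01, class_02, ...}.
#' @param nPerClass images per class.
#' @param imageSize square canvas side in pixels.
#' @param separationDelta unitless class-separation scale (>= 0). At delta
#'   = 1 the extreme classes differ by about 0.16 in mean nucleus:cell area
#'   ratio (~3 within-class standard deviations).
#' @param seed master seed.
#' @param baseline shared baseline \code{\link{CellPhenotypeParams}}.
#' @return A \code{\link{SyntheticDatasetSpec}}.
#' @export
syntheticSpec <- function(nClasses = 2L, nPerClass = 100L, imageSize = 64L,
                          separationDelta = 0, seed = 1L,
                          baseline = CellPhenotypeParams()) {
  stopifnot(nClasses >= 2L)
  angles <- 2 * pi * (seq_len(nClasses) - 1) / nClasses
  cp <- lapply(seq_len(nClasses), function(k) {
    p <- baseline
    p@nucleusRatioMean <- .clip(baseline@nucleusRatioMean +
      separationDelta * 0.08 * cos(angles[k]), 0.1, 0.9)
    p@chromatinTextureScale <- max(0.3, baseline@chromatinTextureScale +
      separationDelta * 1.0 * sin(angles[k]))
    p
  })
  names(cp) <- sprintf("class_%02d", seq_len(nClasses))
  new("SyntheticDatasetSpec", classParams = cp,
      nPerClass = as.integer(nPerClass), imageSize = as.integer(imageSize),
      separationDelta = as.numeric(separationDelta), seed = as.integer(seed))
}

# per-image seed table for a spec: one row per (class, index) pair
.imageSeeds <- function(spec) {
  cls <- names(spec@classParams)
  counter <- 0L
  out <- vector("list", length(cls) * spec@nPerClass)
  i <- 0L
  for (k in seq_along(cls)) {
    for (j in seq_len(spec@nPerClass)) {
      counter <- counter + 1L
      i <- i + 1L
      out[[i]] <- data.frame(class = cls[k], index = j,
                             seed = .deriveSeed(spec@seed, counter),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Draw the phenotype instances of a synthetic dataset without rendering
#'
#' Reproduces exactly the per-image instance draws that
#' \code{\link{generateDataset}} records in its ground-truth manifest, using
#' the same per-image seed scheme, but skips pixel rendering. Useful for
#' testing distributional properties of the generator cheaply.
#'
#' @param spec a \code{\link{SyntheticDatasetSpec}}.
#' @return A data.frame with one row per image: class, index, seed, and the
#'   drawn radius, nucleusRatio, eccentricity, orientation and hueShift.
#' @export
drawPhenotypes <- function(spec) {
  validObject(spec)
  tab <- .imageSeeds(spec)
  draws <- lapply(seq_len(nrow(tab)), function(i) {
    p <- spec@classParams[[tab$class[i]]]
    as.data.frame(.withSeed(tab$seed[i], .drawInstance(p)))
  })
  cbind(tab, do.call(rbind, draws))
}

#' Generate a synthetic single-cell image dataset on disk
#'
#' Writes \code{nPerClass} PNG images per class into per-class
#' subdirectories of \code{outDir} (compatible with
#' \code{\link{buildDatastore}}) plus a ground-truth manifest
#' \code{manifest.csv} holding each image's true parameter draws. Fully
#' reproducible from the master seed: per-image seeds derive from it by a
#' fixed counter scheme, so every image is reproducible element-wise
#' regardless of generation order.
#'
#' @param spec a \code{\link{SyntheticDatasetSpec}}.
#' @param outDir output directory; must be empty or absent unless
#'   \code{overwrite}.
#' @param overwrite if TRUE, an existing non-empty \code{outDir} is removed
#'   and regenerated.
#' @return The ground-truth manifest data.frame, invisibly.
#' @examples
#' \donttest{
#' spec <- syntheticSpec(2, nPerClass = 3, imageSize = 48, seed = 7)
#' out <- file.path(tempdir(), "synthdemo")
#' generateDataset(spec, out, overwrite = TRUE)
#' list.files(out, recursive = TRUE)
#' }
#' @export
generateDataset <- function(spec, outDir, overwrite = FALSE) {
  validObject(spec)
  if (dir.exists(outDir) && length(list.files(outDir, all.files = TRUE,
                                              no.. = TRUE))) {
    if (!overwrite)
      stop("output directory is non-empty (set overwrite = TRUE): ", outDir)
    unlink(outDir, recursive = TRUE)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  man <- drawPhenotypes(spec)
  man$path <- file.path(man$class, sprintf("cell_%04d.png", man$index))
  for (cls in names(spec@classParams))
    dir.create(file.path(outDir, cls), showWarnings = FALSE)
  for (i in seq_len(nrow(man))) {
    img <- renderCellImage(spec@classParams[[man$class[i]]], man$seed[i],
                           spec@imageSize)
    .writeImageArray(img, file.path(outDir, man$path[i]))
  }
  write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Generate a synthetic dataset directly as a datastore
#'
#' Convenience wrapper rendering the images of \code{spec} in memory (no
#' files written) and assembling them into a \code{\link{CellImageSet}},
#' optionally preprocessed (grayscale + contrast enhancement).
#'
#' @param spec a \code{\link{SyntheticDatasetSpec}}.
#' @param cfg a \code{\link{PreprocessConfig}}.
#' @param applyPreprocessing convert to contrast-enhanced grayscale (default
#'   TRUE).
#' @return A \code{CellImageSet} with the manifest attached as attribute
#'   \code{"manifest"}.
#' @export
synthesizeDatastore <- function(spec, cfg = PreprocessConfig(),
                                applyPreprocessing = TRUE) {
  validObject(spec)
  man <- drawPhenotypes(spec)
  man$path <- file.path(man$class, sprintf("cell_%04d.png", man$index))
  imgs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- renderCellImage(spec@classParams[[man$class[i]]], man$seed[i],
                           spec@imageSize)
    attr(img, "instance") <- NULL
    if (applyPreprocessing) {
      img <- rgbToGrayscaleNtsc(img, cfg)
      img <- suppressWarnings(enhanceContrast(img, cfg))
    }
    imgs[[i]] <- img
  }
  ds <- new("CellImageSet", images = imgs, labels = man$class,
            sourcePaths = man$path,
            classNames = sort(names(spec@classParams)))
  attr(ds, "manifest") <- man
  ds
}
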