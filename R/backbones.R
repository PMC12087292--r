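# backbone registry and convolutional feature extraction

# published ImageNet-scale roster (trunks must be supplied as weight
# artifacts) plus desk-scale random-init surrogate CNNs
.publishedRoster <- data.frame(
  name = c("alexnet", "googlenet", "googlenet_places365", "resnet18",
           "resnet50", "resnet101", "vgg16", "vgg19", "inceptionv3",
           "inceptionresnetv2", "squeezenet", "densenet201", "mobilenetv2",
           "shufflenet", "xception", "nasnetmobile", "nasnetlarge"),
  inputSize = c(227L, 224L, 224L, 224L, 224L, 224L, 224L, 224L, 299L, 299L,
                227L, 224L, 224L, 224L, 299L, 224L, 331L),
  pretrainedSource = c("imagenet_weights", "imagenet_weights",
                       "places365_weights", rep("imagenet_weights", 14L)),
  stringsAsFactors = FALSE)

.surrogateRoster <- list(
  scnnA = list(inputSize = 64L, convFilters = c(8L, 16L, 16L),
               hiddenUnits = 32L, weightSeed = 101L),
  scnnB = list(inputSize = 64L, convFilters = c(12L, 24L, 32L),
               hiddenUnits = 48L, weightSeed = 102L),
  scnnC = list(inputSize = 32L, convFilters = c(8L, 16L),
               hiddenUnits = 24L, weightSeed = 103L),
  scnnD = list(inputSize = 64L, convFilters = c(6L, 12L, 24L),
               hiddenUnits = 32L, weightSeed = 104L),
  scnnE = list(inputSize = 32L, convFilters = c(10L, 20L),
               hiddenUnits = 40L, weightSeed = 105L))

#' Backbone registry
#'
#' Lists the available backbones: the seventeen published ImageNet-scale
#' architectures (usable once their pretrained trunk weights are supplied as
#' an artifact) and the desk-scale surrogate CNNs (\code{scnnA} ...
#' \code{scnnE}) whose small random-initialised trunks are materialised
#' deterministically from a registry seed, so tests and benchmarks never
#' require weight downloads. Two further roster slots of the published
#' ensemble are intentionally left configurable via
#' \code{\link{makeSurrogateBackbone}}.
#'
#' @return data.frame with columns name, family, inputSize, pretrainedSource.
#' @examples
#' head(backboneRegistry())
#' @export
backboneRegistry <- function() {
  pub <- data.frame(name = .publishedRoster$name, family = "published",
                    inputSize = .publishedRoster$inputSize,
                    pretrainedSource = .publishedRoster$pretrainedSource,
                    stringsAsFactors = FALSE)
  sur <- data.frame(name = names(.surrogateRoster), family = "surrogate",
                    inputSize = vapply(.surrogateRoster, `[[`, 1L, "inputSize"),
                    pretrainedSource = "random_init",
                    stringsAsFactors = FALSE)
  rbind(pub, sur)
}

#' Retrieve a backbone specification by name
#'
#' @param name a registry name (see \code{\link{backboneRegistry}}).
#' @return A \code{\link{BackboneSpec}}.
#' @examples
#' getBackbone("scnnA")
#' @export
getBackbone <- function(name) {
  if (name %in% names(.surrogateRoster)) {
    s <- .surrogateRoster[[name]]
    nConv <- length(s$convFilters)
    return(new("BackboneSpec", name = name, inputSize = s$inputSize,
               pretrainedSource = "random_init",
               frozenDepth = nConv / (nConv + 2),
               convFilters = s$convFilters, hiddenUnits = s$hiddenUnits,
               weightSeed = s$weightSeed))
  }
  i <- match(name, .publishedRoster$name)
  if (is.na(i))
    stop("unknown backbone '", name, "'; see backboneRegistry()")
  new("BackboneSpec", name = name, inputSize = .publishedRoster$inputSize[i],
      pretrainedSource = .publishedRoster$pretrainedSource[i],
      frozenDepth = 0.9, convFilters = integer(0), hiddenUnits = 64L,
      weightSeed = NA_integer_)
}

#' Define a custom surrogate backbone
#'
#' Creates a small random-initialised CNN entry: a trunk of 3x3 convolution
#' + ReLU + 2x2 mean-pool blocks followed by a trainable dense block and
#' softmax head. Useful for filling additional ensemble roster slots with
#' architecturally diverse desk-scale members.
#'
#' @param name unique identifier.
#' @param inputSize square input side (>= 32).
#' @param convFilters integer vector, filters per trunk block (2-4 blocks
#'   are typical).
#' @param hiddenUnits width of the dense block.
#' @param weightSeed seed materialising the trunk weights.
#' @return A \code{\link{BackboneSpec}}.
#' @export
makeSurrogateBackbone <- function(name, inputSize = 64L,
                                  convFilters = c(8L, 16L),
                                  hiddenUnits = 32L, weightSeed = 1L) {
  nConv <- length(convFilters)
  new("BackboneSpec", name = name, inputSize = as.integer(inputSize),
      pretrainedSource = "random_init", frozenDepth = nConv / (nConv + 2),
      convFilters = as.integer(convFilters),
      hiddenUnits = as.integer(hiddenUnits),
      weightSeed = as.integer(weightSeed))
}

# ---- trunk materialisation -------------------------------------------------

# He-initialised trunk weights for a random-init backbone; weight matrices
# are (9 * Cin) x Cout with rows ordered (kernel row, kernel col) within
# channel, matching .convForward's im2col layout
.materializeTrunk <- function(backbone) {
  if (length(backbone@convFilters) == 0L)
    stop("backbone '", backbone@name, "' requires a pretrained weight ",
         "artifact; supply one via the trunk argument of fineTuneBackbone() ",
         "or use a surrogate backbone")
  .withSeed(backbone@weightSeed, {
    cin <- 3L
    lapply(backbone@convFilters, function(cout) {
      W <- matrix(rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                  nrow = 9L * cin, ncol = cout)
      layer <- list(W = W, b = rep(0, cout))
      cin <<- cout
      layer
    })
  })
}

# im2col gather-index cache, keyed by (side, channels)
.cvCache <- new.env(parent = emptyenv())

.im2colIdx <- function(S, Cin) {
  key <- paste(S, Cin, sep = "x")
  if (!is.null(.cvCache[[key]])) return(.cvCache[[key]])
  P <- S + 2L
  topLeft <- as.vector(outer(seq_len(S), seq_len(S),
                             function(i, j) (j - 1L) * P + i))
  off <- as.vector(outer(0:2, 0:2, function(di, dj) dj * P + di))
  idx2d <- outer(topLeft, off, "+")
  idx <- do.call(cbind, lapply(seq_len(Cin) - 1L,
                               function(ch) idx2d + ch * P * P))
  .cvCache[[key]] <- idx
  idx
}

# one trunk block: 3x3 same-padding convolution + ReLU + 2x2 mean pool
.convBlock <- function(A, layer) {
  S <- dim(A)[1]; Cin <- dim(A)[3]
  P <- S + 2L
  pad <- array(0, c(P, P, Cin))
  pad[2:(S + 1), 2:(S + 1), ] <- A
  cols <- matrix(pad[.im2colIdx(S, Cin)], nrow = S * S)
  Z <- cols %*% layer$W
  Z <- Z + rep(layer$b, each = S * S)
  Z[Z < 0] <- 0
  A2 <- array(Z, c(S, S, ncol(layer$W)))
  o <- seq(1L, S, 2L); e <- o + 1L
  0.25 * (A2[o, o, , drop = FALSE] + A2[e, o, , drop = FALSE] +
          A2[o, e, , drop = FALSE] + A2[e, e, , drop = FALSE])
}

# image (matrix or HxWx3 array, [0,255]) -> trunk feature vector
.imageFeatures <- function(img, trunk, inputSize) {
  if (is.matrix(img)) {
    plane <- .resizePlane(img / 255 - 0.5, inputSize)
    A <- array(rep(plane, 3L), c(inputSize, inputSize, 3L))
  } else {
    A <- array(0, c(inputSize, inputSize, 3L))
    for (k in 1:3) A[, , k] <- .resizePlane(img[, , k] / 255 - 0.5, inputSize)
  }
  for (layer in trunk) A <- .convBlock(A, layer)
  as.vector(A)
}

# datastore -> n x d feature matrix through a frozen trunk
.extractFeatures <- function(ds, trunk, inputSize) {
  n <- length(ds)
  if (n == 0L) return(matrix(0, 0L, 0L))
  first <- .imageFeatures(ds@images[[1L]], trunk, inputSize)
  X <- matrix(0, n, length(first))
  X[1L, ] <- first
  if (n > 1L) for (i in 2:n)
    X[i, ] <- .imageFeatures(ds@images[[i]], trunk, inputSize)
  X
}
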