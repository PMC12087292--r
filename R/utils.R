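# internal helpers shared across modules

#' @importFrom stats quantile rnorm runif sd median
#' @importFrom utils head read.csv write.csv
NULL

# round half away from zero; inputs here are always non-negative intensities
.roundHalfUp <- function(x) floor(x + 0.5)

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# derive a per-item seed from a master seed and a counter; stays < 2^31 - 1
.deriveSeed <- function(master, counter) {
  as.integer((abs(as.numeric(master)) %% 1e6) * 1997 + counter * 7919) %% 2147483647L
}

# run expr under a local RNG state so callers' streams are untouched
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# md5 of a deterministic JSON rendering of an R object (config provenance)
.hashObject <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

# bilinear resize of a numeric matrix (grayscale plane) to size x size
.resizePlane <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  out <- EBImage::resize(EBImage::Image(m), w = size, h = size,
                         filter = "bilinear")
  EBImage::imageData(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
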