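#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that individual stages (stimuli, views, decision noise,
#' bootstrap) are independently reproducible. The derivation is a small
#' multiplicative string hash folded with the master seed; it is stable
#' across platforms and R versions and always returns a value in
#' `[0, 2^31 - 2]`, safe for `set.seed()`.
#'
#' @param master_seed Integer master seed.
#' @param label Character label of the substream (e.g. `"view"`, `"noise"`).
#' @param index Optional nonnegative integer distinguishing draws within a
#'   substream (e.g. the view index).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "view", 0)
derive_seed <- function(master_seed, label, index = 0L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(label), length(label) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master_seed) %% m + m) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h)
}

#' Gaussian blur of a luminance matrix
#'
#' Thin wrapper around [EBImage::gblur()] accepting `sigma = 0` as the exact
#' identity. Used for the smoothness axis of the stimulus space and for the
#' heavily blurred reference image of the local-contrast estimators.
#'
#' @param x Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels, `>= 0`.
#' @return Blurred matrix of the same dimension.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(x)
  as.matrix(EBImage::gblur(x, sigma = sigma))
}

#' Bilinear sampling of a matrix at fractional coordinates
#'
#' Samples `x` at (row, col) positions `(yi, xi)` with bilinear
#' interpolation; positions falling outside the matrix read as `value`
#' (default 0, the black void surrounding every stimulus object).
#'
#' @param x Numeric matrix.
#' @param yi,xi Numeric vectors of equal length: fractional row and column
#'   positions (1-based).
#' @param value Fill value for out-of-frame samples.
#' @return Numeric vector of sampled values, same length as `yi`.
#' @keywords internal
bilinear_sample <- function(x, yi, xi, value = 0) {
  n <- nrow(x); m <- ncol(x)
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0;   fx <- xi - x0
  # gather the four neighbours; out-of-frame neighbours read as `value`
  at <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    out <- rep(value, length(r))
    out[ok] <- x[cbind(r[ok], c[ok])]
    out
  }
  v00 <- at(y0,      x0)
  v01 <- at(y0,      x0 + 1)
  v10 <- at(y0 + 1,  x0)
  v11 <- at(y0 + 1,  x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Sample skewness with population (1/N) moments
#' @param x Numeric vector.
#' @return Scalar skewness; `NaN` when the standard deviation is 0.
#' @keywords internal
population_skewness <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  mean((x - mu)^3) / s^3
}

#' Short deterministic hash of an R object (FNV-1a over its serialization)
#'
#' Used to stamp every pipeline output with the configuration that produced
#' it. Not cryptographic.
#'
#' @param x Any serializable R object.
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2, xdr = TRUE)
  # skip the serialization header (R version fields vary across builds)
  bytes <- as.integer(bytes[-seq_len(14L)])
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", as.integer(h))
}
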