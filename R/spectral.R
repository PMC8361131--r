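#' Apply a taper window to a square image
#'
#' Windowing minimises the edge artefacts (spectral leakage) that an abrupt
#' frame boundary introduces into Fourier spectra. The default is the
#' separable 2-D Hann taper; `"rect"` is the identity (no taper).
#'
#' @param img A `stimulus_image` or numeric matrix.
#' @param window_kind `"hann"` (default) or `"rect"`.
#' @return A numeric matrix of windowed pixels.
#' @export
window_image <- function(img, window_kind = c("hann", "rect")) {
  window_kind <- match.arg(window_kind)
  x <- if (inherits(img, "stimulus_image")) img$pixels else img
  stopifnot(is.matrix(x))
  if (nrow(x) != ncol(x)) stop("image must be square", call. = FALSE)
  if (window_kind == "rect") return(x)
  n <- nrow(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  x * (w %o% w)
}

#' Radially averaged power spectrum
#'
#' The 2-D power spectrum `|FFT|^2` (normalized so that its sum equals the
#' total image energy, Parseval) is interpolated from the Cartesian
#' frequency grid onto a one-dimensional radial frequency axis — equivalent
#' to averaging the spectrum over orientation. Each Cartesian cell at radius
#' `r` (cycles per image, cpi) is split between the two neighbouring integer
#' bins with linear (inverse-distance) weights; bin power is the weighted
#' mean, and the accompanying bin area is the weighted cell count, so that
#' `sum(power * area)` recovers the total non-DC energy exactly. Cells
#' beyond the Nyquist radius (the corners of the grid) are folded into the
#' Nyquist bin. DC is excluded.
#'
#' @param img A `stimulus_image` or square numeric matrix.
#' @param window_kind Taper passed to [window_image()].
#' @return An object of class `radial_spectrum`: data.frame-like list with
#'   `frequencies` (1..Nyquist, cpi), `power`, `area`, `n_bins`, and the
#'   window kind used.
#' @export
#' @examples
#' sp <- radial_power_spectrum(matrix(rnorm(64^2), 64), "rect")
#' head(sp$frequencies)
radial_power_spectrum <- function(img, window_kind = c("hann", "rect")) {
  x <- window_image(img, window_kind)
  n <- nrow(x)
  p2 <- Mod(stats::fft(x))^2 / (n * n) # sum(p2) == sum(x^2)
  k <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1))
  fx <- matrix(k, n, n, byrow = TRUE)
  fy <- matrix(k, n, n)
  r <- sqrt(fx^2 + fy^2)
  nyq <- n %/% 2
  keep <- r > 0
  r <- r[keep]
  p <- p2[keep]
  lo <- floor(r)
  frac <- r - lo
  hi <- lo + 1
  # fold sub-1 and beyond-Nyquist radii into the end bins
  idx <- c(pmin(pmax(lo, 1), nyq), pmin(pmax(hi, 1), nyq))
  wgt <- c(1 - frac, frac)
  pw <- c(p, p)
  acc <- rowsum(cbind(wgt, wgt * pw), idx)
  bins <- as.integer(rownames(acc))
  power <- numeric(nyq)
  ar <- numeric(nyq)
  power[bins] <- acc[, 2] / acc[, 1]
  ar[bins] <- acc[, 1]
  structure(list(frequencies = seq_len(nyq), power = power, area = ar,
                 n_bins = nyq, window_kind = match.arg(window_kind)),
            class = "radial_spectrum")
}

#' @export
print.radial_spectrum <- function(x, ...) {
  cat(sprintf("Radial power spectrum: %d bins (1..%d cpi), %s window\n",
              x$n_bins, x$n_bins, x$window_kind))
  invisible(x)
}

#' Mean spectral power over a radial frequency band
#'
#' The 23-53 cpi band is the conventional high-frequency summary band for
#' material images of this size.
#'
#' @param spectrum A `radial_spectrum`.
#' @param lo_cpi,hi_cpi Inclusive band limits in cycles per image.
#' @return Mean power over bins in the band (unweighted mean of bin powers).
#' @export
band_mean_power <- function(spectrum, lo_cpi = 23, hi_cpi = 53) {
  stopifnot(inherits(spectrum, "radial_spectrum"))
  sel <- spectrum$frequencies >= lo_cpi & spectrum$frequencies <= hi_cpi
  if (!any(sel))
    stop("band [", lo_cpi, ", ", hi_cpi, "] cpi contains no spectrum bins",
         call. = FALSE)
  mean(spectrum$power[sel])
}

#' Log-log slope of a radial power spectrum
#'
#' Least-squares slope of `log(power)` against `log(frequency)`. Natural
#' images have power slopes near -2 (1/f amplitude).
#'
#' @param spectrum A `radial_spectrum`.
#' @param fit_range Length-2 numeric, inclusive cpi range to fit over;
#'   default the central decade `[4, n_bins/2]`.
#' @return The fitted slope (dimensionless).
#' @export
loglog_slope <- function(spectrum, fit_range = NULL) {
  stopifnot(inherits(spectrum, "radial_spectrum"))
  if (is.null(fit_range)) fit_range <- c(4, spectrum$n_bins / 2)
  sel <- spectrum$frequencies >= fit_range[1] &
    spectrum$frequencies <= fit_range[2] & spectrum$power > 0
  if (sum(sel) < 3) stop("need at least 3 bins in `fit_range`", call. = FALSE)
  lf <- log(spectrum$frequencies[sel])
  lp <- log(spectrum$power[sel])
  unname(stats::coef(stats::lm(lp ~ lf))[2])
}

#' Swap the Fourier amplitude and phase spectra of two images
#'
#' Produces the two hybrid images: one carrying the amplitude spectrum of
#' `img_a` with the phase of `img_b`, and vice versa. Hybrids are real by
#' conjugate symmetry of the inputs (imaginary residue below 1e-8 is
#' discarded).
#'
#' @param img_a,img_b `stimulus_image`s or numeric matrices of equal shape.
#' @return List with matrices `hybrid_ab` (amplitude of a, phase of b) and
#'   `hybrid_ba`.
#' @export
amplitude_phase_swap <- function(img_a, img_b) {
  a <- if (inherits(img_a, "stimulus_image")) img_a$pixels else img_a
  b <- if (inherits(img_b, "stimulus_image")) img_b$pixels else img_b
  if (!identical(dim(a), dim(b)))
    stop("images must have identical shape", call. = FALSE)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  n2 <- length(a)
  unit <- function(z) ifelse(Mod(z) > 0, z / Mod(z), 1 + 0i)
  h_ab <- stats::fft(Mod(fa) * unit(fb), inverse = TRUE) / n2
  h_ba <- stats::fft(Mod(fb) * unit(fa), inverse = TRUE) / n2
  list(hybrid_ab = Re(h_ab), hybrid_ba = Re(h_ba))
}

#' Tabulate radial spectra for a set of stimuli
#'
#' @param images List of `stimulus_image` objects.
#' @param window_kind Taper passed to [window_image()].
#' @return A long data.frame with columns `cpi`, `power`,
#'   `smoothness_index`, `bumpiness_index`, `view_index`.
#' @export
spectra_table <- function(images, window_kind = c("hann", "rect")) {
  window_kind <- match.arg(window_kind)
  do.call(rbind, lapply(images, function(img) {
    sp <- radial_power_spectrum(img, window_kind)
    data.frame(cpi = sp$frequencies, power = sp$power,
               smoothness_index = img$smoothness_index,
               bumpiness_index = img$bumpiness_index,
               view_index = img$view_index)
  }))
}
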