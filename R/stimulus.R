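#' Configuration of the synthetic metallicity stimulus space
#'
#' Defines a two-axis grid of synthetic luminance images emulating the
#' statistical structure of rendered coated-metal objects. Along the
#' smoothness axis, decreasing metal smoothness (increasing microfacet
#' roughness) acts as a Gaussian blur of the reflected environment; along the
#' bumpiness axis, an uneven transparent coating acts as a local-disarray
#' warp — a smooth random pixel-displacement field. Images are objects on a
#' black void, with naturalistic 1/f amplitude spectra and a positively
#' skewed, highlight-rich luminance distribution.
#'
#' Smoothness level 1 is the smoothest metal (`blur_sigmas[1] == 0`) and
#' blur increases with level; bumpiness level 1 is the even coating
#' (`disarray_amplitudes[1] == 0`) and displacement amplitude increases with
#' level. "Views" emulate object rotations as statistically identical but
#' pixel-wise independent draws of image content: the rotations exist to
#' prevent direct pixel-based comparisons, and statistical (not geometric)
#' equivalence is what the downstream analyses need.
#'
#' @param image_size Pixels per side (square images).
#' @param n_smoothness_levels,n_bumpiness_levels Number of grid levels per
#'   axis.
#' @param n_views Number of statistically equivalent views per condition
#'   (`>= 2`; paired-comparison trials never show the same view twice).
#' @param blur_sigmas Monotone nondecreasing Gaussian blur standard
#'   deviations in pixels, one per smoothness level, first entry 0. The
#'   default spans 0 to 1% of the image width with mildly superlinear
#'   spacing.
#' @param disarray_amplitudes Monotone nondecreasing RMS displacement
#'   amplitudes in pixels, one per bumpiness level, first entry 0.
#' @param disarray_scale Correlation length of the displacement field in
#'   pixels.
#' @param base_spectral_exponent Amplitude-spectrum falloff exponent; 1 gives
#'   the 1/f amplitude (1/f^2 power) statistics of natural images.
#' @param base_bandlimit_sigma Anti-aliasing bandwidth of the base image in
#'   pixels: the Gaussian point-spread already present in the smoothest
#'   stimulus (physically rendered images are bandlimited by the render's
#'   pixel filter). 0 disables it.
#' @param luminance_skew Exponent of the skew-inducing point nonlinearity
#'   applied to the normalized base field; 1 is the identity (no added skew),
#'   larger values concentrate luminance into sparse specular-like
#'   highlights.
#' @param luminance_floor Strictly positive in-object luminance floor, as a
#'   fraction of the maximum; keeps ratio-based contrast statistics
#'   (dynamic range) defined.
#' @param master_seed Integer master seed; the whole grid is a pure function
#'   of the configuration, including this seed.
#' @return An object of class `stim_config` (a validated list).
#' @export
#' @examples
#' cfg <- stim_config(image_size = 64, n_views = 2)
#' cfg$blur_sigmas
stim_config <- function(image_size = 512L,
                        n_smoothness_levels = 5L,
                        n_bumpiness_levels = 5L,
                        n_views = 8L,
                        blur_sigmas = NULL,
                        disarray_amplitudes = NULL,
                        disarray_scale = NULL,
                        base_spectral_exponent = 1.0,
                        base_bandlimit_sigma = 0.5,
                        luminance_skew = 3.0,
                        luminance_floor = 0.005,
                        master_seed = 1L) {
  if (length(image_size) != 1L || !is.finite(image_size) || image_size <= 0)
    stop("`image_size` must be a single positive number", call. = FALSE)
  image_size <- as.integer(image_size)
  if (n_views < 2L) stop("`n_views` must be >= 2", call. = FALSE)
  # default blur axis scales with image size (0..5.1 px at 512), spaced
  # slightly superlinearly so the finest-scale statistics separate all
  # levels (past ~1% of the image width the finest band is dominated by the
  # sharp silhouette and further blur no longer moves it); the disarray
  # axis is in absolute pixels: the coating grain acts at the scale of the
  # image's fine features, and the nonzero levels start where the warp's
  # shear (not its resampling) dominates the fine-scale statistics,
  # mirroring the perceptually equidistant (not physically linear) spacing
  # the original difference-scaling calibration produced
  if (is.null(blur_sigmas)) {
    u <- seq(0, 1, length.out = n_smoothness_levels)
    blur_sigmas <- (image_size / 100) * u^1.25
  }
  if (is.null(disarray_amplitudes))
    disarray_amplitudes <- if (n_bumpiness_levels == 1L) 0 else
      c(0, seq(6, 9, length.out = n_bumpiness_levels - 1L))
  if (is.null(disarray_scale)) disarray_scale <- 2
  if (length(blur_sigmas) != n_smoothness_levels)
    stop("`blur_sigmas` must have one entry per smoothness level",
         call. = FALSE)
  if (length(disarray_amplitudes) != n_bumpiness_levels)
    stop("`disarray_amplitudes` must have one entry per bumpiness level",
         call. = FALSE)
  if (is.unsorted(blur_sigmas) || blur_sigmas[1] != 0)
    stop("`blur_sigmas` must be nondecreasing with first entry 0",
         call. = FALSE)
  if (is.unsorted(disarray_amplitudes) || disarray_amplitudes[1] != 0)
    stop("`disarray_amplitudes` must be nondecreasing with first entry 0",
         call. = FALSE)
  if (disarray_scale <= 0) stop("`disarray_scale` must be > 0", call. = FALSE)
  if (luminance_floor <= 0 || luminance_floor >= 1)
    stop("`luminance_floor` must be in (0, 1)", call. = FALSE)
  structure(list(
    image_size = image_size,
    n_smoothness_levels = as.integer(n_smoothness_levels),
    n_bumpiness_levels = as.integer(n_bumpiness_levels),
    n_views = as.integer(n_views),
    blur_sigmas = as.numeric(blur_sigmas),
    disarray_amplitudes = as.numeric(disarray_amplitudes),
    disarray_scale = as.numeric(disarray_scale),
    base_spectral_exponent = as.numeric(base_spectral_exponent),
    base_bandlimit_sigma = as.numeric(base_bandlimit_sigma),
    luminance_skew = as.numeric(luminance_skew),
    luminance_floor = as.numeric(luminance_floor),
    master_seed = as.integer(master_seed)
  ), class = "stim_config")
}

#' @export
print.stim_config <- function(x, ...) {
  cat("Stimulus space configuration\n")
  cat(sprintf("  %d x %d px, %d smoothness x %d bumpiness levels, %d views\n",
              x$image_size, x$image_size, x$n_smoothness_levels,
              x$n_bumpiness_levels, x$n_views))
  cat("  blur sigmas (px):        ",
      paste(signif(x$blur_sigmas, 3), collapse = ", "), "\n")
  cat("  disarray RMS amps (px):  ",
      paste(signif(x$disarray_amplitudes, 3), collapse = ", "), "\n")
  cat(sprintf("  disarray scale %.3g px, spectral exponent %.3g, skew %.3g\n",
              x$disarray_scale, x$base_spectral_exponent, x$luminance_skew))
  cat(sprintf("  master seed %d\n", x$master_seed))
  invisible(x)
}

new_stimulus_image <- function(pixels, mask, smoothness_index,
                               bumpiness_index, view_index, seed) {
  structure(list(pixels = pixels,
                 object_mask = mask,
                 smoothness_index = as.integer(smoothness_index),
                 bumpiness_index = as.integer(bumpiness_index),
                 view_index = as.integer(view_index),
                 seed = as.integer(seed)),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf(paste0("Stimulus image %dx%d | smoothness level %d, ",
                     "bumpiness level %d, view %d (seed %d)\n"),
              nrow(x$pixels), ncol(x$pixels), x$smoothness_index,
              x$bumpiness_index, x$view_index, x$seed))
  inm <- x$pixels[x$object_mask]
  cat(sprintf("  in-object luminance: mean %.4g, max %.4g (%d px in object)\n",
              mean(inm), max(inm), sum(x$object_mask)))
  invisible(x)
}

# per-session cache for the deterministic heavy intermediates (the object
# mask and the displacement taper envelope are identical across the grid)
.stim_cache <- new.env(parent = emptyenv())

# smooth blob-shaped object mask, deterministic in the master seed:
# a disc whose radius is modulated by a few low-order angular harmonics
object_mask <- function(config) {
  n <- config$image_size
  key <- sprintf("mask_%d_%d", config$master_seed, n)
  cached <- .stim_cache[[key]]
  if (!is.null(cached)) return(cached)
  ctr <- (n + 1) / 2
  withr::with_seed(derive_seed(config$master_seed, "mask"), {
    amp <- c(0.12, 0.08, 0.05)
    k <- c(2L, 3L, 5L)
    ph <- stats::runif(3, 0, 2 * pi)
    xy <- seq_len(n) - ctr
    dx <- matrix(xy, n, n, byrow = TRUE)
    dy <- matrix(xy, n, n)
    r <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    r0 <- 0.36 * n
    rad <- r0 * (1 + amp[1] * cos(k[1] * th + ph[1]) +
                   amp[2] * cos(k[2] * th + ph[2]) +
                   amp[3] * cos(k[3] * th + ph[3]))
    .stim_cache[[key]] <- (r <= rad)
    .stim_cache[[key]]
  })
}

# random-phase field with amplitude spectrum ~ 1/f^exponent, unit variance;
# bandlimit_sigma (pixels) applies the Gaussian anti-aliasing envelope
# exp(-omega^2 sigma^2 / 2) that any physically rendered image carries
spectral_noise_field <- function(n, exponent, seed, bandlimit_sigma = 0) {
  withr::with_seed(seed, {
    w <- matrix(stats::rnorm(n * n), n, n)
  })
  f <- stats::fft(w)
  k <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) # fft frequency order, cpi
  fx <- matrix(k, n, n, byrow = TRUE)
  fy <- matrix(k, n, n)
  r <- sqrt(fx^2 + fy^2)
  amp <- ifelse(r > 0, r^(-exponent), 0) # DC removed
  if (bandlimit_sigma > 0) {
    omega2 <- (2 * pi / n)^2 * r^2
    amp <- amp * exp(-omega2 * bandlimit_sigma^2 / 2)
  }
  z <- Re(stats::fft(f * amp, inverse = TRUE)) / (n * n)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a base stimulus image (zero blur, zero disarray)
#'
#' Builds one "view" of the smoothest, even-coated stimulus: a random-phase
#' noise field with amplitude spectrum proportional to
#' `1/f^base_spectral_exponent` is normalized to `[0, 1]`, passed through the
#' monotone skew-inducing point nonlinearity `u^luminance_skew` (creating a
#' positively skewed, high-dynamic-range "specular" luminance distribution),
#' lifted onto the strictly positive luminance floor, and multiplied by a
#' smooth blob-shaped object mask centred in the frame. Different
#' `view_seed` values give statistically identical but pixel-wise
#' independent content.
#'
#' @param view_seed Integer seed for this view's content.
#' @param config A [stim_config()].
#' @return A `stimulus_image`: list with `pixels` (nonnegative luminance
#'   matrix, zero outside the object), `object_mask` (logical matrix),
#'   condition indices and the seed actually used.
#' @export
#' @examples
#' img <- make_base_image(0, stim_config(image_size = 64, n_views = 2))
#' range(img$pixels)
make_base_image <- function(view_seed, config) {
  stopifnot(inherits(config, "stim_config"))
  n <- config$image_size
  z <- spectral_noise_field(n, config$base_spectral_exponent,
                            as.integer(view_seed),
                            config$base_bandlimit_sigma)
  u <- (z - min(z)) / (max(z) - min(z))
  l <- u^config$luminance_skew
  l <- config$luminance_floor + (1 - config$luminance_floor) * l
  mask <- object_mask(config)
  l[!mask] <- 0
  new_stimulus_image(l, mask, 1L, 1L, 1L, view_seed)
}

#' Apply the smoothness transform (Gaussian blur of in-object content)
#'
#' Decreasing metal smoothness blurs the reflected environment, not the
#' object outline: the image content is Gaussian-blurred and the object mask
#' re-applied afterwards so the silhouette stays sharp. `sigma = 0` is the
#' exact identity.
#'
#' @param img A `stimulus_image`.
#' @param sigma Blur standard deviation in pixels, `>= 0`.
#' @return The blurred `stimulus_image`.
#' @export
apply_smoothness <- function(img, sigma) {
  stopifnot(inherits(img, "stimulus_image"))
  if (!is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a finite number >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  px <- gaussian_blur(img$pixels, sigma)
  px[!img$object_mask] <- 0
  px[px < 0] <- 0 # clip numerical undershoot from the truncated kernel
  img$pixels <- px
  img
}

# two independent smooth random displacement fields, each blurred to the
# requested correlation length, tapered to zero at the object boundary (the
# coating follows the object, so the silhouette itself does not shift), and
# jointly rescaled so the in-object displacement vectors have RMS radius
# `amplitude`
disarray_field <- function(n, amplitude, scale, seed, mask = NULL) {
  withr::with_seed(seed, {
    dx <- matrix(stats::rnorm(n * n), n, n)
    dy <- matrix(stats::rnorm(n * n), n, n)
  })
  dx <- gaussian_blur(dx, scale)
  dy <- gaussian_blur(dy, scale)
  if (!is.null(mask)) {
    # envelope 0 on/outside the silhouette, rising to 1 over ~2 blur widths
    # inside, so boundary pixels are never displaced into the void
    ekey <- sprintf("env_%d_%g_%d", n, scale, sum(mask))
    envelope <- .stim_cache[[ekey]]
    if (is.null(envelope)) {
      soft <- gaussian_blur(matrix(as.numeric(mask), n, n),
                            max(scale, n / 64))
      envelope <- pmin(1, pmax(0, (soft - 0.5) * 2))^2
      .stim_cache[[ekey]] <- envelope
    }
    dx <- dx * envelope
    dy <- dy * envelope
    rms <- sqrt(mean((dx^2 + dy^2)[mask]))
  } else {
    rms <- sqrt(mean(dx^2 + dy^2))
  }
  list(dx = dx / rms * amplitude, dy = dy / rms * amplitude)
}

#' Apply the bumpiness transform (local disarray warp)
#'
#' An uneven transparent coating distorts the image of the metal beneath it;
#' this is emulated by warping the in-object content with a smooth random
#' displacement field: two independent Gaussian random fields are smoothed to
#' correlation length `scale`, rescaled so the displacement vectors have RMS
#' length `amplitude`, and the image is resampled at the displaced positions
#' with bilinear interpolation (samples falling outside the object read the
#' black void, 0). The mask is re-applied afterwards. `amplitude = 0` is the
#' exact identity.
#'
#' @param img A `stimulus_image`.
#' @param amplitude RMS displacement in pixels, `>= 0`.
#' @param scale Correlation length of the displacement field in pixels,
#'   `> 0`.
#' @param warp_seed Integer seed for the displacement field.
#' @return The warped `stimulus_image`.
#' @export
apply_bumpiness <- function(img, amplitude, scale, warp_seed) {
  stopifnot(inherits(img, "stimulus_image"))
  if (!is.finite(amplitude) || amplitude < 0)
    stop("`amplitude` must be a finite number >= 0", call. = FALSE)
  if (!is.finite(scale) || scale <= 0)
    stop("`scale` must be a finite number > 0", call. = FALSE)
  if (amplitude == 0) return(img)
  n <- nrow(img$pixels)
  fld <- disarray_field(n, amplitude, scale, as.integer(warp_seed),
                        mask = img$object_mask)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  vals <- bilinear_sample(img$pixels,
                          as.vector(rows + fld$dy),
                          as.vector(cols + fld$dx),
                          value = 0)
  px <- matrix(vals, n, n)
  px[!img$object_mask] <- 0
  img$pixels <- px
  img
}

#' Render one condition of the stimulus grid
#'
#' Composes the base image with the two axis transforms: the blur of the
#' smoothness level is applied first (metal roughness blurs the reflection
#' beneath the coating), then the disarray of the bumpiness level (the
#' coating distorts the already-blurred reflection). The content seed depends
#' only on the view index and the warp seed only on the master seed and view
#' (not on the smoothness level), so conditions differ only through the two
#' transforms.
#'
#' @param s_idx Smoothness level, 1-based (1 = smoothest, zero blur).
#' @param b_idx Bumpiness level, 1-based (1 = even coating, zero disarray).
#' @param view_idx View, 1-based in `1:n_views`.
#' @param config A [stim_config()].
#' @return A `stimulus_image` carrying its condition and view indices.
#' @export
#' @examples
#' cfg <- stim_config(image_size = 64, n_views = 2)
#' img <- render_condition(2, 3, 1, cfg)
#' img$smoothness_index
render_condition <- function(s_idx, b_idx, view_idx, config) {
  stopifnot(inherits(config, "stim_config"))
  if (s_idx < 1 || s_idx > config$n_smoothness_levels)
    stop("`s_idx` out of range", call. = FALSE)
  if (b_idx < 1 || b_idx > config$n_bumpiness_levels)
    stop("`b_idx` out of range", call. = FALSE)
  if (view_idx < 1 || view_idx > config$n_views)
    stop("`view_idx` out of range", call. = FALSE)
  view_seed <- derive_seed(config$master_seed, "view", view_idx)
  img <- make_base_image(view_seed, config)
  img <- apply_smoothness(img, config$blur_sigmas[s_idx])
  warp_seed <- derive_seed(config$master_seed, "warp", view_idx)
  img <- apply_bumpiness(img, config$disarray_amplitudes[b_idx],
                         config$disarray_scale, warp_seed)
  img$smoothness_index <- as.integer(s_idx)
  img$bumpiness_index <- as.integer(b_idx)
  img$view_index <- as.integer(view_idx)
  img$seed <- view_seed
  img
}

#' Render the full conjoint-measurement stimulus grid
#'
#' All combinations of smoothness level, bumpiness level and view. At the
#' default 5 x 5 x 8 configuration this is the 200-image set used for
#' conjoint measurement.
#'
#' @param config A [stim_config()].
#' @return A list of `stimulus_image` objects.
#' @export
render_grid <- function(config) {
  stopifnot(inherits(config, "stim_config"))
  out <- vector("list",
                config$n_smoothness_levels * config$n_bumpiness_levels *
                  config$n_views)
  i <- 0L
  for (s in seq_len(config$n_smoothness_levels))
    for (b in seq_len(config$n_bumpiness_levels))
      for (v in seq_len(config$n_views)) {
        i <- i + 1L
        out[[i]] <- render_condition(s, b, v, config)
      }
  out
}

#' Render the difference-scaling stimulus sets
#'
#' One finely sampled axis per dimension, the other dimension held at its
#' first level: `n_levels` smoothness levels (even coating) and `n_levels`
#' bumpiness levels (smoothest metal), each under every view. At the default
#' 11 levels and 8 views this is the 176-image set used for difference
#' scaling.
#'
#' @param config A [stim_config()]; its level lists are ignored in favour of
#'   `n_levels` values linearly spaced over the same physical ranges.
#' @param n_levels Number of levels per dimension (default 11).
#' @return A list with elements `smoothness` and `bumpiness`, each a list of
#'   `stimulus_image` objects, plus the per-dimension physical values.
#' @export
render_mlds_sets <- function(config, n_levels = 11L) {
  stopifnot(inherits(config, "stim_config"))
  sig <- seq(0, max(config$blur_sigmas), length.out = n_levels)
  amp <- seq(0, max(config$disarray_amplitudes), length.out = n_levels)
  cfg_s <- config
  cfg_s$n_smoothness_levels <- as.integer(n_levels)
  cfg_s$blur_sigmas <- sig
  cfg_s$n_bumpiness_levels <- 1L
  cfg_s$disarray_amplitudes <- 0
  cfg_b <- config
  cfg_b$n_bumpiness_levels <- as.integer(n_levels)
  cfg_b$disarray_amplitudes <- amp
  cfg_b$n_smoothness_levels <- 1L
  cfg_b$blur_sigmas <- 0
  smooth_set <- list()
  bump_set <- list()
  for (lv in seq_len(n_levels))
    for (v in seq_len(config$n_views)) {
      smooth_set[[length(smooth_set) + 1L]] <-
        render_condition(lv, 1L, v, cfg_s)
      bump_set[[length(bump_set) + 1L]] <-
        render_condition(1L, lv, v, cfg_b)
    }
  list(smoothness = smooth_set, bumpiness = bump_set,
       blur_sigmas = sig, disarray_amplitudes = amp)
}
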