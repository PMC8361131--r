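# Global/local contrast estimators over the in-object luminance sample.
# All nine candidate metallicity statistics operate on the pixels inside the
# object mask: the black void surrounding every object would otherwise make
# the ratio statistics (dynamic range, Michelson) degenerate.

# in-object luminance sample, optionally paired with a heavily blurred copy
luminance_sample <- function(img, with_blur = FALSE, blur_sigma = NULL) {
  stopifnot(inherits(img, "stimulus_image"))
  L <- img$pixels[img$object_mask]
  out <- list(L = L, N = length(L), mu = mean(L),
              sigma = sqrt(mean((L - mean(L))^2)))
  if (with_blur) {
    if (is.null(blur_sigma)) blur_sigma <- nrow(img$pixels) / 8
    B <- gaussian_blur(img$pixels, blur_sigma)
    out$B <- B[img$object_mask]
  }
  out
}

#' Luminance skewness
#'
#' Third standardized moment of the in-object luminance histogram, with
#' population (1/N) moments. Skewness of the luminance distribution has a
#' long record as a candidate gloss statistic.
#'
#' @param img A `stimulus_image`.
#' @return Scalar skewness.
#' @export
lum_skewness <- function(img) {
  s <- luminance_sample(img)
  if (s$sigma == 0)
    stop("skewness undefined for a constant luminance sample", call. = FALSE)
  mean((s$L - s$mu)^3) / s$sigma^3
}

#' Dynamic range
#'
#' Ratio of the brightest to the dimmest in-object pixel. Requires a
#' strictly positive minimum; `floor` (if given) clips the sample from below
#' before the ratio, an option for images whose object pixels can reach 0.
#'
#' @param img A `stimulus_image`.
#' @param floor Optional strictly positive lower clip.
#' @return Scalar `L_max / L_min`.
#' @export
dynamic_range <- function(img, floor = NULL) {
  s <- luminance_sample(img)
  L <- s$L
  if (!is.null(floor)) {
    stopifnot(floor > 0)
    L <- pmax(L, floor)
  }
  if (min(L) <= 0)
    stop("dynamic range undefined: minimum luminance <= 0 ",
         "(use `floor` or exclude the background)", call. = FALSE)
  max(L) / min(L)
}

#' Robust dynamic range
#'
#' Ratio of the mean of the `n` brightest to the mean of the `n` dimmest
#' in-object pixels; `n = 1` reduces to [dynamic_range()].
#'
#' @inheritParams dynamic_range
#' @param n Sub-population size (default 10).
#' @return Scalar robust dynamic range.
#' @export
robust_dynamic_range <- function(img, n = 10L, floor = NULL) {
  s <- luminance_sample(img)
  if (n < 1 || n > s$N)
    stop("`n` must be between 1 and the in-object sample size", call. = FALSE)
  L <- s$L
  if (!is.null(floor)) {
    stopifnot(floor > 0)
    L <- pmax(L, floor)
  }
  L <- sort(L)
  lo <- mean(L[seq_len(n)])
  hi <- mean(L[seq.int(length(L) - n + 1L, length(L))])
  if (lo <= 0)
    stop("robust dynamic range undefined: dimmest sub-population mean <= 0",
         call. = FALSE)
  hi / lo
}

#' Michelson contrast
#'
#' `(L_max - L_min) / (L_max + L_min)` over the in-object sample; lies in
#' `[0, 1]` for nonnegative luminance.
#'
#' @param img A `stimulus_image`.
#' @return Scalar Michelson contrast.
#' @export
michelson_contrast <- function(img) {
  s <- luminance_sample(img)
  if (max(s$L) + min(s$L) == 0) return(0)
  (max(s$L) - min(s$L)) / (max(s$L) + min(s$L))
}

#' Root-mean-square contrast
#'
#' Population standard deviation of the in-object luminance sample.
#'
#' @param img A `stimulus_image`.
#' @return Scalar RMS contrast.
#' @export
rms_contrast <- function(img) luminance_sample(img)$sigma

#' Local image contrast (against the sample mean)
#'
#' Mean (default) or sum of `|L_i - mu|` over the in-object sample. The mean
#' form is image-size invariant; `form = "sum"` restores the raw-sum
#' variant.
#'
#' @param img A `stimulus_image`.
#' @param form `"mean"` or `"sum"` aggregation.
#' @return Scalar local image contrast.
#' @export
lic <- function(img, form = c("mean", "sum")) {
  form <- match.arg(form)
  s <- luminance_sample(img)
  d <- abs(s$L - s$mu)
  if (form == "mean") mean(d) else sum(d)
}

#' Local image contrast against a blurred reference
#'
#' As [lic()], but differences are taken against the same pixel of a heavily
#' blurred copy of the image (a local rather than global mean), with
#' `blur_sigma` defaulting to one eighth of the image size.
#'
#' @inheritParams lic
#' @param blur_sigma Standard deviation of the reference blur in pixels.
#' @return Scalar blurred local image contrast.
#' @export
lic_blur <- function(img, form = c("mean", "sum"), blur_sigma = NULL) {
  form <- match.arg(form)
  s <- luminance_sample(img, with_blur = TRUE, blur_sigma = blur_sigma)
  d <- abs(s$L - s$B)
  if (form == "mean") mean(d) else sum(d)
}

# the gain-controlled contrast term of each pixel: d^2.4 / (1 + d^2)
meese_summers_term <- function(d) d^2.4 / (1 + d^2)

#' Meese-Summers contrast (gain-controlled)
#'
#' Mean (default) or sum over in-object pixels of `d^2.4 / (1 + d^2)` with
#' `d = |L_i - mu|`: a contrast estimator with divisive gain control whose
#' per-pixel term grows only as `d^0.4` for large deviations.
#'
#' @inheritParams lic
#' @return Scalar Meese-Summers contrast.
#' @export
meese_summers <- function(img, form = c("mean", "sum")) {
  form <- match.arg(form)
  s <- luminance_sample(img)
  term <- meese_summers_term(abs(s$L - s$mu))
  if (form == "mean") mean(term) else sum(term)
}

#' Meese-Summers contrast against a blurred reference
#'
#' As [meese_summers()] with `d = |L_i - B_i|`, `B` a heavily blurred copy
#' of the luminance image.
#'
#' @inheritParams lic_blur
#' @return Scalar blurred Meese-Summers contrast.
#' @export
meese_summers_blur <- function(img, form = c("mean", "sum"),
                               blur_sigma = NULL) {
  form <- match.arg(form)
  s <- luminance_sample(img, with_blur = TRUE, blur_sigma = blur_sigma)
  term <- meese_summers_term(abs(s$L - s$B))
  if (form == "mean") mean(term) else sum(term)
}

#' Names of the nine contrast-family metallicity statistics
#' @return Character vector of statistic names as used by
#'   [contrast_table()] and the model-observer roster.
#' @export
contrast_statistic_names <- function() {
  c("Sk", "DR", "rDR", "MC", "RMS", "LIC", "LICblur", "MS", "MSblur")
}

#' Tabulate all nine contrast statistics for a set of stimuli
#'
#' Before the estimators are evaluated, in-object luminance is clipped from
#' below at `floor` — a display black level. Without it, object pixels near
#' the silhouette (darkened by blur or by warp samples grazing the void)
#' approach zero and the ratio statistics (DR, rDR, MC) are driven entirely
#' by a few boundary pixels rather than by the object's luminance structure.
#'
#' @param images List of `stimulus_image` objects.
#' @param form Aggregation for the LIC/MS families.
#' @param floor Display black level: strictly positive lower clip applied to
#'   the in-object luminance sample.
#' @param rdr_n Sub-population size for the robust dynamic range.
#' @return Data.frame with one row per image: condition indices, view and
#'   the columns named by [contrast_statistic_names()].
#' @export
contrast_table <- function(images, form = c("mean", "sum"), floor = 0.02,
                           rdr_n = 10L) {
  form <- match.arg(form)
  stopifnot(floor > 0)
  do.call(rbind, lapply(images, function(img) {
    img$pixels[img$object_mask] <- pmax(img$pixels[img$object_mask], floor)
    data.frame(smoothness_index = img$smoothness_index,
               bumpiness_index = img$bumpiness_index,
               view_index = img$view_index,
               Sk = lum_skewness(img),
               DR = dynamic_range(img),
               rDR = robust_dynamic_range(img, n = rdr_n),
               MC = michelson_contrast(img),
               RMS = rms_contrast(img),
               LIC = lic(img, form),
               LICblur = lic_blur(img, form),
               MS = meese_summers(img, form),
               MSblur = meese_summers_blur(img, form))
  }))
}
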