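---
title: "Modelling metallicity perception from low-level image statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metallicity perception from low-level image statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalsim)
```

## The scientific problem

Metallicity — the visual quality that makes an object look like it is made
of metal — cannot plausibly be computed by inverting the optics of the
scene: estimating a surface's bi-directional reflectance function from a
single image is ill-posed. A long line of work in material perception
instead asks whether the visual system leans on *low-level image
statistics* as heuristics. `metalsim` packages one complete computational
version of that question for metallicity:

1. synthesize a two-dimensional stimulus space whose axes emulate the image
   consequences of two physical surface properties — the smoothness of a
   metal (blurring of the reflected environment) and the bumpiness of a
   transparent coating over it (a smooth random distortion of that
   reflection);
2. extract candidate decision statistics from every stimulus: radially
   averaged power spectra, steerable-pyramid level activations, and nine
   global-contrast estimators;
3. simulate noisy observers who judge pairs ("which looks more metallic?")
   and quadruples ("which pair differs more?") using one statistic each;
4. fit the standard psychophysical decision models — maximum-likelihood
   difference scaling (MLDS) and maximum-likelihood conjoint measurement
   (MLCM) with its nested independent/additive/saturated hypotheses — and
   a two-parameter metallicity model that weights fine-scale against
   coarse-scale pyramid responses.

Everything runs from code; no downloads or rendered scenes are required.

## The synthetic stimulus space

`stim_config()` fixes the study conditions. A stimulus is a 512 × 512
luminance image of a blob-shaped object on a black void. The base image is
random-phase noise with amplitude spectrum $\propto 1/f$ (the signature of
natural images; `base_spectral_exponent = 1`), multiplied through a
monotone point nonlinearity $u \mapsto u^{3}$ that concentrates luminance
into sparse, bright, highlight-like regions, lifted onto a small strictly
positive floor (0.005) inside the object. Two further ingredients deserve
explanation because they are choices of this package rather than textbook
defaults:

* **Anti-aliasing bandwidth** (`base_bandlimit_sigma = 0.5` px). A
  physically rendered image is bandlimited by the renderer's pixel filter;
  a raw $1/f$ noise field is not. Without this term the finest pyramid
  band is dominated by synthetic pixel noise that a bilinear warp then
  *removes*, reversing the direction the bumpiness axis must have.
* **Views as content resampling.** The original experiments rotate the
  object between presentations so observers cannot compare pixels.
  Statistically — which is all the downstream analyses see — rotation
  produces images with identical statistics and independent content, so a
  "view" here is an independent base-image draw. Geometric consistency
  across views is deliberately not modelled.

The **smoothness axis** Gaussian-blurs the image content and then
re-applies the object mask (roughness blurs the *reflection*, not the
silhouette). Defaults span 0 to 1% of the image width (≈ 5 px at 512),
spaced mildly superlinearly: past that range the finest band is dominated
by the fixed sharp silhouette and further blur no longer separates levels.

The **bumpiness axis** is a local-disarray warp: two Gaussian random
fields, smoothed to a 2-px correlation length, scaled to a target RMS
displacement, and used to resample the image bilinearly; samples that fall
outside the object read the black void. Two deliberate deviations from the
simplest construction:

* the displacement field is **tapered to zero at the silhouette** (the
  coating follows the object). An untapered field drags background zeros
  into the object, shifting the in-object mean by more than 5% and raising
  RMS contrast with bumpiness — both contrary to the separability this
  axis needs;
* the nonzero amplitudes start at 6 px rather than rising linearly from
  zero. Bilinear resampling always costs a little fine-scale energy; below
  about 6 px RMS the resampling loss exceeds the energy that warp shear
  creates, and the fine/coarse statistic would be non-monotone in
  amplitude. The original stimulus levels were themselves spaced for
  perceptual (not physical) equidistance by a difference-scaling
  pre-study, so a nonlinear physical spacing is in keeping.

These defaults were calibrated once, before the downstream analyses were
frozen, to reproduce the qualitative image-statistic trends of the
physical system: high-frequency spectral power and fine-scale activations
fall with blur; the fine/coarse activation difference rises with disarray;
luminance-histogram statistics are nearly invariant along the bumpiness
axis.

## Image statistics

**Radial spectra.** Images are windowed (2-D Hann by default; whole-frame,
since the black void contributes nothing except the silhouette edge), the
power spectrum is interpolated onto integer cycles-per-image bins with
linear inverse-distance weights, and bin areas are carried so that
`sum(power * area)` reproduces the non-DC energy exactly. The 23–53 cpi
band mean is the conventional high-frequency summary; `loglog_slope()`
fits the naturalistic $1/f$ power-law slope.

**Steerable pyramid.** `build_pyramid()` is a frequency-domain steerable
decomposition: raised-cosine (in log₂ radius) radial masks split each
octave, angular $|\cos|^{K-1}$ masks (normalized so their squares sum to
one) provide four orientation bands, and each recursion crops the central
quarter of the spectrum. The construction is an exact tight frame, so
reconstruction (`collapse_pyramid()`) and frame energy
(`pyramid_energy()`) are machine-precision identities — that is why this
flavour was chosen over filter-tap implementations. The scalar **level
activation** is
$A_\ell = \log \sum_k \mathrm{mean}\,|b_{\ell,k}|$: mean absolute
coefficient (robust to the sparse highlight outliers), summed over
orientations, natural log (the base only shifts the scale). `A1` (finest
level) is the smoothness statistic; `A1 − A4` — a log ratio, hence exactly
invariant to global luminance scaling — is the bumpiness statistic. An
all-zero level reports `-Inf` with a warning rather than a silent value.

**Contrast estimators.** Nine candidate metallicity statistics over the
in-object sample: skewness, dynamic range, robust dynamic range (mean of
the ten brightest over the ten dimmest), Michelson contrast, RMS
(population SD), local image contrast against the global mean and against
a heavily blurred copy (σ = image/8), and the Meese–Summers
gain-controlled contrast $\sum d^{2.4}/(1+d^2)$ in both variants. The
printed forms of the sum-type estimators are divided by $N$ by default so
values are image-size invariant; `form = "sum"` restores raw sums.
Population (1/N) moments throughout. `contrast_table()` additionally clips
the sample at a display black level (0.02) first: without it the ratio
statistics are driven entirely by a handful of near-zero pixels on the
blurred silhouette boundary.

## Simulated psychophysics

`enumerate_mlcm_pairs()` builds all 325 unordered pairs of the 5 × 5 grid;
a session presents each four times (1300 trials) with two *different*
views per trial. `enumerate_mlds_quadruples()` builds the 330
non-overlapping quadruples $a<b<c<d$ of 11 levels; because published
designs sometimes report slightly smaller counts without stating the
exclusion rule, an optional uniform subsample (e.g. to 310) is provided
rather than a guessed rule. A `model_observer()` carries one statistic and
a Gaussian decision noise; the conjoint decision variable is the statistic
difference, the difference-scaling variable compares absolute pair
differences, exact ties are split by a fair coin. The default simulation
noise is a tenth of the statistic's range over the stimulus set, which
produces fitted scales of a few d′ — the magnitude typical of
suprathreshold scaling data.

## Model fitting

Both tasks are Bernoulli likelihoods with a probit link, decision-noise SD
fixed at 1 and first levels anchored at 0, so estimates are d′ values.
MLCM design matrices contrast per-level indicators (independent: one
dimension; additive: both; saturated: one parameter per grid cell);
`fit_mlds()` uses the signed-difference linearization — responses recoded
so the design is linear in ψ — which is exact whenever the fitted scale is
monotone, with a direct optimizer of the absolute-value likelihood as a
fallback (`method = "optim"`; it is only accepted when it improves the
exact likelihood, which is also the likelihood always reported).
Separation (noise-free observers) is flagged and the estimate vector is
rescaled onto a |ψ| ≤ 10 box, preserving order. `lr_test()` compares
nested fits by the χ² approximation; the pipeline selects a model class at
α = 0.001. `bootstrap_ci()` case-resamples trials (percentile intervals);
`normalize_and_average()` divides each observer's pooled estimates by
their RMS before averaging — the normalization rule is this package's
choice.

A note on identifiability: a difference scale is identified only up to
sign (the likelihood sees only |ψ differences|), and on very small designs
the absolute-value likelihood has near-equal reflected local modes. Tests
therefore compare fits against exhaustive grid searches within the
monotone (identified) region, and the MLDS oracle uses 5 levels — the
smallest design with more than one quadruple.

## The two-parameter metallicity model

`metallicity_statistic()` is $m = a A_4 + b A_1$: coarse weight $a$, fine
weight $b$. `fit_weights_to_scale()` recovers $(a, b)$ from an observer's
additive conjoint scale by closed-form least squares of the additive cell
values against the view-averaged activations — after projecting the
activation surfaces onto the additive (row + column) subspace, because the
conjoint fit can only expose the additive part of the decision surface;
with the projection the noise-free inverse problem is exact.
`simulate_model_conjoint()` closes the loop: weighted statistic → noisy
observer → session → additive fit, with pure-fine `c(0, 1)` and
pure-coarse `c(1, 0)` reference models as special cases.

## What the synthetic space does and does not show

The generator reproduces the qualitative structure that matters to the
analyses: naturalistic spectra, monotone blur signatures, a view-robust
fine/coarse bumpiness signature, and histogram statistics that barely move
along the bumpiness axis. It does **not** reproduce rendered optics. Three
consequences worth stating plainly:

* A value-preserving warp cannot change the luminance histogram of content
  it merely rearranges; the contrast loss that coating bumpiness causes in
  physical stimuli (refraction spreads highlight energy) appears here only
  through the small resampling loss at the smoothest level. The negative
  bumpiness contributions of the dispersion statistics (RMS, LIC and
  relatives) are therefore a few hundredths of a d′ — reliably negative
  under session averaging, but far weaker than with rendered stimuli, and
  for the unblurred Meese–Summers estimator statistically
  indistinguishable from zero.
* The fine and coarse activation surfaces are nearly collinear over the
  grid (their additive parts differ mostly through the bumpiness axis), so
  the fine-vs-coarse weight *contrast* of the metallicity model is
  ill-conditioned: weight recovery through the full simulate-then-refit
  loop is unbiased to within 20% for observers of typical sensitivity
  (weights of magnitude ≲ 1, decision ranges of a few d′) but degrades for
  strongly saturating observers.
* Numeric agreement with published per-observer weights is out of reach by
  construction (those depend on human data and rendered activations);
  `reproduce_weight_table()` accepts such deposited data if present and
  otherwise skips cleanly.

## Problem sizes

The package's reference analyses use the full study geometry: 512-px
images, the 5 × 5 × 8 conjoint grid (200 images), 11-level
difference-scaling sets (176 images), 1300-trial sessions. Monte-Carlo
components use 20 seeds for recovery studies, 100–150 replications with
199 bootstrap resamples for interval calibration, and 12–24 averaged
sessions for direction checks of the smallest effects; difference-scaling
stimulus sets in the acceptance script are rendered at 128 px, where the
driving statistics behave identically. These sizes are the package's
choices for a desk-scale, fully reproducible analysis.

## A short example

```{r example, eval = FALSE}
cfg <- stim_config(image_size = 128, n_smoothness_levels = 3,
                   n_bumpiness_levels = 3, n_views = 4,
                   blur_sigmas = c(0, 1.5, 3),
                   disarray_amplitudes = c(0, 6, 8), master_seed = 1)
run <- run_pipeline(run_config(stimulus = cfg,
                               observers = c("A1", "RMS", "Sk"),
                               mlds_levels = 5),
                    out_dir = "metalsim-demo")
pipeline_report("metalsim-demo")
```

The report lists, per simulated observer, the conjoint model class
selected by the likelihood-ratio tests and the sign of each dimension's
contribution — the synthetic analogue of asking which image statistics
behave like human observers.
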