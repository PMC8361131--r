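# metalsim

Simulated psychophysics of **metallicity perception** — the visual quality
that makes an object look like metal — built on low-level image statistics.

Human observers judge metallicity robustly across viewpoints even though
recovering a surface's reflectance function from an image is intractable.
A computational account holds that the visual system relies on simple
image statistics instead. `metalsim` implements that account end to end
for a two-axis stimulus space in which:

* **metal smoothness** acts as a Gaussian blur of the reflected
  environment (rougher metal → blurrier reflection), and
* **coating bumpiness** acts as a *local disarray* warp — a smooth random
  pixel-displacement field distorting the reflection beneath a transparent
  coating.

The package synthesizes the stimulus space (512 × 512 luminance images of
an object in a black void, naturalistic 1/f spectra, eight statistically
equivalent "views" per condition), computes the candidate decision
statistics, simulates noisy observers performing the two classical tasks,
and fits the standard decision models:

* **MLDS** (maximum-likelihood difference scaling): perceptual scale
  values ψ in d′ units from quadruple judgments,
  `P(choose pair cd) = Φ(|ψ_d − ψ_c| − |ψ_b − ψ_a|)`;
* **MLCM** (maximum-likelihood conjoint measurement): nested
  *independent* / *additive* / *saturated* hypotheses for paired
  metallicity judgments,
  `Δ = (ψ^S(s_i) + ψ^B(b_j)) − (ψ^S(s_k) + ψ^B(b_l)) + ε`, `ε ~ N(0, 1)`,
  compared by likelihood-ratio tests;
* the **two-parameter metallicity model** `m = a·A4 + b·A1`, a weighted
  comparison of coarse (level 4) and fine (level 1) steerable-pyramid
  activations, fitted to each observer's conjoint scale.

Statistics on offer: radially averaged power spectra (with the 23–53
cycles-per-image band summary and log–log slopes), an exactly invertible
frequency-domain steerable pyramid (4 levels × 4 orientations) with scalar
level activations `A1..A4`, and nine global-contrast estimators
(skewness, dynamic range, robust dynamic range, Michelson, RMS, local
image contrast plain/blurred, Meese–Summers plain/blurred).

## Worked example

Render conditions from the default space, read off the two pyramid
statistics, then let a noisy observer who uses the finest-level activation
`A1` judge a full 1300-trial conjoint session:

```r
library(metalsim)
cfg <- stim_config(image_size = 256, n_views = 4, master_seed = 1)
img_smooth <- render_condition(1, 1, 1, cfg)  # smoothest, even coating
img_rough  <- render_condition(5, 1, 1, cfg)  # roughest metal
img_bumpy  <- render_condition(1, 5, 1, cfg)  # bumpiest coating

smoothness_statistic(img_smooth)   # A1 = -3.80
smoothness_statistic(img_rough)    # A1 = -6.17  (blur removes fine detail)
bumpiness_statistic(img_smooth)    # A1 - A4 = -0.68
bumpiness_statistic(img_bumpy)     # A1 - A4 = -0.25  (disarray adds it)

grid  <- render_grid(cfg)
stats <- activation_table(grid)
ses   <- build_mlcm_session(enumerate_mlcm_pairs(5, 5), 4, 4, seed = 2)
obs   <- model_observer("A1", default_noise_sd(stats, "A1"), seed = 3)
fit   <- fit_mlcm(simulate_responses(ses, obs, stats), "additive")
fit
#> Conjoint fit (additive): 1300 trials, 8 parameters, logLik -559.97
#>   psi_S: 0, -0.252, -1.092, -1.681, -2.097
#>   psi_B: 0, 1.017, 1.125, 1.299, 1.188
lr_test(fit_mlcm(simulate_responses(ses, obs, stats), "independent"), fit)
#> LR test: chi2 = 200.523, df = 4, p = 2.9e-42
```

Read: for an observer equating metallicity with fine detail, increasing
roughness lowers the metallicity scale by about 2 d′ across the axis,
bumpiness *raises* it by about 1 d′ (the warp adds fine detail), and the
likelihood-ratio test rejects the single-dimension (independent) model
decisively — the additive conjoint structure of both stimulus axes is
recovered from the simulated trials.

`run_pipeline(run_config(), out_dir)` runs the whole study — stimuli,
statistics tables, difference-scaling and conjoint simulations for a
roster of observers, model selection at α = 0.001, metallicity-weight
fits, CSV/JSON artifacts and summary figures — and
`pipeline_report(out_dir)` tabulates which image statistics behave like
additive observers and which are blind to the bumpiness axis.

See the vignette (`vignettes/metallicity-methods.Rmd`) for the models,
the generator's design decisions, and known limitations of the synthetic
space.

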