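# Shared fixtures. Heavy stimulus statistics are computed lazily once per
# test run and cached here, so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  val <- .fixture_cache[[key]]
  if (is.null(val)) {
    val <- force(expr)
    .fixture_cache[[key]] <- val
  }
  val
}

# small configuration for fast unit tests (96 px supports a 4-level pyramid)
small_config <- function(master_seed = 42L, ...) {
  stim_config(image_size = 96L, n_smoothness_levels = 3L,
              n_bumpiness_levels = 3L, n_views = 4L,
              blur_sigmas = c(0, 1.5, 3), disarray_amplitudes = c(0, 6, 8),
              master_seed = master_seed, ...)
}

# hand-built stimulus image with prescribed in-mask values, for the contrast
# estimators' hand-computed examples
toy_image <- function(values, n = 8L) {
  px <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  stopifnot(length(values) <= n * n)
  idx <- seq_along(values)
  px[idx] <- values
  mask[idx] <- TRUE
  metalsim:::new_stimulus_image(px, mask, 1L, 1L, 1L, 0L)
}

# statistics table for a synthetic additive observer on a K x K grid:
# psi values realized directly as statistic values (no images involved)
synthetic_stats_table <- function(psi_s, psi_b, n_views = 8L) {
  tab <- expand.grid(smoothness_index = seq_along(psi_s),
                     bumpiness_index = seq_along(psi_b),
                     view_index = seq_len(n_views))
  tab$stat <- psi_s[tab$smoothness_index] + psi_b[tab$bumpiness_index]
  tab
}

# direct Bernoulli log-likelihood of an additive conjoint parameterization
mlcm_loglik <- function(trials, psi_s, psi_b) {
  dv <- psi_s[trials$s1] + psi_b[trials$b1] -
    psi_s[trials$s2] - psi_b[trials$b2]
  p <- pmin(pmax(pnorm(dv), 1e-12), 1 - 1e-12)
  sum(trials$response * log(p) + (1 - trials$response) * log(1 - p))
}

# direct Bernoulli log-likelihood of an MLDS parameterization (exact, with
# absolute values)
mlds_loglik <- function(trials, psi) {
  dv <- abs(psi[trials$d] - psi[trials$c]) - abs(psi[trials$b] - psi[trials$a])
  p_cd <- pmin(pmax(pnorm(dv), 1e-12), 1 - 1e-12)
  y_cd <- 1 - trials$response
  sum(y_cd * log(p_cd) + (1 - y_cd) * log(1 - p_cd))
}
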