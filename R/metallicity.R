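# The two-parameter metallicity model: a weighted comparison of the
# coarsest and finest steerable-pyramid level activations,
# m = a * A4 + b * A1. With (a, b) free, the model spans observers who
# equate metallicity with fine detail (b > 0), with coarse structure
# (a > 0), or with their inverses, capturing the individual differences
# seen in metallicity judgments.

#' Weighted fine/coarse metallicity statistic
#'
#' `m = a * A_coarse + b * A_fine`, with the activations from
#' [level_activations()] (fine = level 1, coarse = the last level).
#'
#' @param img A `stimulus_image` or square numeric matrix.
#' @param weights Numeric `c(a, b)`: weight `a` on the coarsest level,
#'   weight `b` on the finest.
#' @param n_levels,n_orientations Pyramid shape.
#' @return Scalar metallicity statistic.
#' @export
metallicity_statistic <- function(img, weights, n_levels = 4L,
                                  n_orientations = 4L) {
  stopifnot(length(weights) == 2L, is.numeric(weights))
  a <- level_activations(build_pyramid(img, n_levels, n_orientations))
  unname(weights[1] * a[n_levels] + weights[2] * a[1])
}

# view-averaged A1/A4 per grid cell, aligned with a K_s x K_b grid
cell_activations <- function(act_table, K_s, K_b, n_levels = 4L) {
  a1 <- matrix(NA_real_, K_s, K_b)
  a4 <- matrix(NA_real_, K_s, K_b)
  coarse <- paste0("A", n_levels)
  for (s in seq_len(K_s)) for (b in seq_len(K_b)) {
    sel <- act_table$smoothness_index == s & act_table$bumpiness_index == b
    if (!any(sel)) stop("activation table is missing cell (", s, ", ", b,
                        ")", call. = FALSE)
    a1[s, b] <- mean(act_table$A1[sel])
    a4[s, b] <- mean(act_table[[coarse]][sel])
  }
  list(a1 = a1, a4 = a4)
}

#' Fit metallicity weights to an observer's conjoint scale
#'
#' Least-squares fit, in scale space, of the observer's additive cell
#' values `psi_S(i) + psi_B(j)` against the view-averaged coarse and fine
#' activations of each grid cell, with a free intercept (absorbed by the
#' anchoring convention). Because the conjoint fit can only expose the
#' additive part of the decision surface, the activation predictors are
#' first projected onto the additive (row + column) subspace of the grid,
#' which makes the noise-free inverse problem exact even when the raw
#' activations carry smoothness-by-bumpiness interactions. The solution is
#' closed-form and deterministic.
#'
#' @param observer_fit An additive (or independent) `conjoint_fit`.
#' @param act_table Activation table from [activation_table()] covering the
#'   fit's grid.
#' @param n_levels Pyramid depth used for the activations (coarse level).
#' @return An object of class `metallicity_weights`: `a` (coarse weight),
#'   `b` (fine weight), `intercept`, `loss` (residual sum of squares),
#'   `fit_method`.
#' @export
fit_weights_to_scale <- function(observer_fit, act_table, n_levels = 4L) {
  stopifnot(inherits(observer_fit, "conjoint_fit"))
  if (observer_fit$model_class == "saturated")
    stop("weight fitting expects an additive or independent fit",
         call. = FALSE)
  K_s <- observer_fit$grid["K_s"]
  K_b <- observer_fit$grid["K_b"]
  cells <- cell_activations(act_table, K_s, K_b, n_levels)
  additive_part <- function(M) {
    outer(rowMeans(M), rep(1, ncol(M))) +
      outer(rep(1, nrow(M)), colMeans(M)) - mean(M)
  }
  y <- as.vector(outer(observer_fit$psi_s, observer_fit$psi_b, `+`))
  X <- cbind(1, as.vector(additive_part(cells$a4)),
             as.vector(additive_part(cells$a1)))
  qrX <- qr(X)
  if (qrX$rank < 3L)
    stop("rank-deficient predictors: coarse and fine activations are ",
         "collinear over the grid", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  structure(list(a = unname(beta[2]), b = unname(beta[3]),
                 intercept = unname(beta[1]),
                 loss = sum(res^2), fit_method = "scale_space_ls"),
            class = "metallicity_weights")
}

#' @export
print.metallicity_weights <- function(x, ...) {
  cat(sprintf(
    "Metallicity weights: coarse a = %.4g, fine b = %.4g (RSS %.4g, %s)\n",
    x$a, x$b, x$loss, x$fit_method))
  invisible(x)
}

#' Run the weighted metallicity model through a conjoint session
#'
#' Attaches the weighted statistic `a * A_coarse + b * A_fine` to the
#' activation table, simulates the session with a noisy model observer and
#' fits the additive conjoint model — the full loop that turns model
#' weights into the same coordinates as observer conjoint scales. The pure
#' fine-only (`c(0, 1)`) and coarse-only (`c(1, 0)`) special cases give the
#' single-level reference models.
#'
#' @param weights Numeric `c(a, b)` as in [metallicity_statistic()].
#' @param session A pair session from [build_mlcm_session()].
#' @param act_table Activation table covering the session's grid and views.
#' @param noise_sd Decision noise SD (default 1, so the fitted scale is in
#'   units of the statistic).
#' @param seed Integer seed for the decision noise.
#' @param n_levels Pyramid depth used for the activations.
#' @return The additive `conjoint_fit` of the simulated responses.
#' @export
simulate_model_conjoint <- function(weights, session, act_table,
                                    noise_sd = 1, seed = 1L, n_levels = 4L) {
  stopifnot(length(weights) == 2L)
  tab <- act_table
  tab$m <- weights[1] * tab[[paste0("A", n_levels)]] + weights[2] * tab$A1
  obs <- model_observer("m", noise_sd = noise_sd, seed = seed)
  fit_mlcm(simulate_responses(session, obs, tab), "additive")
}

#' Report optimal weights for externally collected observer fits
#'
#' Companion for deposited experimental data: given a directory containing
#' per-observer additive conjoint scales (CSV with columns `observer`,
#' `dimension` (`S`/`B`), `level`, `psi`) and an activation table for the
#' same rendered stimuli (CSV with `smoothness_index`, `bumpiness_index`,
#' `view_index`, `A1..A4`), recomputes each observer's optimal fine/coarse
#' weights. The report is qualitative: synthetic stimuli cannot reproduce
#' the deposited activations numerically, so no equality with published
#' values is asserted.
#'
#' @param deposited_dir Directory with `observer_scales.csv` and
#'   `activations.csv`.
#' @return Data.frame with one row per observer (`observer`, `L1`, `L4`),
#'   or `NULL` invisibly (with a message) when the directory or files are
#'   absent.
#' @export
reproduce_weight_table <- function(deposited_dir) {
  sc_path <- file.path(deposited_dir, "observer_scales.csv")
  ac_path <- file.path(deposited_dir, "activations.csv")
  if (!dir.exists(deposited_dir) || !file.exists(sc_path) ||
      !file.exists(ac_path)) {
    message("optional deposited data not present; skipping weight table")
    return(invisible(NULL))
  }
  scales <- utils::read.csv(sc_path)
  acts <- utils::read.csv(ac_path)
  need_s <- c("observer", "dimension", "level", "psi")
  if (!all(need_s %in% names(scales)))
    stop("observer_scales.csv must have columns: ",
         paste(need_s, collapse = ", "), call. = FALSE)
  if (!all(c("smoothness_index", "bumpiness_index", "A1", "A4") %in%
           names(acts)))
    stop("activations.csv is missing activation columns", call. = FALSE)
  out <- lapply(split(scales, scales$observer), function(sc) {
    psi_s <- sc$psi[sc$dimension == "S"][order(sc$level[sc$dimension == "S"])]
    psi_b <- sc$psi[sc$dimension == "B"][order(sc$level[sc$dimension == "B"])]
    fake_fit <- structure(list(model_class = "additive", psi_s = psi_s,
                               psi_b = psi_b,
                               grid = c(K_s = length(psi_s),
                                        K_b = length(psi_b)),
                               n_trials = NA_integer_, n_parameters =
                                 length(psi_s) + length(psi_b) - 2L),
                          class = "conjoint_fit")
    w <- fit_weights_to_scale(fake_fit, acts)
    data.frame(observer = sc$observer[1], L1 = w$b, L4 = w$a)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
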