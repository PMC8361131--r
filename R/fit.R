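# Maximum-likelihood fitting of perceptual scales.
#
# Both tasks reduce to binomial probit GLMs in which the linear predictor
# is a signed combination of per-level scale values psi. Identifiability is
# obtained by the standard convention: the first level of each dimension is
# anchored at 0 and the decision-noise SD is fixed at 1, so estimates are in
# d-prime units.

# fit a probit GLM without intercept, catching separation warnings
probit_fit <- function(X, y) {
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(link = "probit"),
                   intercept = FALSE),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- fit$coefficients
  # complete separation inflates estimates without bound; rescale the whole
  # vector onto a |psi| <= 10 box (preserving the estimates' ordering) and
  # flag
  clip <- 10
  if (separated || any(abs(coefs) > clip, na.rm = TRUE)) {
    separated <- TRUE
    mx <- max(abs(coefs), na.rm = TRUE)
    if (is.finite(mx) && mx > clip) coefs <- coefs * (clip / mx)
    warning("complete or quasi-complete separation: scale estimates clipped",
            call. = FALSE)
  }
  eta <- as.vector(X %*% ifelse(is.na(coefs), 0, coefs))
  p <- stats::pnorm(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  list(coefficients = ifelse(is.na(coefs), 0, coefs), log_likelihood = ll,
       separated = separated)
}

#' Fit a perceptual scale by maximum-likelihood difference scaling
#'
#' Estimates per-level scale values `psi` from quadruple judgments by
#' maximizing the Bernoulli likelihood with
#' `P(choose pair cd) = Phi(|psi_d - psi_c| - |psi_b - psi_a|)` under the
#' anchoring `psi_1 = 0`, noise SD 1. The default `"glm"` method uses the
#' signed-difference linearization (responses recoded so the design matrix
#' is linear in `psi`), exact whenever the fitted scale is monotone in level
#' — the standard GLM formulation of difference scaling; `"optim"` maximizes
#' the exact absolute-value likelihood directly from the GLM start.
#'
#' @param trials A quadruple session with simulated or collected `response`
#'   (1 = pair (a,b) judged the larger difference).
#' @param method `"glm"` (default) or `"optim"`.
#' @return An object of class `perceptual_scale`: `psi` (length = number of
#'   levels, `psi[1] == 0`), `dimension`, `log_likelihood`, `n_trials`,
#'   `separated` flag; confidence intervals may be attached by
#'   [bootstrap_ci()].
#' @export
fit_mlds <- function(trials, method = c("glm", "optim")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(trials),
            all(c("a", "b", "c", "d", "response") %in% names(trials)))
  if (anyNA(trials$response)) stop("trials have missing responses",
                                   call. = FALSE)
  K <- max(trials[, c("a", "b", "c", "d")])
  if (K < 4L || nrow(trials) < K - 1L)
    stop("insufficient quadruples to constrain ", K, " levels",
         call. = FALSE)
  lev <- sort(unique(unlist(trials[, c("a", "b", "c", "d")])))
  if (!identical(lev, seq_len(K)))
    stop("levels must cover 1..K with every level appearing", call. = FALSE)
  n <- nrow(trials)
  X <- matrix(0, n, K)
  idx <- cbind(seq_len(n), trials$a); X[idx] <- X[idx] + 1
  idx <- cbind(seq_len(n), trials$b); X[idx] <- X[idx] - 1
  idx <- cbind(seq_len(n), trials$c); X[idx] <- X[idx] - 1
  idx <- cbind(seq_len(n), trials$d); X[idx] <- X[idx] + 1
  X <- X[, -1, drop = FALSE] # anchor psi_1 = 0
  y <- 1L - trials$response  # 1 = chose pair (c,d)
  fit <- probit_fit(X, y)
  psi <- c(0, fit$coefficients)
  # the reported likelihood is always the exact absolute-value one, so the
  # linearized and direct methods are comparable
  nll <- function(par) {
    p <- c(0, par)
    dv <- abs(p[trials$d] - p[trials$c]) - abs(p[trials$b] - p[trials$a])
    pr <- pmin(pmax(stats::pnorm(dv), 1e-12), 1 - 1e-12)
    -sum(y * log(pr) + (1 - y) * log(1 - pr))
  }
  ll <- -nll(psi[-1])
  if (method == "optim") {
    opt <- stats::optim(psi[-1], nll, method = "BFGS",
                        control = list(maxit = 500))
    if (-opt$value >= ll) {
      psi <- c(0, opt$par)
      ll <- -opt$value
    }
  }
  structure(list(psi = unname(psi),
                 dimension = if ("dim" %in% names(trials))
                   trials$dim[1] else NA_character_,
                 log_likelihood = ll, n_trials = n, n_levels = K,
                 n_parameters = K - 1L,
                 method = method, separated = fit$separated),
            class = "perceptual_scale")
}

#' @export
print.perceptual_scale <- function(x, ...) {
  cat(sprintf("Difference scale (%s), %d levels, %d trials, logLik %.2f\n",
              x$dimension, x$n_levels, x$n_trials, x$log_likelihood))
  est <- data.frame(level = seq_len(x$n_levels), psi = round(x$psi, 3))
  if (!is.null(x$ci_low)) {
    est$ci_low <- round(x$ci_low, 3)
    est$ci_high <- round(x$ci_high, 3)
  }
  print(est, row.names = FALSE)
  if (x$separated) cat("  (separation: estimates clipped)\n")
  invisible(x)
}

# design matrix for a conjoint model class; columns are named
mlcm_design <- function(trials, model_class, K_s, K_b,
                        dimension = "smoothness") {
  n <- nrow(trials)
  add_cols <- function(lev1, lev2, K, prefix) {
    M <- matrix(0, n, K)
    idx <- cbind(seq_len(n), lev1); M[idx] <- M[idx] + 1
    idx <- cbind(seq_len(n), lev2); M[idx] <- M[idx] - 1
    M <- M[, -1, drop = FALSE]
    colnames(M) <- paste0(prefix, seq_len(K)[-1])
    M
  }
  switch(model_class,
    independent = {
      if (dimension == "smoothness")
        add_cols(trials$s1, trials$s2, K_s, "s")
      else add_cols(trials$b1, trials$b2, K_b, "b")
    },
    additive = cbind(add_cols(trials$s1, trials$s2, K_s, "s"),
                     add_cols(trials$b1, trials$b2, K_b, "b")),
    saturated = {
      cell1 <- (trials$s1 - 1L) * K_b + trials$b1
      cell2 <- (trials$s2 - 1L) * K_b + trials$b2
      M <- matrix(0, n, K_s * K_b)
      idx <- cbind(seq_len(n), cell1); M[idx] <- M[idx] + 1
      idx <- cbind(seq_len(n), cell2); M[idx] <- M[idx] - 1
      M <- M[, -1, drop = FALSE]
      colnames(M) <- paste0("cell", seq_len(K_s * K_b)[-1])
      M
    },
    stop("unknown model class: ", model_class, call. = FALSE))
}

#' Fit a conjoint-measurement decision model
#'
#' Maximum-likelihood fit of the nested conjoint hypotheses to paired
#' metallicity judgments, by binomial probit regression on signed level
#' indicators: the probability of choosing stimulus 1 is `Phi(Delta)` where
#' `Delta` contrasts the two stimuli's scale values under the chosen model
#' class — one dimension only (*independent*), the sum of both dimensions'
#' contributions (*additive*), or one value per grid cell (*saturated*).
#' First levels (first cell for saturated) are anchored at 0 and the
#' decision-noise SD is 1, so estimates are d-prime values.
#'
#' @param trials A pair session with responses (1 = stimulus 1 chosen).
#' @param model_class `"independent"`, `"additive"` or `"saturated"`.
#' @param dimension For the independent class: `"auto"` (default, pick the
#'   dimension with the higher likelihood), `"smoothness"` or
#'   `"bumpiness"`.
#' @param grid Optional `c(K_s, K_b)`; defaults to the maxima observed in
#'   the trials.
#' @return An object of class `conjoint_fit` with elements `psi_s`, `psi_b`
#'   (additive/independent; the unused dimension is all zero for
#'   independent), or `psi_cell` (`K_s x K_b` matrix, saturated), plus
#'   `log_likelihood`, `n_parameters`, `model_class`, `n_trials`.
#' @export
fit_mlcm <- function(trials,
                     model_class = c("additive", "independent", "saturated"),
                     dimension = c("auto", "smoothness", "bumpiness"),
                     grid = NULL) {
  model_class <- match.arg(model_class)
  dimension <- match.arg(dimension)
  stopifnot(is.data.frame(trials),
            all(c("s1", "b1", "s2", "b2", "response") %in% names(trials)))
  if (anyNA(trials$response)) stop("trials have missing responses",
                                   call. = FALSE)
  K_s <- if (is.null(grid)) max(trials$s1, trials$s2) else grid[1]
  K_b <- if (is.null(grid)) max(trials$b1, trials$b2) else grid[2]
  y <- trials$response
  fit_one <- function(class, dim) {
    X <- mlcm_design(trials, class, K_s, K_b, dim)
    c(probit_fit(X, y), list(X = X))
  }
  if (model_class == "independent" && dimension == "auto") {
    fs <- fit_one("independent", "smoothness")
    fb <- fit_one("independent", "bumpiness")
    if (fs$log_likelihood >= fb$log_likelihood) {
      fit <- fs; dimension <- "smoothness"
    } else {
      fit <- fb; dimension <- "bumpiness"
    }
  } else {
    fit <- fit_one(model_class,
                   if (dimension == "auto") "smoothness" else dimension)
  }
  out <- list(model_class = model_class,
              log_likelihood = fit$log_likelihood,
              n_parameters = ncol(fit$X),
              n_trials = nrow(trials),
              grid = c(K_s = K_s, K_b = K_b),
              separated = fit$separated)
  cf <- fit$coefficients
  if (model_class == "saturated") {
    out$psi_cell <- matrix(c(0, cf), K_s, K_b, byrow = TRUE)
    dimnames(out$psi_cell) <- list(paste0("s", seq_len(K_s)),
                                   paste0("b", seq_len(K_b)))
  } else {
    psi_s <- numeric(K_s)
    psi_b <- numeric(K_b)
    sidx <- grep("^s", names(cf)); bidx <- grep("^b", names(cf))
    if (length(sidx)) psi_s[-1] <- cf[sidx]
    if (length(bidx)) psi_b[-1] <- cf[bidx]
    out$psi_s <- psi_s
    out$psi_b <- psi_b
    if (model_class == "independent") out$dimension <- dimension
  }
  structure(out, class = "conjoint_fit")
}

#' @export
print.conjoint_fit <- function(x, ...) {
  cat(sprintf("Conjoint fit (%s): %d trials, %d parameters, logLik %.2f\n",
              x$model_class, x$n_trials, x$n_parameters, x$log_likelihood))
  if (x$model_class == "saturated") {
    print(round(x$psi_cell, 3))
  } else {
    cat("  psi_S:", paste(round(x$psi_s, 3), collapse = ", "), "\n")
    cat("  psi_B:", paste(round(x$psi_b, 3), collapse = ", "), "\n")
  }
  if (x$separated) cat("  (separation: estimates clipped)\n")
  invisible(x)
}

#' Likelihood-ratio test between nested conjoint fits
#'
#' `2 (LL_full - LL_nested)` referred to a chi-square with degrees of
#' freedom equal to the parameter-count difference; the conventional test
#' for whether the second stimulus dimension (independent vs additive) or
#' their interaction (additive vs saturated) contributes to the judgments.
#'
#' @param nested,full `conjoint_fit`s (or `perceptual_scale`s) fitted to the
#'   same trials, the first nested in the second.
#' @return List of class `lr_test`: `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(nested, full) {
  if (full$n_trials != nested$n_trials)
    stop("fits are not on the same trials", call. = FALSE)
  df <- full$n_parameters - nested$n_parameters
  if (is.null(df) || length(df) == 0 || df < 1)
    stop("`full` must have more parameters than `nested`", call. = FALSE)
  stat <- 2 * (full$log_likelihood - nested$log_likelihood)
  if (stat < -1e-6)
    warning("nested likelihood exceeds full: optimizer tolerance exceeded",
            call. = FALSE)
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("LR test: chi2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Bootstrap confidence intervals for scale estimates
#'
#' Case-resamples trials with replacement, refits, and returns percentile
#' intervals per parameter. Works for both conjoint (pair) and
#' difference-scaling (quadruple) sessions.
#'
#' @param trials Trial data.frame with responses.
#' @param model_class Conjoint model class, ignored for quadruple trials.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return The point-estimate fit with `ci_low`/`ci_high` attached (vectors
#'   over the pooled parameter vector: `psi` for difference scaling,
#'   `c(psi_s, psi_b)` or `psi_cell` for conjoint fits) and the bootstrap
#'   draws in `boot_draws`.
#' @export
bootstrap_ci <- function(trials, model_class = "additive", n_boot = 1000L,
                         seed = 1L, level = 0.95) {
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  is_mlds <- "a" %in% names(trials) && "dim" %in% names(trials)
  refit <- function(tr) {
    if (is_mlds) fit_mlds(tr)
    else fit_mlcm(tr, model_class,
                  dimension = if (model_class == "independent") "auto"
                  else "auto")
  }
  point <- suppressWarnings(refit(trials))
  pooled <- function(f) {
    if (is_mlds) f$psi
    else if (f$model_class == "saturated") as.vector(f$psi_cell)
    else c(f$psi_s, f$psi_b)
  }
  n <- nrow(trials)
  draws <- matrix(NA_real_, n_boot, length(pooled(point)))
  withr::with_seed(derive_seed(seed, "bootstrap"), {
    for (i in seq_len(n_boot)) {
      tr <- trials[sample.int(n, n, replace = TRUE), ]
      draws[i, ] <- suppressWarnings(pooled(refit(tr)))
    }
  })
  alpha <- (1 - level) / 2
  point$ci_low <- apply(draws, 2, stats::quantile, probs = alpha)
  point$ci_high <- apply(draws, 2, stats::quantile, probs = 1 - alpha)
  point$boot_draws <- draws
  point$n_boot <- as.integer(n_boot)
  point
}

#' Normalize conjoint fits and average across observers
#'
#' Each fit's pooled parameter vector `c(psi_s, psi_b)` is divided by the
#' root-mean-square of its entries (making the averaging insensitive to each
#' observer's overall sensitivity), then averaged elementwise.
#'
#' @param fits List of additive/independent `conjoint_fit`s on the same
#'   grid.
#' @return List with `psi_s`, `psi_b` (means of normalized estimates) and
#'   `sem_s`, `sem_b` (standard errors of the mean; 0 for a single fit).
#' @export
normalize_and_average <- function(fits) {
  stopifnot(length(fits) >= 1L)
  norm_one <- function(f) {
    v <- c(f$psi_s, f$psi_b)
    r <- sqrt(mean(v^2))
    if (r == 0) stop("cannot normalize an all-zero fit", call. = FALSE)
    list(s = f$psi_s / r, b = f$psi_b / r)
  }
  ns <- lapply(fits, norm_one)
  S <- do.call(rbind, lapply(ns, `[[`, "s"))
  B <- do.call(rbind, lapply(ns, `[[`, "b"))
  sem <- function(M) {
    if (nrow(M) < 2L) return(rep(0, ncol(M)))
    apply(M, 2, stats::sd) / sqrt(nrow(M))
  }
  list(psi_s = colMeans(S), psi_b = colMeans(B),
       sem_s = sem(S), sem_b = sem(B), n = length(fits))
}

#' Serialize a fit to JSON
#'
#' @param fit A `perceptual_scale` or `conjoint_fit`.
#' @param path Output path.
#' @param extra Optional named list merged into the record (e.g. seeds,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, extra = NULL) {
  rec <- unclass(fit)
  rec$boot_draws <- NULL
  if (!is.null(extra)) rec <- c(rec, extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
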