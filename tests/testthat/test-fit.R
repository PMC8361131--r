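simulate_mlds_session <- function(psi_true, n_views = 8, noise_sd = 1,
                                  seed = 1, reps = 1) {
  K <- length(psi_true)
  quads <- enumerate_mlds_quadruples(K)
  quads <- quads[rep(seq_len(nrow(quads)), reps), ]
  ses <- build_mlds_session(quads, "smoothness", n_views, seed = seed)
  tab <- expand.grid(smoothness_index = seq_len(K), bumpiness_index = 1L,
                     view_index = seq_len(n_views))
  tab$stat <- psi_true[tab$smoothness_index]
  simulate_responses(ses, model_observer("stat", noise_sd, seed + 1), tab)
}

simulate_mlcm_session <- function(psi_s, psi_b, noise_sd = 1, seed = 1,
                                  n_views = 8, reps = 4) {
  pairs <- enumerate_mlcm_pairs(length(psi_s), length(psi_b))
  ses <- build_mlcm_session(pairs, reps, n_views, seed = seed)
  tab <- synthetic_stats_table(psi_s, psi_b, n_views)
  simulate_responses(ses, model_observer("stat", noise_sd, seed + 1), tab)
}

test_that("difference scaling recovers a noise-free scale's ordering", {
  ses <- simulate_mlds_session(seq(0, 4, length.out = 11), noise_sd = 0)
  fit <- suppressWarnings(fit_mlds(ses))
  expect_identical(fit$psi[1], 0)
  expect_true(fit$separated)
  expect_true(all(diff(fit$psi) > 0))
  expect_identical(order(fit$psi), 1:11)
})

test_that("difference scaling recovers a linear scale under noise", {
  errs <- vapply(1:6, function(s) {
    psi_true <- seq(0, 6, length.out = 11)
    ses <- simulate_mlds_session(psi_true, noise_sd = 1, seed = 100 + s)
    mean(abs(fit_mlds(ses)$psi - psi_true))
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("difference scaling enforces its design preconditions", {
  ses <- simulate_mlds_session(c(0, 1, 2, 3, 4))
  expect_error(fit_mlds(ses[1, ]), "insufficient")
  bad <- ses; bad$response[1] <- NA
  expect_error(fit_mlds(bad), "missing")
})

test_that("the exact-likelihood optimizer agrees with the linearized fit", {
  ses <- simulate_mlds_session(seq(0, 4, length.out = 7), seed = 3,
                               reps = 3)
  f_glm <- fit_mlds(ses, "glm")
  f_opt <- fit_mlds(ses, "optim")
  expect_gte(f_opt$log_likelihood, f_glm$log_likelihood - 1e-6)
  expect_lt(max(abs(f_opt$psi - f_glm$psi)), 0.1)
})

test_that("MLDS estimates match an exhaustive likelihood grid search", {
  # independent oracle: exhaustive refinement search of the exact
  # absolute-value likelihood on a small problem (5 levels, 40 trials)
  ses <- simulate_mlds_session(c(0, 0.6, 1.3, 1.9, 2.6), noise_sd = 1,
                               seed = 11, reps = 8)
  ses <- ses[1:40, ]
  fit <- fit_mlds(ses, "optim")
  # log-likelihood of many candidate parameter vectors at once
  ll_many <- function(G) {
    P <- cbind(0, G)
    dv <- 0
    out <- numeric(nrow(G))
    y_cd <- 1 - ses$response
    ll <- 0
    for (t in seq_len(nrow(ses))) {
      d <- abs(P[, ses$d[t]] - P[, ses$c[t]]) -
        abs(P[, ses$b[t]] - P[, ses$a[t]])
      p <- pmin(pmax(pnorm(d), 1e-12), 1 - 1e-12)
      ll <- ll + if (y_cd[t] == 1) log(p) else log(1 - p)
    }
    ll
  }
  make_grid <- function(centers, step, span) {
    as.matrix(do.call(expand.grid, lapply(seq_len(ncol(centers)),
      function(j) seq(min(centers[, j]) - span, max(centers[, j]) + span,
                      by = step))))
  }
  # coarse exhaustive pass, then an exhaustive 0.05 grid around each of the
  # top basins; the absolute-value likelihood has reflected modes outside
  # the identified (monotone) region, so the argmax comparison is made over
  # monotone candidates while the likelihood bound uses every candidate
  best <- list(ll = -Inf, par = NULL)
  best_mono <- list(ll = -Inf, par = NULL)
  consider <- function(G, ll) {
    i <- which.max(ll)
    if (ll[i] > best$ll) best <<- list(ll = ll[i], par = G[i, ])
    mono <- G[, 1] >= 0 &
      rowSums(G[, -1, drop = FALSE] < G[, -ncol(G), drop = FALSE]) == 0
    if (any(mono)) {
      j <- which(mono)[which.max(ll[mono])]
      if (ll[j] > best_mono$ll)
        best_mono <<- list(ll = ll[j], par = G[j, ])
    }
  }
  G0 <- make_grid(matrix(1.5, 1, 4), step = 0.25, span = 2.5)
  ll0 <- ll_many(G0)
  consider(G0, ll0)
  tops <- G0[order(ll0, decreasing = TRUE)[1:20], , drop = FALSE]
  for (i in seq_len(nrow(tops))) {
    G1 <- make_grid(tops[i, , drop = FALSE], step = 0.05, span = 0.25)
    consider(G1, ll_many(G1))
  }
  # the fitted scale is a true maximum: no grid point beats it
  expect_gte(fit$log_likelihood, best$ll - 1e-6)
  # and it coincides with the exhaustive optimum of the identified region
  expect_lt(max(abs(fit$psi[-1] - best_mono$par)), 0.1)
})

test_that("conjoint fitting recovers additive observers at session scale", {
  psi_s <- c(0, 1, 2, 3, 4)
  psi_b <- c(0, -0.5, -1, -1.5, -2)
  errs <- vapply(1:6, function(s) {
    ses <- simulate_mlcm_session(psi_s, psi_b, seed = 200 + s)
    f <- fit_mlcm(ses, "additive")
    mean(abs(c(f$psi_s - psi_s, f$psi_b - psi_b)))
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("an independent observer yields bumpiness estimates near zero", {
  ses <- simulate_mlcm_session(c(0, 1, 2, 3, 4), rep(0, 5), seed = 31)
  boot <- suppressWarnings(bootstrap_ci(ses, "additive", n_boot = 200,
                                        seed = 5))
  # bumpiness entries (positions 6..10 of the pooled vector) bracket zero
  b_idx <- 6:10
  expect_true(all(boot$ci_low[b_idx] <= 0 & boot$ci_high[b_idx] >= 0))
})

test_that("conjoint fits are invariant to trial order", {
  ses <- simulate_mlcm_session(c(0, 1, 2), c(0, -1, -2), seed = 8, reps = 2)
  f1 <- fit_mlcm(ses, "additive")
  f2 <- fit_mlcm(ses[rev(seq_len(nrow(ses))), ], "additive")
  expect_equal(f1$psi_s, f2$psi_s, tolerance = 1e-8)
  expect_equal(f1$psi_b, f2$psi_b, tolerance = 1e-8)
})

test_that("degenerate all-identical responses warn but do not crash", {
  ses <- simulate_mlcm_session(c(0, 1, 2), c(0, 0, 0), noise_sd = 0,
                               seed = 2, reps = 1)
  ses$response <- 1L
  expect_warning(fit_mlcm(ses, "additive"), "separation")
})

test_that("nested model likelihoods are ordered and parameters counted", {
  ses <- simulate_mlcm_session(c(0, 1, 2, 3, 4), c(0, -0.5, -1, -1.5, -2),
                               seed = 17)
  f_ind <- fit_mlcm(ses, "independent")
  f_add <- fit_mlcm(ses, "additive")
  f_sat <- fit_mlcm(ses, "saturated")
  expect_identical(f_ind$n_parameters, 4L)
  expect_identical(f_add$n_parameters, 8L)
  expect_identical(f_sat$n_parameters, 24L)
  expect_lte(f_ind$log_likelihood, f_add$log_likelihood + 1e-6)
  expect_lte(f_add$log_likelihood, f_sat$log_likelihood + 1e-6)
  lr <- lr_test(f_ind, f_add)
  expect_identical(lr$df, 4L)
  expect_lt(lr$p_value, 0.001)
})

test_that("identical fits yield a null likelihood-ratio test", {
  ses <- simulate_mlcm_session(c(0, 1), c(0, -1), seed = 4, reps = 2,
                               n_views = 4)
  f_add <- fit_mlcm(ses, "additive")
  f_sat <- fit_mlcm(ses, "saturated")
  # additive and saturated coincide on a 2x2 grid up to one parameter
  lr <- lr_test(f_add, f_sat)
  expect_gte(lr$statistic, 0)
  expect_error(lr_test(f_sat, f_add), "more parameters")
})

test_that("MLCM estimates match an exhaustive likelihood grid search", {
  # 2x2 grid: two free parameters, full 0.05 grid over [-3, 3]
  ses <- simulate_mlcm_session(c(0, 1.2), c(0, -0.7), seed = 13, reps = 5,
                               n_views = 4)
  ses <- ses[1:40, ]
  fit <- fit_mlcm(ses, "additive")
  ax <- seq(-3, 3, by = 0.05)
  G <- expand.grid(s2 = ax, b2 = ax)
  ll <- apply(G, 1, function(p) mlcm_loglik(ses, c(0, p[1]), c(0, p[2])))
  best <- G[which.max(ll), ]
  expect_lt(abs(fit$psi_s[2] - best$s2), 0.1)
  expect_lt(abs(fit$psi_b[2] - best$b2), 0.1)
})

test_that("bootstrap intervals behave at the degenerate and null limits", {
  expect_error(bootstrap_ci(simulate_mlcm_session(c(0, 1), c(0, 0),
                                                  seed = 1, reps = 1,
                                                  n_views = 4),
                            n_boot = 0), ">= 1")
  # noise-free observer: intervals nearly degenerate around the estimate
  ses <- simulate_mlcm_session(c(0, 2, 4), c(0, 0, 0), noise_sd = 1e-6,
                               seed = 3, reps = 4, n_views = 4)
  boot <- suppressWarnings(bootstrap_ci(ses, "additive", n_boot = 60,
                                        seed = 2))
  widths <- boot$ci_high - boot$ci_low
  expect_lt(stats::median(widths), 0.5)
})

test_that("normalization and averaging respect their invariances", {
  ses <- simulate_mlcm_session(c(0, 1, 2), c(0, -1, -2), seed = 21, reps = 2)
  f <- fit_mlcm(ses, "additive")
  one <- normalize_and_average(list(f))
  r <- sqrt(mean(c(f$psi_s, f$psi_b)^2))
  expect_equal(one$psi_s, f$psi_s / r)
  expect_equal(one$sem_s, rep(0, 3))
  two <- normalize_and_average(list(f, f))
  expect_equal(two$psi_s, one$psi_s)
  expect_equal(two$sem_b, rep(0, 3))
  # scaling one fit before normalizing leaves the average unchanged
  f10 <- f
  f10$psi_s <- 10 * f$psi_s
  f10$psi_b <- 10 * f$psi_b
  mix <- normalize_and_average(list(f, f10))
  expect_equal(mix$psi_s, one$psi_s, tolerance = 1e-10)
})
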