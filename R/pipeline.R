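# End-to-end orchestration: stimuli -> statistics tables -> simulated
# sessions -> scale and conjoint fits -> metallicity weights -> CSV/JSON
# artifacts and summary figures. Every output carries the configuration
# hash; all randomness flows from the configuration's master seed through
# named substreams, so each stage is independently reproducible.

#' Assemble a pipeline run configuration
#'
#' @param stimulus A [stim_config()].
#' @param observers Character vector of statistic names to simulate as model
#'   observers: any of `"A1"`, `"A14"` (the fine/coarse difference) and the
#'   contrast statistics of [contrast_statistic_names()].
#' @param mlds_levels Number of levels for the difference-scaling sets.
#' @param mlcm_repeats Session repeats per pair.
#' @param n_boot Bootstrap replicates for conjoint confidence intervals
#'   (0 disables bootstrapping).
#' @param alpha Significance level for nested model selection.
#' @param write_stimuli Write NPY/PNG stimulus files (off by default: the
#'   statistics tables are what downstream stages consume).
#' @param run_mlds Simulate and fit the difference-scaling sessions.
#' @param metallicity_weights Optional list of named numeric `c(a, b)`
#'   vectors to push through the conjoint loop (fine-only and coarse-only
#'   reference models are always included).
#' @return A list of class `run_config`.
#' @export
run_config <- function(stimulus = stim_config(),
                       observers = c("A1", "A14",
                                     contrast_statistic_names()),
                       mlds_levels = 11L,
                       mlcm_repeats = 4L,
                       n_boot = 0L,
                       alpha = 0.001,
                       write_stimuli = FALSE,
                       run_mlds = TRUE,
                       metallicity_weights = NULL) {
  stopifnot(inherits(stimulus, "stim_config"))
  structure(list(stimulus = stimulus, observers = observers,
                 mlds_levels = as.integer(mlds_levels),
                 mlcm_repeats = as.integer(mlcm_repeats),
                 n_boot = as.integer(n_boot), alpha = alpha,
                 write_stimuli = write_stimuli, run_mlds = run_mlds,
                 metallicity_weights = metallicity_weights),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$stimulus <- unclass(lst$stimulus)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  stim <- do.call(stim_config, lst$stimulus)
  lst$stimulus <- NULL
  do.call(run_config, c(list(stimulus = stim), lst))
}

# stage wrapper: any failure aborts with the stage name and config hash
run_stage <- function(name, hash, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed [config %s]: %s", name, hash,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Generates the stimulus grid and difference-scaling sets, computes the
#' statistics tables (pyramid activations and contrast estimators, plus
#' radial spectra summaries), simulates a difference-scaling and a conjoint
#' session for every observer in the roster, fits scales, the three nested
#' conjoint models and the likelihood-ratio model selection, fits the
#' two-parameter metallicity model to each additive conjoint scale, and
#' writes CSV/JSON artifacts plus summary figures into `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the main in-memory results (`stats`,
#'   `conjoint`, `mlds`, `weights`, `selection`, `hash`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  scfg <- config$stimulus
  msg <- function(...) message(sprintf("[metalsim %s] ", hash), sprintf(...))

  msg("rendering %d x %d x %d stimulus grid",
      scfg$n_smoothness_levels, scfg$n_bumpiness_levels, scfg$n_views)
  grid <- run_stage("stimuli", hash, render_grid(scfg))
  if (config$write_stimuli)
    run_stage("stimuli_io", hash,
              write_stimulus_set(grid, file.path(out_dir, "stimuli")))

  msg("computing statistics tables")
  stats_tab <- run_stage("statistics", hash, {
    act <- activation_table(grid)
    act$A14 <- act$A1 - act[[paste0("A", 4L)]]
    ct <- contrast_table(grid)
    merge(act, ct,
          by = c("smoothness_index", "bumpiness_index", "view_index"))
  })
  stats_tab$config_hash <- hash
  utils::write.csv(stats_tab, file.path(out_dir, "statistics.csv"),
                   row.names = FALSE)

  msg("computing radial spectra band summary")
  run_stage("spectra", hash, {
    sp <- spectra_table(grid[vapply(grid, function(g)
      g$bumpiness_index == 1L || g$smoothness_index == 1L, logical(1))])
    sp$config_hash <- hash
    utils::write.csv(sp, file.path(out_dir, "spectra.csv"),
                     row.names = FALSE)
  })

  mlds_fits <- NULL
  if (config$run_mlds) {
    msg("simulating difference scaling (%d levels)", config$mlds_levels)
    mlds_fits <- run_stage("mlds", hash, {
      sets <- render_mlds_sets(scfg, config$mlds_levels)
      act_s <- activation_table(sets$smoothness)
      act_b <- activation_table(sets$bumpiness)
      act_s$A14 <- act_s$A1 - act_s$A4
      act_b$A14 <- act_b$A1 - act_b$A4
      quads <- enumerate_mlds_quadruples(config$mlds_levels)
      out <- list()
      for (spec in list(list(dim = "smoothness", stat = "A1", tab = act_s),
                        list(dim = "bumpiness", stat = "A14", tab = act_b))) {
        ses <- build_mlds_session(quads, spec$dim, scfg$n_views,
                                  seed = derive_seed(scfg$master_seed,
                                                     "mlds", 1L))
        obs <- model_observer(spec$stat,
                              default_noise_sd(spec$tab, spec$stat),
                              seed = derive_seed(scfg$master_seed,
                                                 "mlds_noise", 2L))
        fit <- suppressWarnings(fit_mlds(simulate_responses(ses, obs,
                                                            spec$tab)))
        write_fit_json(fit, file.path(out_dir,
                                      paste0("mlds_", spec$dim, ".json")),
                       extra = list(statistic = spec$stat,
                                    config_hash = hash))
        out[[spec$dim]] <- fit
      }
      out
    })
  }

  msg("simulating conjoint sessions for %d observers",
      length(config$observers))
  pairs <- enumerate_mlcm_pairs(scfg$n_smoothness_levels,
                                scfg$n_bumpiness_levels)
  conjoint <- run_stage("mlcm", hash, {
    out <- list()
    for (i in seq_along(config$observers)) {
      stat <- config$observers[i]
      ses <- build_mlcm_session(pairs, config$mlcm_repeats, scfg$n_views,
                                seed = derive_seed(scfg$master_seed,
                                                   "mlcm_session", i))
      obs <- model_observer(stat, default_noise_sd(stats_tab, stat),
                            seed = derive_seed(scfg$master_seed,
                                               "mlcm_noise", i))
      ses <- simulate_responses(ses, obs, stats_tab)
      write_trials(ses, file.path(out_dir,
                                  paste0("trials_", stat, ".csv")))
      fits <- list(
        independent = suppressWarnings(fit_mlcm(ses, "independent")),
        additive = suppressWarnings(fit_mlcm(ses, "additive")),
        saturated = suppressWarnings(fit_mlcm(ses, "saturated")))
      if (config$n_boot > 0L)
        fits$additive <- suppressWarnings(
          bootstrap_ci(ses, "additive", n_boot = config$n_boot,
                       seed = derive_seed(scfg$master_seed, "boot", i)))
      lr_ia <- lr_test(fits$independent, fits$additive)
      lr_as <- lr_test(fits$additive, fits$saturated)
      selected <- if (lr_ia$p_value >= config$alpha) "independent"
      else if (lr_as$p_value < config$alpha) "saturated"
      else "additive"
      write_fit_json(fits$additive,
                     file.path(out_dir, paste0("mlcm_", stat, ".json")),
                     extra = list(
                       statistic = stat, selected_model = selected,
                       lr_independent_vs_additive = lr_ia$p_value,
                       lr_additive_vs_saturated = lr_as$p_value,
                       config_hash = hash))
      out[[stat]] <- list(fits = fits, lr_ia = lr_ia, lr_as = lr_as,
                          selected = selected)
    }
    out
  })

  msg("fitting metallicity weights")
  weights <- run_stage("metallicity", hash, {
    wl <- list()
    for (stat in names(conjoint)) {
      w <- tryCatch(
        fit_weights_to_scale(conjoint[[stat]]$fits$additive, stats_tab),
        error = function(e) NULL)
      if (!is.null(w)) wl[[stat]] <- w
    }
    wtab <- do.call(rbind, lapply(names(wl), function(s)
      data.frame(observer = s, L1 = wl[[s]]$b, L4 = wl[[s]]$a,
                 rss = wl[[s]]$loss)))
    wtab$config_hash <- hash
    utils::write.csv(wtab, file.path(out_dir, "metallicity_weights.csv"),
                     row.names = FALSE)
    wl
  })

  msg("rendering figures")
  run_stage("figures", hash, {
    pipeline_figures(stats_tab, conjoint, mlds_fits, out_dir, hash)
  })

  sel <- data.frame(
    observer = names(conjoint),
    selected_model = vapply(conjoint, `[[`, character(1), "selected"),
    p_independent_vs_additive =
      vapply(conjoint, function(x) x$lr_ia$p_value, numeric(1)),
    p_additive_vs_saturated =
      vapply(conjoint, function(x) x$lr_as$p_value, numeric(1)))
  sel$config_hash <- hash
  utils::write.csv(sel, file.path(out_dir, "model_selection.csv"),
                   row.names = FALSE)
  msg("done")
  invisible(list(stats = stats_tab, conjoint = conjoint, mlds = mlds_fits,
                 weights = weights, selection = sel, hash = hash))
}

# summary figures: conjoint contributions per observer, activation heatmap,
# spectra band means, difference scales
pipeline_figures <- function(stats_tab, conjoint, mlds_fits, out_dir, hash) {
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 9, height = 6,
                 onefile = TRUE)
  on.exit(grDevices::dev.off())
  oldpar <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(oldpar), add = TRUE)

  # conjoint contributions
  ns <- length(conjoint)
  graphics::par(mfrow = c(ceiling(ns / 4), min(ns, 4)),
                mar = c(3, 3, 2, 1), mgp = c(1.8, 0.6, 0))
  for (stat in names(conjoint)) {
    f <- conjoint[[stat]]$fits$additive
    ylim <- range(c(f$psi_s, f$psi_b))
    graphics::plot(seq_along(f$psi_s), f$psi_s, type = "b", col = "darkgreen",
                   pch = 16, ylim = ylim, xlab = "level",
                   ylab = expression(psi ~ "(d')"),
                   main = sprintf("%s (%s)", stat,
                                  conjoint[[stat]]$selected))
    graphics::lines(seq_along(f$psi_b), f$psi_b, type = "b", col = "steelblue",
                    pch = 17)
  }
  graphics::mtext(sprintf("conjoint contributions [%s]", hash), side = 1,
                  line = -1, outer = TRUE, cex = 0.6)

  # activation heatmaps (view-averaged)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 2))
  for (lvl in c("A1", "A4")) {
    agg <- stats::aggregate(stats_tab[[lvl]],
                            by = list(s = stats_tab$smoothness_index,
                                      b = stats_tab$bumpiness_index), mean)
    K_s <- max(agg$s); K_b <- max(agg$b)
    M <- matrix(NA_real_, K_s, K_b)
    M[cbind(agg$s, agg$b)] <- agg$x
    graphics::image(seq_len(K_s), seq_len(K_b), M,
                    xlab = "smoothness level (1 = smoothest)",
                    ylab = "bumpiness level (1 = even)",
                    main = paste("mean", lvl), col = grDevices::hcl.colors(24))
  }

  # difference scales
  if (!is.null(mlds_fits)) {
    graphics::par(mfrow = c(1, 2))
    for (dm in names(mlds_fits)) {
      f <- mlds_fits[[dm]]
      graphics::plot(seq_along(f$psi), f$psi, type = "b", pch = 16,
                     xlab = paste(dm, "level"), ylab = "psi (d')",
                     main = paste("simulated difference scale:", dm))
    }
  }
}

#' Summarize a pipeline run directory
#'
#' Tabulates, per simulated observer, the conjoint model class selected by
#' the likelihood-ratio tests and the direction of each dimension's
#' contribution — the synthetic analogue of a published summary table of
#' which image statistics behave like human observers.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Data.frame with one row per observer: selected model, test
#'   p-values, signs of the top-level contributions.
#' @export
pipeline_report <- function(run_dir) {
  sel_path <- file.path(run_dir, "model_selection.csv")
  if (!file.exists(sel_path))
    stop("`", run_dir, "` is not a pipeline run directory ",
         "(no model_selection.csv)", call. = FALSE)
  sel <- utils::read.csv(sel_path)
  details <- lapply(sel$observer, function(stat) {
    rec <- jsonlite::read_json(
      file.path(run_dir, paste0("mlcm_", stat, ".json")),
      simplifyVector = TRUE)
    s_dir <- sign(rec$psi_s[length(rec$psi_s)])
    b_dir <- sign(rec$psi_b[length(rec$psi_b)])
    data.frame(observer = stat,
               smoothness_direction = c("-", "0", "+")[s_dir + 2],
               bumpiness_direction = c("-", "0", "+")[b_dir + 2])
  })
  out <- merge(sel, do.call(rbind, details), by = "observer", sort = FALSE)
  class(out) <- c("pipeline_report", class(out))
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report: simulated observers and selected conjoint models\n")
  NextMethod()
  invisible(x)
}
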