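# Trial designs for the two psychophysical tasks and the noisy model
# observers that perform them. A model observer carries one scalar image
# statistic; on each trial it computes the statistic for every stimulus
# shown (condition x view), perturbs its decision variable with Gaussian
# noise and answers deterministically from the sign.

#' Enumerate all conjoint-measurement condition pairs
#'
#' All unordered pairs of the `n_s x n_b` grid conditions, including
#' identical-condition pairs (those still differ by view at presentation):
#' `n(n+1)/2` pairs, 325 for the default 5 x 5 grid.
#'
#' @param n_s,n_b Number of smoothness and bumpiness levels.
#' @return Data.frame with columns `s1, b1, s2, b2` (1-based levels), in
#'   deterministic order.
#' @export
#' @examples
#' nrow(enumerate_mlcm_pairs(5, 5)) # 325
enumerate_mlcm_pairs <- function(n_s = 5L, n_b = 5L) {
  stopifnot(n_s >= 1L, n_b >= 1L)
  conds <- expand.grid(s = seq_len(n_s), b = seq_len(n_b))
  conds <- conds[order(conds$s, conds$b), ]
  n <- nrow(conds)
  idx <- which(upper.tri(matrix(TRUE, n, n), diag = TRUE), arr.ind = TRUE)
  data.frame(s1 = conds$s[idx[, 1]], b1 = conds$b[idx[, 1]],
             s2 = conds$s[idx[, 2]], b2 = conds$b[idx[, 2]])
}

#' Build a randomized conjoint-measurement session
#'
#' Each pair is presented `n_repeats` times (1300 trials for 325 pairs at 4
#' repeats); on every trial the two stimuli are assigned views drawn without
#' replacement from the `n_views` available, so the two views always differ
#' and a pixel-based comparison is impossible. Trial order is shuffled.
#'
#' @param pairs Data.frame from [enumerate_mlcm_pairs()].
#' @param n_repeats Presentations per pair.
#' @param n_views Number of available views.
#' @param seed Integer seed for view assignment and shuffling.
#' @return Data.frame of `pair_trial`s: `trial_id, s1, b1, v1, s2, b2, v2,
#'   repetition`, with `response` unset (`NA`) until simulation or data
#'   entry.
#' @export
build_mlcm_session <- function(pairs, n_repeats = 4L, n_views = 8L, seed = 1L) {
  stopifnot(is.data.frame(pairs), n_repeats >= 1L, n_views >= 2L)
  trials <- pairs[rep(seq_len(nrow(pairs)), times = n_repeats), ]
  trials$repetition <- rep(seq_len(n_repeats), each = nrow(pairs))
  n <- nrow(trials)
  withr::with_seed(seed, {
    vs <- t(vapply(seq_len(n), function(i) sample.int(n_views, 2L),
                   integer(2)))
    ord <- sample.int(n)
  })
  trials$v1 <- vs[, 1]
  trials$v2 <- vs[, 2]
  trials <- trials[ord, ]
  trials$trial_id <- seq_len(n)
  trials$response <- NA_integer_
  rownames(trials) <- NULL
  trials[, c("trial_id", "s1", "b1", "v1", "s2", "b2", "v2", "repetition",
             "response")]
}

#' Enumerate difference-scaling quadruples
#'
#' Non-overlapping quadruples `a < b < c < d` of one dimension's levels,
#' judged as pair (a,b) versus pair (c,d): `choose(n_levels, 4)` of them
#' (330 for 11 levels). `n_subsample` draws a uniform random subset, which
#' reproduces designs reported with slightly smaller counts without guessing
#' their exclusion rule.
#'
#' @param n_levels Number of stimulus levels along the dimension.
#' @param n_subsample Optional number of quadruples to keep
#'   (`<= choose(n_levels, 4)`).
#' @param seed Seed for the optional subsample.
#' @return Data.frame with columns `a, b, c, d` (1-based level indices).
#' @export
#' @examples
#' nrow(enumerate_mlds_quadruples(11)) # 330
enumerate_mlds_quadruples <- function(n_levels = 11L, n_subsample = NULL,
                                      seed = 1L) {
  if (n_levels < 4L) stop("need at least 4 levels", call. = FALSE)
  q <- t(utils::combn(n_levels, 4L))
  quads <- data.frame(a = q[, 1], b = q[, 2], c = q[, 3], d = q[, 4])
  if (!is.null(n_subsample)) {
    if (n_subsample < 1L || n_subsample > nrow(quads))
      stop("`n_subsample` out of range", call. = FALSE)
    withr::with_seed(seed, {
      quads <- quads[sort(sample.int(nrow(quads), n_subsample)), ]
    })
    rownames(quads) <- NULL
  }
  quads
}

#' Build a randomized difference-scaling session
#'
#' Each quadruple becomes one trial; the four stimuli receive views drawn
#' without replacement from the available views. Trial order is shuffled.
#'
#' @param quadruples Data.frame from [enumerate_mlds_quadruples()].
#' @param dimension `"smoothness"` or `"bumpiness"` (recorded per trial).
#' @param n_views Number of available views (`>= 4`).
#' @param seed Integer seed.
#' @return Data.frame of `quadruple_trial`s: `trial_id, dim, a, b, c, d,
#'   va, vb, vc, vd, response` (response `NA` until simulated).
#' @export
build_mlds_session <- function(quadruples,
                               dimension = c("smoothness", "bumpiness"),
                               n_views = 8L, seed = 1L) {
  dimension <- match.arg(dimension)
  stopifnot(is.data.frame(quadruples), n_views >= 4L)
  n <- nrow(quadruples)
  withr::with_seed(seed, {
    vs <- t(vapply(seq_len(n), function(i) sample.int(n_views, 4L),
                   integer(4)))
    ord <- sample.int(n)
  })
  trials <- quadruples
  trials$dim <- dimension
  trials$va <- vs[, 1]; trials$vb <- vs[, 2]
  trials$vc <- vs[, 3]; trials$vd <- vs[, 4]
  trials <- trials[ord, ]
  trials$trial_id <- seq_len(n)
  trials$response <- NA_integer_
  rownames(trials) <- NULL
  trials[, c("trial_id", "dim", "a", "b", "c", "d", "va", "vb", "vc", "vd",
             "response")]
}

#' Define a noisy model observer
#'
#' @param statistic Name of the statistic column the observer reads from the
#'   statistics table (e.g. `"A1"`, `"RMS"`, or a weighted metallicity
#'   statistic column).
#' @param noise_sd Standard deviation of the Gaussian decision noise added
#'   to the decision variable (`>= 0`).
#' @param seed Integer seed for the observer's noise stream.
#' @return An object of class `model_observer`.
#' @export
model_observer <- function(statistic, noise_sd = 1, seed = 1L) {
  stopifnot(is.character(statistic), length(statistic) == 1L,
            noise_sd >= 0)
  structure(list(statistic = statistic, noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "model_observer")
}

#' @export
print.model_observer <- function(x, ...) {
  cat(sprintf("Model observer: statistic %s, decision noise SD %.4g (seed %d)\n",
              x$statistic, x$noise_sd, x$seed))
  invisible(x)
}

# look up statistic values for (s, b, view) triples in a statistics table
lookup_stat <- function(table, statistic, s, b, v) {
  if (is.null(table[[statistic]]))
    stop("statistics table has no column `", statistic, "`", call. = FALSE)
  key <- paste(table$smoothness_index, table$bumpiness_index,
               table$view_index)
  m <- match(paste(s, b, v), key)
  if (anyNA(m))
    stop("statistics table has no row for condition (s=",
         s[which(is.na(m))[1]], ", b=", b[which(is.na(m))[1]], ", view=",
         v[which(is.na(m))[1]], ")", call. = FALSE)
  table[[statistic]][m]
}

#' Simulate an observer's responses to a session
#'
#' For conjoint (pair) trials the decision variable is
#' `stat(stimulus 1) - stat(stimulus 2) + noise` and the response is 1 when
#' stimulus 1 is judged the more metallic (decision variable positive). For
#' difference-scaling (quadruple) trials it is
#' `|stat(d) - stat(c)| - |stat(b) - stat(a)| + noise`, with response 1 when
#' pair (a,b) is judged the larger difference (decision variable negative).
#' Exact ties at zero are broken by a fair coin from the same noise stream
#' (reachable only at `noise_sd = 0`).
#'
#' @param trials A session from [build_mlcm_session()] or
#'   [build_mlds_session()].
#' @param observer A [model_observer()].
#' @param stats_table Statistics table with columns `smoothness_index`,
#'   `bumpiness_index`, `view_index` and the observer's statistic. For
#'   difference-scaling sessions of one dimension, the off-dimension index
#'   must be 1 (the fixed level).
#' @return `trials` with the `response` column filled in.
#' @export
simulate_responses <- function(trials, observer, stats_table) {
  stopifnot(inherits(observer, "model_observer"), is.data.frame(trials))
  n <- nrow(trials)
  withr::with_seed(derive_seed(observer$seed, "noise"), {
    eps <- stats::rnorm(n, 0, observer$noise_sd)
    coin <- stats::runif(n) < 0.5
  })
  if (all(c("s1", "b1", "v1") %in% names(trials))) {
    d1 <- lookup_stat(stats_table, observer$statistic,
                      trials$s1, trials$b1, trials$v1)
    d2 <- lookup_stat(stats_table, observer$statistic,
                      trials$s2, trials$b2, trials$v2)
    delta <- d1 - d2 + eps
    trials$response <- ifelse(delta == 0, as.integer(coin),
                              as.integer(delta > 0))
  } else if (all(c("dim", "a", "va") %in% names(trials))) {
    one <- rep(1L, n)
    get <- function(lev, vv) {
      if (all(trials$dim == "smoothness"))
        lookup_stat(stats_table, observer$statistic, lev, one, vv)
      else lookup_stat(stats_table, observer$statistic, one, lev, vv)
    }
    sa <- get(trials$a, trials$va); sb <- get(trials$b, trials$vb)
    sc <- get(trials$c, trials$vc); sd_ <- get(trials$d, trials$vd)
    delta <- abs(sd_ - sc) - abs(sb - sa) + eps
    trials$response <- ifelse(delta == 0, as.integer(coin),
                              as.integer(delta < 0))
  } else {
    stop("`trials` is neither a pair nor a quadruple session", call. = FALSE)
  }
  trials
}

#' Write or read a trial table as CSV
#'
#' @param trials Trial data.frame.
#' @param path CSV path.
#' @return `path` (write) or the trial data.frame (read).
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) utils::read.csv(path)

#' Default decision-noise SD for a simulated observer
#'
#' One tenth of the statistic's range over the stimulus set, which yields
#' fitted scales of a few d-prime units — the magnitude typical of
#' suprathreshold difference-scaling data.
#'
#' @param stats_table Statistics table.
#' @param statistic Statistic column name.
#' @return Scalar noise SD.
#' @export
default_noise_sd <- function(stats_table, statistic) {
  v <- stats_table[[statistic]]
  if (is.null(v)) stop("no column `", statistic, "` in table", call. = FALSE)
  0.1 * diff(range(v))
}
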