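#' Per-trial spike counts in the tonic analysis windows
#'
#' For each trial, counts one unit's spikes in three half-open windows
#' around cue onset: an ITI baseline [-3, -2) s, a pre-cue window [-1, 0) s,
#' and a response window [0, 1) s. Counts are kept separate per CS
#' condition. Windows must lie inside the ITI: trials whose baseline window
#' would overlap the previous trial's tone epoch are an error.
#'
#' @param spikes one unit's spike times.
#' @param trials trial table.
#' @param windows named list of length-2 windows relative to cue onset.
#' @return data.frame: trial, cs_type, baseline, pre_cue, response.
#' @export
trial_window_counts <- function(spikes, trials,
                                windows = list(baseline = c(-3, -2),
                                               pre_cue = c(-1, 0),
                                               response = c(0, 1))) {
  tone_s <- attr(trials, "tone_duration_s") %||% 4
  earliest <- min(vapply(windows, `[`, numeric(1), 1))
  if (nrow(trials) > 1) {
    prev_end <- trials$cs_onset_s[-nrow(trials)] + tone_s
    bad <- which(trials$cs_onset_s[-1] + earliest < prev_end) + 1L
    if (length(bad)) {
      stop_input("tonic windows overlap the previous trial's tone for trial(s) %s",
                 paste(trials$trial[bad], collapse = ", "))
    }
  }
  out <- data.frame(trial = trials$trial, cs_type = trials$cs_type)
  for (wn in names(windows)) {
    w <- windows[[wn]]
    out[[wn]] <- count_in_windows(spikes, trials$cs_onset_s + w[1],
                                  trials$cs_onset_s + w[2])
  }
  out
}

# map the smoothing factor to a trailing-window span (in trials)
.tonic_window <- function(f, n_trials) max(3L, ceiling(f * n_trials / 2))

#' Baseline-normalised, trial-smoothed tonic series for one unit
#'
#' Per CS condition, z-scores the pre-cue and response per-trial counts
#' against the across-trial mean and SD of that condition's baseline-window
#' counts, smooths each series across trials with a causal Gaussian whose
#' span is set by `smoothing_factor`, and concatenates the four series in
#' the order E-pre, E-response, A-pre, A-response.
#'
#' @param counts a [trial_window_counts()] data.frame.
#' @param smoothing_factor f in [0, 1]; the trailing window is
#'   `max(3, ceiling(f * n_trials / 2))` trials with sigma = span / 5. Set
#'   to 0 for (almost) no smoothing.
#' @return list: `z` (the concatenated series), `blocks` (data.frame
#'   block/condition/window/length), or NULL when a baseline SD is zero
#'   (unit must be removed and reported by the caller).
#' @export
normalize_trial_series <- function(counts, smoothing_factor = 0.85) {
  blocks <- list(); zs <- list()
  for (cond in c("E", "A")) {
    sub <- counts[counts$cs_type == cond, ]
    if (nrow(sub) < 5) stop_input("need >= 5 trials per condition")
    mu <- mean(sub$baseline); sd <- stats::sd(sub$baseline)
    if (!is.finite(sd) || sd == 0) return(NULL)
    wspan <- .tonic_window(smoothing_factor, nrow(sub))
    for (wn in c("pre_cue", "response")) {
      z <- (sub[[wn]] - mu) / sd
      if (smoothing_factor > 0) z <- smooth_causal_gaussian(z, wspan)
      zs[[length(zs) + 1L]] <- z
      blocks[[length(blocks) + 1L]] <- data.frame(
        block = length(zs), condition = cond, window = wn, length = nrow(sub))
    }
  }
  list(z = unlist(zs), blocks = do.call(rbind, blocks))
}

#' Tonic feature matrix for a unit population
#'
#' Applies [trial_window_counts()] and [normalize_trial_series()] to every
#' unit and stacks the concatenated series into a units x features matrix.
#' Units with zero baseline SD are removed and reported.
#'
#' @param spikes_list named list of spike-time vectors.
#' @param trials trial table.
#' @param smoothing_factor see [normalize_trial_series()].
#' @return list: `features` matrix, `blocks`, `removed`, and `counts` (list
#'   of per-unit raw [trial_window_counts()] data.frames).
#' @export
build_tonic_matrix <- function(spikes_list, trials, smoothing_factor = 0.85) {
  rows <- list(); removed <- character(0); blocks <- NULL
  counts <- list()
  for (uid in names(spikes_list)) {
    cnt <- trial_window_counts(spikes_list[[uid]], trials)
    counts[[uid]] <- cnt
    ns <- normalize_trial_series(cnt, smoothing_factor)
    if (is.null(ns)) { removed <- c(removed, uid); next }
    rows[[uid]] <- ns$z
    blocks <- ns$blocks
  }
  if (!length(rows)) stop_input("no unit survived baseline normalisation")
  list(features = do.call(rbind, rows), blocks = blocks, removed = removed,
       counts = counts)
}

#' Cluster tonic trial series
#'
#' Ward/Euclidean clustering of the concatenated z-scored trial series with
#' the tonic defaults: cut at 20% of the maximum merge height, discard
#' clusters under 3 members. Delegates to [ward_cut()].
#'
#' @param zseries units x features matrix (or `build_tonic_matrix()$features`).
#' @param cutoff_fraction default 0.20.
#' @param min_cluster_size default 3.
#' @return a `cluster_result`.
#' @export
cluster_trial_series <- function(zseries, cutoff_fraction = 0.20,
                                 min_cluster_size = 3) {
  ward_cut(zseries, cutoff_fraction, min_cluster_size)
}

#' Regression test for a tonic firing-rate change
#'
#' Ordinary least squares of per-trial spike count against trial index, with
#' a t-based confidence interval on the slope; a tonic change is flagged
#' when the interval excludes zero.
#'
#' @param counts per-trial counts (typically a cluster's mean raw series).
#' @param trials trial indices (default 1..n).
#' @param ci_level confidence level (default 0.95).
#' @return a `tonic_test` data.frame row: slope, ci_low, ci_high, ci_level,
#'   change (logical), n_trials.
#' @export
detect_tonic_change <- function(counts, trials = seq_along(counts),
                                ci_level = 0.95) {
  if (length(unique(trials)) < 3) stop_input("need >= 3 distinct trial indices")
  if (length(counts) < 5) stop_input("need >= 5 trials")
  fit <- stats::lm(counts ~ trials)
  ci <- stats::confint(fit, "trials", level = ci_level)
  slope <- unname(stats::coef(fit)["trials"])
  data.frame(slope = slope, ci_low = ci[1], ci_high = ci[2],
             ci_level = ci_level,
             change = is.finite(ci[1]) && (ci[1] > 0 || ci[2] < 0),
             n_trials = length(counts))
}

#' Per-cluster tonic regression report
#'
#' For every retained cluster, averages the member units' raw per-trial
#' counts and fits the tonic regression separately for each of the four
#' series (E/A x pre-cue/response), reporting slope, CI, and change flag.
#' By default the fit uses the raw (unsmoothed) counts; `smoothing_factor`
#' > 0 fits the across-trial smoothed means instead.
#'
#' @param counts_list per-unit [trial_window_counts()] data.frames (e.g.
#'   `build_tonic_matrix()$counts`).
#' @param result a `cluster_result` over (a subset of) those units.
#' @param ci_level confidence level.
#' @param smoothing_factor 0 (default) fits raw mean counts.
#' @return data.frame: cluster, condition, window, slope, ci_low, ci_high,
#'   change, n_trials, n_units.
#' @export
tonic_change_report <- function(counts_list, result, ci_level = 0.95,
                                smoothing_factor = 0) {
  labels <- result$labels
  out <- list()
  for (cl in sort(unique(labels[!is.na(labels)]))) {
    members <- names(labels)[!is.na(labels) & labels == cl]
    for (cond in c("E", "A")) for (wn in c("pre_cue", "response")) {
      series <- sapply(members, function(uid) {
        sub <- counts_list[[uid]]
        sub[[wn]][sub$cs_type == cond]
      })
      m <- rowMeans(as.matrix(series))
      if (smoothing_factor > 0) {
        m <- smooth_causal_gaussian(m, .tonic_window(smoothing_factor, length(m)))
      }
      tt <- detect_tonic_change(m, ci_level = ci_level)
      out[[length(out) + 1L]] <- cbind(
        data.frame(cluster = cl, condition = cond, window = wn),
        tt, data.frame(n_units = length(members)))
    }
  }
  if (!length(out)) {
    return(data.frame(cluster = integer(0), condition = character(0),
                      window = character(0), slope = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      ci_level = numeric(0), change = logical(0),
                      n_trials = integer(0), n_units = integer(0)))
  }
  do.call(rbind, out)
}
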