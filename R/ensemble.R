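#' Event-aligned peri-stimulus time histogram
#'
#' Trial-averaged firing rate per unit in contiguous half-open bins aligned
#' to a set of events.
#'
#' @param spikes_list named list of spike-time vectors (one per unit).
#' @param events alignment event times (s).
#' @param bin_width_s bin width; 0.05 for trajectory input, 0.1 for
#'   clustering input.
#' @param window length-2 window around the event, e.g. `c(-2, 4)`.
#' @return a `psth` list: `values` (units x bins rate matrix, Hz), `edges`
#'   (bin edges, event-aligned s), `bin_width_s`, `unit_ids`.
#' @export
compute_psth <- function(spikes_list, events, bin_width_s = 0.05,
                         window = c(-2, 4)) {
  if (length(events) == 0) stop_input("no alignment events")
  stopifnot(length(window) == 2, window[2] > window[1])
  nb <- round((window[2] - window[1]) / bin_width_s)
  edges <- window[1] + bin_width_s * (0:nb)
  vals <- t(vapply(spikes_list, function(st) {
    rel <- unlist(lapply(events, function(ev) {
      st[st >= ev + window[1] & st < ev + window[2]] - ev
    }))
    if (length(rel) == 0) return(rep(0, nb))
    counts <- tabulate(findInterval(rel, edges), nbins = nb)
    counts / (length(events) * bin_width_s)
  }, numeric(nb)))
  if (length(spikes_list) == 1) vals <- matrix(vals, nrow = 1)
  rownames(vals) <- names(spikes_list)
  structure(list(values = vals, edges = edges, bin_width_s = bin_width_s,
                 unit_ids = names(spikes_list)),
            class = "psth")
}

#' Baseline z-scoring with causal Gaussian smoothing
#'
#' Each unit's PSTH is z-scored against the mean and SD of its own bins in
#' the baseline window (default -2 s to cue onset), then smoothed along time
#' with a causal Gaussian over the current and `smooth_bins` previous bins.
#' Units whose baseline SD is zero (or whose z-scores are not finite) are
#' removed and reported in the `removed` attribute.
#'
#' @param psth a [compute_psth()] result.
#' @param baseline_window length-2 window of baseline bins.
#' @param smooth_bins number of previous bins in the smoothing window; 0
#'   disables smoothing.
#' @return a `psth` with z-scored (and smoothed) `values`; removed unit ids
#'   in `attr(, "removed")`.
#' @export
zscore_smooth <- function(psth, baseline_window = c(-2, 0), smooth_bins = 10) {
  lo <- psth$edges[-length(psth$edges)]
  if (baseline_window[1] < psth$edges[1] - 1e-9 ||
      baseline_window[2] > psth$edges[length(psth$edges)] + 1e-9) {
    stop_input("baseline window outside the PSTH window")
  }
  in_base <- lo >= baseline_window[1] - 1e-9 & lo < baseline_window[2] - 1e-9
  if (!any(in_base)) stop_input("baseline window contains no bins")
  v <- psth$values
  mu <- rowMeans(v[, in_base, drop = FALSE])
  sd <- apply(v[, in_base, drop = FALSE], 1, stats::sd)
  bad <- !is.finite(sd) | sd == 0
  z <- (v[!bad, , drop = FALSE] - mu[!bad]) / sd[!bad]
  bad2 <- apply(z, 1, function(r) any(!is.finite(r)))
  removed <- c(rownames(v)[bad], rownames(z)[bad2])
  z <- z[!bad2, , drop = FALSE]
  if (smooth_bins > 0 && nrow(z) > 0) z <- smooth_causal_gaussian(z, smooth_bins)
  out <- psth
  out$values <- z
  out$unit_ids <- rownames(z)
  attr(out, "removed") <- removed
  attr(out, "baseline_window") <- baseline_window
  attr(out, "smooth_bins") <- smooth_bins
  out
}

# Per-trial response counts vs duration-scaled baseline counts for one
# stimulus; returns the signed-rank p and the mean z of the response.
.stim_response_test <- function(spikes, onsets, baseline_anchor, baseline_s,
                                window_s) {
  resp <- count_in_windows(spikes, onsets, onsets + window_s)
  base <- count_in_windows(spikes, baseline_anchor - baseline_s, baseline_anchor)
  base_scaled <- base * (window_s / baseline_s)
  p <- if (all(resp == base_scaled)) 1 else {
    suppressWarnings(
      stats::wilcox.test(resp, base_scaled, paired = TRUE, exact = FALSE)$p.value)
  }
  if (is.na(p)) p <- 1
  bsd <- stats::sd(base_scaled)
  z <- if (is.finite(bsd) && bsd > 0) (mean(resp) - mean(base_scaled)) / bsd else NA_real_
  list(p = p, z = z)
}

#' Task-responsiveness call for one unit
#'
#' Wilcoxon signed-rank test of per-trial spike counts in the 100 ms window
#' after stimulus onset against a 3 s baseline taken from the preceding ITI
#' (ending at cue onset), rescaled to the response-window duration. A unit
#' is responsive to a stimulus at p < alpha; its sign is excited when the
#' mean z of the response is positive. CS and US significance combine into
#' one of "CS", "US", "both", "none".
#'
#' @param spikes one unit's spike times.
#' @param cs_onsets,us_onsets per-trial CS and US onset times (s), same
#'   trials in the same order.
#' @param baseline_s baseline duration (default 3).
#' @param window_ms response window (default 100).
#' @param alpha significance threshold (default 0.01).
#' @return data.frame row: p_cs, z_cs, p_us, z_us, responsive_cs,
#'   responsive_us, sign_cs, sign_us, label.
#' @export
classify_responsiveness <- function(spikes, cs_onsets, us_onsets,
                                    baseline_s = 3, window_ms = 100,
                                    alpha = 0.01) {
  if (length(cs_onsets) < 10 || length(us_onsets) < 10) {
    stop_input("need >= 10 trials per stimulus")
  }
  w <- window_ms / 1000
  cs <- .stim_response_test(spikes, cs_onsets, cs_onsets, baseline_s, w)
  us <- .stim_response_test(spikes, us_onsets, cs_onsets, baseline_s, w)
  sgn <- function(t, sig) {
    if (!sig) NA_character_
    else if (is.na(t$z)) "indeterminate"
    else if (t$z > 0) "excited" else if (t$z < 0) "inhibited" else "indeterminate"
  }
  rc <- cs$p < alpha; ru <- us$p < alpha
  label <- if (rc && ru) "both" else if (rc) "CS" else if (ru) "US" else "none"
  data.frame(p_cs = cs$p, z_cs = cs$z, p_us = us$p, z_us = us$z,
             responsive_cs = rc, responsive_us = ru,
             sign_cs = sgn(cs, rc), sign_us = sgn(us, ru), label = label)
}

# decision tree from per-CS significance and sign into the 9 labels
.valence_label <- function(sigE, signE, sigA, signA) {
  e <- if (sigE) (if (signE > 0) "E+" else "E-") else ""
  a <- if (sigA) (if (signA > 0) "A+" else "A-") else ""
  lab <- paste0(e, a)
  if (lab == "") "none" else lab
}

#' A-priori valence/arousal category of one unit
#'
#' Tests the unit's 100 ms response to each CS (reward CS-E and punishment
#' CS-A) with the signed-rank machinery of [classify_responsiveness()] and
#' combines significance and sign into one of nine labels: E+A+, E+A-,
#' E-A+, E-A- (responsive to both cues), E+, E-, A+, A- (one cue), or none.
#' Same-sign labels (E+A+, E-A-) indicate arousal/salience coding, mixed
#' signs valence coding.
#'
#' @param spikes one unit's spike times.
#' @param csE_onsets,csA_onsets CS onsets per trial type.
#' @inheritParams classify_responsiveness
#' @return data.frame row: p_E, z_E, p_A, z_A, label.
#' @export
classify_valence_category <- function(spikes, csE_onsets, csA_onsets,
                                      baseline_s = 3, window_ms = 100,
                                      alpha = 0.01) {
  if (length(csE_onsets) < 10 || length(csA_onsets) < 10) {
    stop_input("need >= 10 trials per CS")
  }
  w <- window_ms / 1000
  e <- .stim_response_test(spikes, csE_onsets, csE_onsets, baseline_s, w)
  a <- .stim_response_test(spikes, csA_onsets, csA_onsets, baseline_s, w)
  sigE <- e$p < alpha && !is.na(e$z) && e$z != 0
  sigA <- a$p < alpha && !is.na(a$z) && a$z != 0
  data.frame(p_E = e$p, z_E = e$z, p_A = a$p, z_A = a$z,
             label = .valence_label(sigE, e$z %||% 0, sigA, a$z %||% 0))
}

#' Category proportion and prevalence statistics
#'
#' `proportion_test` compares category count tables with a chi-squared test,
#' falling back to Fisher's exact test when any cell is below 5.
#' `prevalence_test` takes a leave-one-subject-out count matrix (one row per
#' left-out subject, one column per category), runs a Kruskal-Wallis test
#' across categories, and - when significant at `alpha` - runs pairwise
#' rank-sum post hocs of the largest-mean category against each other
#' category at a Bonferroni-adjusted threshold.
#'
#' @param tab matrix/table of non-negative integer counts.
#' @return list: method ("chi-squared" or "fisher"), p_value, table.
#' @export
proportion_test <- function(tab) {
  tab <- as.matrix(tab)
  if (all(tab == 0)) stop_input("degenerate all-zero table")
  if (any(tab < 5)) {
    list(method = "fisher", p_value = stats::fisher.test(tab)$p.value, table = tab)
  } else {
    list(method = "chi-squared",
         p_value = suppressWarnings(stats::chisq.test(tab)$p.value), table = tab)
  }
}

#' @rdname proportion_test
#' @param loo_counts k x categories matrix of leave-one-subject-out counts.
#' @param alpha significance level for the omnibus test (default 0.05).
#' @export
prevalence_test <- function(loo_counts, alpha = 0.05) {
  loo_counts <- as.matrix(loo_counts)
  if (ncol(loo_counts) < 2) {
    return(list(omnibus_p = NA_real_, significant = FALSE, posthoc = NULL,
                adjusted_alpha = NA_real_))
  }
  groups <- lapply(seq_len(ncol(loo_counts)), function(j) loo_counts[, j])
  kw <- stats::kruskal.test(groups)
  sig <- !is.na(kw$p.value) && kw$p.value < alpha
  posthoc <- NULL; adj <- NA_real_
  if (sig) {
    top <- which.max(colMeans(loo_counts))
    others <- setdiff(seq_len(ncol(loo_counts)), top)
    adj <- alpha / length(others)
    posthoc <- do.call(rbind, lapply(others, function(j) {
      p <- suppressWarnings(
        stats::wilcox.test(loo_counts[, top], loo_counts[, j], exact = FALSE)$p.value)
      data.frame(top = colnames(loo_counts)[top] %||% top,
                 other = colnames(loo_counts)[j] %||% j,
                 p_value = p, significant = !is.na(p) && p < adj)
    }))
  }
  list(omnibus_p = kw$p.value, significant = sig, posthoc = posthoc,
       adjusted_alpha = adj)
}

#' Leave-one-subject-out count matrix
#'
#' For each subject, counts category members among the units of all other
#' subjects; the rows form the sampling distribution used by
#' [prevalence_test()].
#'
#' @param labels per-unit category or cluster labels.
#' @param subjects per-unit subject ids (same length/order).
#' @return k x categories integer matrix, rows named by the left-out
#'   subject.
#' @export
loo_counts <- function(labels, subjects) {
  stopifnot(length(labels) == length(subjects))
  keep <- !is.na(labels)
  labels <- labels[keep]; subjects <- subjects[keep]
  subj <- sort(unique(subjects))
  cats <- sort(unique(labels))
  out <- t(vapply(subj, function(s) {
    tab <- table(factor(labels[subjects != s], levels = cats))
    as.integer(tab)
  }, integer(length(cats))))
  dimnames(out) <- list(subj, cats)
  out
}
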