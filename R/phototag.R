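#' Pulse-aligned light-response statistics for one unit
#'
#' Compares per-pulse spike counts in the response window `[0, window_ms)`
#' after light onset against a duration-matched pre-pulse window, with either
#' a paired Wilcoxon signed-rank test or an unpaired rank-sum test. The peak
#' z-score is computed from the pulse-aligned response binned at 1 ms,
#' z-scored against the mean and SD of the pre-pulse bins (spanning
#' `baseline_ms` before onset). The first-spike latency is the median over
#' pulses of the first spike inside the response window.
#'
#' @param spike_times sorted spike times (s).
#' @param pulse_onsets laser pulse onsets (s); the 5 ms 1 Hz protocol.
#' @param window_ms response window length (ms): 10 for MGN, 50 for BLA.
#' @param baseline_ms pre-pulse span used for the z-score baseline.
#' @param test "signed_rank" (paired) or "rank_sum" (unpaired).
#' @return a `photoresponse` list: p_value, z_peak, first_spike_latency_ms,
#'   n_pulses, window_ms, test.
#' @export
photoresponse_stats <- function(spike_times, pulse_onsets, window_ms = 10,
                                baseline_ms = 50,
                                test = c("signed_rank", "rank_sum")) {
  test <- match.arg(test)
  if (length(pulse_onsets) == 0) stop_input("no laser pulses supplied")
  w <- window_ms / 1000
  resp <- count_in_windows(spike_times, pulse_onsets, pulse_onsets + w)
  base <- count_in_windows(spike_times, pulse_onsets - w, pulse_onsets)
  p <- if (all(resp == base) && test == "signed_rank") {
    1  # all differences zero: signed-rank is degenerate, nothing evoked
  } else {
    suppressWarnings(if (test == "signed_rank") {
      stats::wilcox.test(resp, base, paired = TRUE, exact = FALSE)$p.value
    } else {
      stats::wilcox.test(resp, base, exact = FALSE)$p.value
    })
  }
  if (is.na(p)) p <- 1
  # 1 ms-binned pulse-aligned histogram, counts summed across pulses
  edges <- seq(-baseline_ms, window_ms, by = 1) / 1000
  rel <- unlist(lapply(pulse_onsets, function(on) {
    spike_times[spike_times >= on - baseline_ms / 1000 &
                  spike_times < on + w] - on
  }))
  h <- if (length(rel)) {
    tabulate(findInterval(rel, edges), nbins = length(edges) - 1)
  } else rep(0L, length(edges) - 1)
  base_bins <- h[seq_len(baseline_ms)]
  resp_bins <- h[baseline_ms + seq_len(window_ms)]
  bsd <- stats::sd(base_bins)
  z_peak <- if (bsd > 0) max((resp_bins - mean(base_bins)) / bsd) else {
    if (any(resp_bins > 0)) Inf else NA_real_
  }
  first <- vapply(pulse_onsets, function(on) {
    s <- spike_times[spike_times >= on & spike_times < on + w]
    if (length(s)) (s[1] - on) * 1000 else NA_real_
  }, numeric(1))
  lat <- if (all(is.na(first))) NA_real_ else stats::median(first, na.rm = TRUE)
  structure(list(p_value = p, z_peak = z_peak, first_spike_latency_ms = lat,
                 n_pulses = length(pulse_onsets), window_ms = window_ms,
                 test = test),
            class = "photoresponse")
}

#' Classify a unit from its light-response statistics
#'
#' MGN units are called MGN-to-BLA projectors when the signed-rank p-value
#' is below `p_threshold` and the peak z-score exceeds `z_threshold` inside
#' the 10 ms response window; BLA units are called in-network when the
#' rank-sum p-value is below `p_threshold` inside the 50 ms window.
#' Everything else keeps the region's unidentified label.
#'
#' @param resp a [photoresponse_stats()] result computed with the
#'   region-appropriate window.
#' @param region "MGN" or "BLA".
#' @param p_threshold significance threshold (default 0.001).
#' @param z_threshold peak z threshold for MGN tagging (default 3.5).
#' @param mgn_window_ms,bla_window_ms response windows the statistics must
#'   have been computed with (10 and 50 ms).
#' @return one of "MGN_to_BLA", "MGN_untagged", "BLA_in", "BLA_out".
#' @export
classify_unit <- function(resp, region = c("MGN", "BLA"), p_threshold = 0.001,
                          z_threshold = 3.5, mgn_window_ms = 10,
                          bla_window_ms = 50) {
  region <- match.arg(region)
  want <- if (region == "MGN") mgn_window_ms else bla_window_ms
  if (resp$window_ms != want) {
    stop_input("photoresponse computed with a %g ms window; %s requires %g ms",
               resp$window_ms, region, want)
  }
  if (region == "MGN") {
    tagged <- !is.na(resp$p_value) && resp$p_value < p_threshold &&
      !is.na(resp$z_peak) && resp$z_peak > z_threshold
    if (tagged) "MGN_to_BLA" else "MGN_untagged"
  } else {
    if (!is.na(resp$p_value) && resp$p_value < p_threshold) "BLA_in" else "BLA_out"
  }
}

#' Phototag every unit in a session
#'
#' Runs [photoresponse_stats()] and [classify_unit()] over all units, using
#' the 5 ms 1 Hz pulse block and each unit's recorded region (signed-rank /
#' 10 ms for MGN, rank-sum / 50 ms for BLA).
#'
#' @param session an `ephys_session`.
#' @param ... thresholds passed to [classify_unit()].
#' @return data.frame: unit_id, region, p_value, z_peak, latency_ms, class.
#' @export
tag_session <- function(session, ...) {
  pulses <- session$laser[session$laser$width_s == 0.005 &
                            session$laser$freq_hz == 1, "onset_s"]
  if (length(pulses) < 10) stop_input("need >= 10 pulses in the 1 Hz block")
  out <- lapply(seq_len(nrow(session$units)), function(i) {
    uid <- session$units$unit_id[i]
    region <- session$units$region[i]
    resp <- if (region == "MGN") {
      photoresponse_stats(session$spikes[[uid]], pulses, window_ms = 10,
                          test = "signed_rank")
    } else {
      photoresponse_stats(session$spikes[[uid]], pulses, window_ms = 50,
                          test = "rank_sum")
    }
    data.frame(unit_id = uid, region = region, p_value = resp$p_value,
               z_peak = resp$z_peak, latency_ms = resp$first_spike_latency_ms,
               class = classify_unit(resp, region, ...))
  })
  do.call(rbind, out)
}
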