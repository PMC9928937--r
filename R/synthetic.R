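#' Phasic response template for a simulated unit
#'
#' Describes how a unit's instantaneous firing rate departs from baseline
#' around the two conditioned stimuli. Each cue effect is a step at
#' `onset_latency_s` after cue onset that decays exponentially with time
#' constant `decay_s`; `sustained_hz` adds a constant offset for the whole
#' tone. Negative amplitudes model inhibition; the total rate is rectified at
#' zero before spikes are drawn.
#'
#' @param label template name, carried into the ground truth.
#' @param cue_e_hz,cue_a_hz signed phasic amplitude (Hz) for the reward (E)
#'   and punishment (A) cue.
#' @param latency_s onset latency of the phasic effect after cue onset.
#' @param decay_s exponential decay constant of the phasic effect.
#' @param sustained_hz constant rate offset during the tone (both cues).
#' @return a `response_template` list.
#' @export
response_template <- function(label, cue_e_hz = 0, cue_a_hz = 0,
                              latency_s = 0.015, decay_s = 0.3,
                              sustained_hz = 0) {
  stopifnot(is.character(label), latency_s >= 0, decay_s > 0)
  structure(list(label = label, cue_e_hz = cue_e_hz, cue_a_hz = cue_a_hz,
                 latency_s = latency_s, decay_s = decay_s,
                 sustained_hz = sustained_hz),
            class = "response_template")
}

#' Default response-template battery
#'
#' Five archetypes spanning the profiles the clustering stage is meant to
#' separate: excitation to one cue, to both (arousal-like), inhibition, and
#' no task response.
#' @param baseline_hz baseline rate the inhibited template must not drive
#'   below zero for too long (amplitudes are chosen accordingly).
#' @return list of [response_template()].
#' @export
default_templates <- function(baseline_hz = 5) {
  list(
    response_template("E_excited", cue_e_hz = 15),
    response_template("A_excited", cue_a_hz = 15),
    response_template("both_excited", cue_e_hz = 15, cue_a_hz = 15,
                      decay_s = 0.25),
    response_template("both_inhibited", cue_e_hz = -baseline_hz,
                      cue_a_hz = -baseline_hz, decay_s = 0.5),
    response_template("flat")
  )
}

# The valence/arousal category a template should land in, given ideal
# statistics; used for ground truth.
.template_truth <- function(tp) {
  sig <- function(a) if (a == 0) "" else if (a > 0) "+" else "-"
  e <- sig(tp$cue_e_hz); a <- sig(tp$cue_a_hz)
  if (e == "" && a == "") return("none")
  paste0(if (e != "") paste0("E", e) else "", if (a != "") paste0("A", a) else "")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. Defaults reproduce the task
#' structure of a discrimination session: 75 reward (CS-E) and 35 punishment
#' (CS-A) trials of a 4 s tone, US onset jittered 1--1.5 s after cue onset,
#' cue onsets separated by the tone plus a uniform 16--24 s inter-trial
#' interval, and a post-task laser epoch for phototagging.
#'
#' @param n_subjects number of simulated subjects (sessions).
#' @param units_per_subpop named counts of units per subject for the four
#'   subpopulations `MGN_untagged`, `MGN_to_BLA`, `BLA_out`, `BLA_in`.
#' @param n_reward_trials,n_punish_trials CS-E / CS-A trial counts.
#' @param tone_duration_s tone (CS) duration in seconds.
#' @param us_jitter_s length-2 interval for US onset after cue onset.
#' @param iti_s center and halfwidth of the uniform gap between tone offset
#'   and the next cue onset.
#' @param baseline_rate_hz baseline firing rate of every unit.
#' @param response_templates list of [response_template()]s sampled per unit.
#' @param tonic_slope_spikes_per_trial drift in firing rate, expressed as the
#'   expected change in a 1 s window count per trial, for drifting units.
#' @param tonic_fraction fraction of units carrying the tonic drift.
#' @param lick_rate_iti_hz,lick_rate_anticip_hz Poisson lick rates outside /
#'   inside reward-trial anticipatory windows.
#' @param tag_latency_ms length-2 interval of light-evoked first-spike
#'   latency for tagged (MGN to BLA) units.
#' @param tag_reliability per-pulse probability that a tagged unit spikes.
#' @param network_latency_ms,network_reliability polysynaptic light response
#'   of in-network BLA units.
#' @param seed master seed; every derived random stream is a pure function
#'   of it.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 3,
                       units_per_subpop = c(MGN_untagged = 14, MGN_to_BLA = 6,
                                            BLA_out = 12, BLA_in = 8),
                       n_reward_trials = 75, n_punish_trials = 35,
                       tone_duration_s = 4, us_jitter_s = c(1.0, 1.5),
                       iti_s = c(center = 20, halfwidth = 4),
                       baseline_rate_hz = 5,
                       response_templates = default_templates(baseline_rate_hz),
                       tonic_slope_spikes_per_trial = 0.05,
                       tonic_fraction = 0.2,
                       lick_rate_iti_hz = 1, lick_rate_anticip_hz = 6,
                       tag_latency_ms = c(3, 8), tag_reliability = 0.9,
                       network_latency_ms = c(12, 35),
                       network_reliability = 0.6,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, units_per_subpop = units_per_subpop,
              n_reward_trials = n_reward_trials,
              n_punish_trials = n_punish_trials,
              tone_duration_s = tone_duration_s, us_jitter_s = us_jitter_s,
              iti_s = iti_s, baseline_rate_hz = baseline_rate_hz,
              response_templates = response_templates,
              tonic_slope_spikes_per_trial = tonic_slope_spikes_per_trial,
              tonic_fraction = tonic_fraction,
              lick_rate_iti_hz = lick_rate_iti_hz,
              lick_rate_anticip_hz = lick_rate_anticip_hz,
              tag_latency_ms = tag_latency_ms,
              tag_reliability = tag_reliability,
              network_latency_ms = network_latency_ms,
              network_reliability = network_reliability,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_input("invalid sim_config: %s", msg)
  chk(cfg$n_subjects >= 0, "n_subjects must be >= 0")
  chk(all(cfg$units_per_subpop >= 0), "unit counts must be >= 0")
  chk(all(c("MGN_untagged", "MGN_to_BLA", "BLA_out", "BLA_in") %in%
            names(cfg$units_per_subpop)), "units_per_subpop must name all four subpopulations")
  chk(cfg$n_reward_trials >= 0 && cfg$n_punish_trials >= 0, "trial counts must be >= 0")
  chk(cfg$tone_duration_s > 0, "tone duration must be positive")
  chk(length(cfg$us_jitter_s) == 2 && cfg$us_jitter_s[1] <= cfg$us_jitter_s[2],
      "us_jitter_s must be an ordered interval")
  chk(cfg$us_jitter_s[1] > 0 && cfg$us_jitter_s[2] < cfg$tone_duration_s,
      "US jitter interval must lie inside (0, tone_duration_s)")
  chk(length(cfg$iti_s) == 2 && cfg$iti_s[[2]] < cfg$iti_s[[1]] && cfg$iti_s[[2]] >= 0,
      "ITI halfwidth must be non-negative and smaller than the center")
  chk(cfg$baseline_rate_hz >= 0, "baseline rate must be >= 0")
  chk(all(c(cfg$lick_rate_iti_hz, cfg$lick_rate_anticip_hz) >= 0), "lick rates must be >= 0")
  chk(cfg$tag_reliability >= 0 && cfg$tag_reliability <= 1, "tag_reliability must be in [0, 1]")
  chk(cfg$tonic_fraction >= 0 && cfg$tonic_fraction <= 1, "tonic_fraction must be in [0, 1]")
  invisible(cfg)
}

#' Generate a pseudorandomly interleaved trial table
#'
#' Shuffles `n_reward_trials` CS-E and `n_punish_trials` CS-A trials into one
#' sequence, places cue onsets separated by the tone duration plus a uniform
#' inter-trial gap, and draws each trial's US onset uniformly inside the
#' jitter interval after cue onset.
#'
#' @param config a [sim_config()].
#' @param seed seed for the shuffle and the timing draws (defaults to the
#'   config's seed).
#' @param t_start onset of the first cue, leaving room for pre-cue windows.
#' @return data.frame with columns `trial`, `cs_type` ("E"/"A"),
#'   `cs_onset_s`, `us_onset_s`; tone duration attached as attribute
#'   `tone_duration_s`.
#' @export
generate_trial_table <- function(config, seed = config$seed, t_start = 30) {
  validate_sim_config(config)
  nE <- config$n_reward_trials; nA <- config$n_punish_trials
  n <- nE + nA
  if (n == 0) {
    tab <- data.frame(trial = integer(0), cs_type = character(0),
                      cs_onset_s = numeric(0), us_onset_s = numeric(0))
    attr(tab, "tone_duration_s") <- config$tone_duration_s
    return(tab)
  }
  with_seed(seed, {
    cs_type <- sample(c(rep("E", nE), rep("A", nA)))
    gaps <- runif(n - 1, config$iti_s[[1]] - config$iti_s[[2]],
                  config$iti_s[[1]] + config$iti_s[[2]])
    cs_onset <- t_start + c(0, cumsum(config$tone_duration_s + gaps))
    us_onset <- cs_onset + runif(n, config$us_jitter_s[1], config$us_jitter_s[2])
  })
  tab <- data.frame(trial = seq_len(n), cs_type = cs_type,
                    cs_onset_s = cs_onset, us_onset_s = us_onset)
  attr(tab, "tone_duration_s") <- config$tone_duration_s
  tab
}

# Piecewise rate function of one unit on a time grid, in Hz.
.unit_rate_on_grid <- function(grid, template, baseline_hz, tonic_slope,
                               trials, tone_s) {
  rate <- rep(baseline_hz, length(grid))
  if (nrow(trials) > 0) {
    # trial epochs: boundaries midway between consecutive cue onsets
    mids <- if (nrow(trials) > 1) {
      (trials$cs_onset_s[-1] + trials$cs_onset_s[-nrow(trials)]) / 2
    } else numeric(0)
    epoch <- findInterval(grid, mids) + 1L  # 1..n_trials
    rate <- rate + tonic_slope * (epoch - 1L)
    dt <- grid[2] - grid[1]
    n <- length(grid)
    span <- function(a, b) {  # grid indices with a <= t < b
      i0 <- max(1L, ceiling(a / dt - 1e-9) + 1L)
      i1 <- min(n, ceiling(b / dt - 1e-9))
      if (i0 > i1) integer(0) else i0:i1
    }
    for (i in seq_len(nrow(trials))) {
      cs <- trials$cs_onset_s[i]
      amp <- if (trials$cs_type[i] == "E") template$cue_e_hz else template$cue_a_hz
      if (template$sustained_hz != 0) {
        idx <- span(cs, cs + tone_s)
        rate[idx] <- rate[idx] + template$sustained_hz
      }
      if (amp != 0) {
        t0 <- cs + template$latency_s
        idx <- span(t0, cs + tone_s)
        if (length(idx)) {
          rate[idx] <- rate[idx] +
            amp * exp(-(grid[idx] - t0) / template$decay_s)
        }
      }
    }
  }
  pmax(rate, 0)
}

#' Simulate one unit's spike train
#'
#' Draws an inhomogeneous-Poisson spike train whose instantaneous rate is
#' baseline plus the template's per-cue phasic kernels and sustained tone
#' term, plus a linear-in-trial-index tonic drift. The rate is evaluated on a
#' fine grid (piecewise constant), rectified at zero, and spikes are placed
#' uniformly within grid steps.
#'
#' @param template a [response_template()].
#' @param baseline_hz baseline rate (Hz).
#' @param tonic_slope drift in Hz per trial (equivalently spikes per trial in
#'   a 1 s window), applied across each trial's whole epoch.
#' @param trials trial table from [generate_trial_table()].
#' @param seed RNG seed.
#' @param dt_s rate-grid resolution.
#' @param t_end session end; defaults to 10 s past the last tone offset.
#' @return sorted numeric vector of spike times (s).
#' @export
simulate_unit <- function(template, baseline_hz, tonic_slope, trials, seed,
                          dt_s = 0.01, t_end = NULL) {
  tone_s <- attr(trials, "tone_duration_s") %||% 4
  if (is.null(t_end)) {
    t_end <- if (nrow(trials)) max(trials$cs_onset_s) + tone_s + 10 else 100
  }
  grid <- seq(0, t_end - dt_s, by = dt_s)
  rate <- .unit_rate_on_grid(grid, template, baseline_hz, tonic_slope,
                             trials, tone_s)
  with_seed(seed, {
    counts <- stats::rpois(length(grid), rate * dt_s)
    total <- sum(counts)
    times <- rep(grid, counts) + stats::runif(total, 0, dt_s)
  })
  sort(times)
}

#' Simulate licking as a piecewise-homogeneous Poisson process
#'
#' Licks occur at `iti_rate` everywhere except inside anticipatory windows
#' (cue onset to US onset), where reward trials use `anticip_rate` and
#' punishment trials `anticip_rate_A`.
#'
#' @param trials trial table.
#' @param iti_rate,anticip_rate rates in Hz.
#' @param seed RNG seed.
#' @param anticip_rate_A anticipatory rate on CS-A trials (default: ITI rate,
#'   i.e. no learned response to punishment cues).
#' @param t_end session end.
#' @return sorted lick times (s).
#' @export
simulate_licks <- function(trials, iti_rate, anticip_rate, seed,
                           anticip_rate_A = iti_rate, t_end = NULL) {
  stopifnot(iti_rate >= 0, anticip_rate >= 0, anticip_rate_A >= 0)
  tone_s <- attr(trials, "tone_duration_s") %||% 4
  if (is.null(t_end)) {
    t_end <- if (nrow(trials)) max(trials$cs_onset_s) + tone_s + 10 else 100
  }
  # segment the session into [start, end, rate) pieces
  starts <- 0; rates <- iti_rate
  if (nrow(trials)) {
    ord <- order(trials$cs_onset_s)
    for (i in ord) {
      a <- trials$cs_onset_s[i]; b <- trials$us_onset_s[i]
      r <- if (trials$cs_type[i] == "E") anticip_rate else anticip_rate_A
      starts <- c(starts, a, b); rates <- c(rates, r, iti_rate)
    }
  }
  ends <- c(starts[-1], t_end)
  with_seed(seed, {
    times <- unlist(lapply(seq_along(starts), function(i) {
      len <- ends[i] - starts[i]
      if (len <= 0 || rates[i] == 0) return(numeric(0))
      n <- stats::rpois(1, rates[i] * len)
      stats::runif(n, starts[i], ends[i])
    }))
  })
  sort(times)
}

# Laser stimulation schedule: 1 s pulses, then 5 ms pulse trains at
# 1 / 10 / 20 Hz, appended after the task.
.laser_schedule <- function(t0) {
  blocks <- list(
    data.frame(onset_s = t0 + seq(0, by = 10, length.out = 5),
               width_s = 1, freq_hz = 0.1),
    data.frame(onset_s = t0 + 60 + seq(0, by = 1, length.out = 100),
               width_s = 0.005, freq_hz = 1),
    data.frame(onset_s = t0 + 170 + seq(0, by = 0.1, length.out = 100),
               width_s = 0.005, freq_hz = 10),
    data.frame(onset_s = t0 + 190 + seq(0, by = 0.05, length.out = 100),
               width_s = 0.005, freq_hz = 20)
  )
  do.call(rbind, blocks)
}

# Light-evoked spikes for a responsive unit: one spike per pulse with
# probability `reliability`, at a uniform latency inside `latency_ms`.
.evoked_spikes <- function(pulses, latency_ms, reliability, seed) {
  with_seed(seed, {
    hit <- stats::runif(nrow(pulses)) < reliability
    lat <- stats::runif(nrow(pulses), latency_ms[1], latency_ms[2]) / 1000
  })
  sort(pulses$onset_s[hit] + lat[hit])
}

#' Simulate a full multi-subject study with ground truth
#'
#' Generates `n_subjects` sessions. Each unit is assigned a subpopulation, a
#' response template (uniformly at random from the config's battery), and
#' with probability `tonic_fraction` a tonic drift. Tagged (MGN to BLA)
#' units and in-network BLA units additionally fire light-evoked spikes
#' during a post-task laser epoch. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `sessions` (list of session objects, see
#'   [write_session()] for the on-disk schema) and `ground_truth`
#'   (data.frame: unit_id, subject, region, subpopulation, template,
#'   valence_category, tonic_slope, tag_latency_ms).
#' @export
simulate_study <- function(config = sim_config()) {
  validate_sim_config(config)
  n_per <- sum(config$units_per_subpop)
  seeds <- derive_seeds(config$seed, config$n_subjects * (3 + 3 * n_per) + 1)
  si <- 0L; next_seed <- function() { si <<- si + 1L; seeds[si] }
  sessions <- vector("list", config$n_subjects)
  gt <- list()
  for (s in seq_len(config$n_subjects)) {
    subject <- sprintf("subj%02d", s)
    trials <- generate_trial_table(config, seed = next_seed())
    tone_s <- config$tone_duration_s
    task_end <- if (nrow(trials)) max(trials$cs_onset_s) + tone_s + 10 else 100
    licks <- simulate_licks(trials, config$lick_rate_iti_hz,
                            config$lick_rate_anticip_hz, seed = next_seed(),
                            t_end = task_end)
    laser <- .laser_schedule(task_end + 30)
    t_end <- max(laser$onset_s) + 5
    subpops <- rep(names(config$units_per_subpop), config$units_per_subpop)
    spikes <- list(); units <- list()
    tmpl_idx <- with_seed(next_seed(), {
      list(tmpl = sample.int(length(config$response_templates), n_per, replace = TRUE),
           drifting = stats::runif(n_per) < config$tonic_fraction)
    })
    for (u in seq_len(n_per)) {
      unit_id <- sprintf("%s_u%03d", subject, u)
      subpop <- subpops[u]
      region <- if (startsWith(subpop, "MGN")) "MGN" else "BLA"
      tp <- config$response_templates[[tmpl_idx$tmpl[u]]]
      slope <- if (tmpl_idx$drifting[u]) config$tonic_slope_spikes_per_trial else 0
      st <- simulate_unit(tp, config$baseline_rate_hz, slope, trials,
                          seed = next_seed(), t_end = t_end)
      tag_lat <- NA_real_
      if (subpop == "MGN_to_BLA") {
        ev <- .evoked_spikes(laser, config$tag_latency_ms,
                             config$tag_reliability, next_seed())
        st <- sort(c(st, ev))
        tag_lat <- mean(config$tag_latency_ms)
      } else if (subpop == "BLA_in") {
        ev <- .evoked_spikes(laser, config$network_latency_ms,
                             config$network_reliability, next_seed())
        st <- sort(c(st, ev))
        tag_lat <- mean(config$network_latency_ms)
      } else {
        next_seed()  # keep the seed stream aligned across subpopulations
      }
      next_seed()
      spikes[[unit_id]] <- st
      units[[u]] <- data.frame(unit_id = unit_id, subject = subject,
                               region = region, channel = u)
      gt[[length(gt) + 1L]] <- data.frame(
        unit_id = unit_id, subject = subject, region = region,
        subpopulation = subpop, template = tp$label,
        valence_category = .template_truth(tp), tonic_slope = slope,
        tag_latency_ms = tag_lat)
    }
    sessions[[s]] <- structure(
      list(subject_id = subject, trials = trials,
           units = do.call(rbind, units), spikes = spikes, licks = licks,
           laser = laser,
           metadata = list(format_version = "1", seed = config$seed,
                           tone_duration_s = tone_s)),
      class = "ephys_session")
  }
  list(sessions = sessions, ground_truth = do.call(rbind, gt))
}

#' @export
print.ephys_session <- function(x, ...) {
  cat(sprintf("<ephys_session %s: %d units, %d trials, %d licks, %d laser pulses>\n",
              x$subject_id, nrow(x$units), nrow(x$trials), length(x$licks),
              nrow(x$laser)))
  invisible(x)
}
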