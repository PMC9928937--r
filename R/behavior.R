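#' Detect licks from an IR beam-break voltage trace
#'
#' A lick is a downward crossing of the threshold; crossings closer together
#' than the refractory period are merged into one event (sensor chatter).
#'
#' @param voltage numeric vector, uniformly sampled.
#' @param fs_hz sampling rate.
#' @param threshold_v crossing threshold (volts); an event starts where the
#'   trace drops below it.
#' @param refractory_s minimum separation between successive events; default
#'   30 ms, well under the ~100 ms period of rhythmic mouse licking.
#' @return event times in seconds (time of the crossing sample).
#' @export
detect_licks <- function(voltage, fs_hz, threshold_v, refractory_s = 0.03) {
  if (length(voltage) == 0) stop_input("empty voltage trace")
  below <- voltage < threshold_v
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  times <- (crossings - 1) / fs_hz
  if (length(times) <= 1) return(times)
  keep <- c(TRUE, diff(times) >= refractory_s)
  # merge chains: an event only survives if it is >= refractory after the
  # last *kept* event, not the last crossing
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] >= refractory_s) out <- c(out, t)
  out
}

#' Per-trial anticipatory and ITI lick counts
#'
#' Counts licks in each trial's anticipatory window (cue onset to US onset,
#' half-open) and in a duration-matched window immediately preceding cue
#' onset, and forms the per-trial difference score (anticipatory minus ITI).
#'
#' @param licks lick event times (s).
#' @param trials trial table.
#' @return data.frame: trial, cs_type, anticipatory, iti, difference.
#' @export
per_trial_lick_counts <- function(licks, trials) {
  d <- trials$us_onset_s - trials$cs_onset_s
  stopifnot(all(d > 0))
  ant <- count_in_windows(licks, trials$cs_onset_s, trials$us_onset_s)
  iti <- count_in_windows(licks, trials$cs_onset_s - d, trials$cs_onset_s)
  data.frame(trial = trials$trial, cs_type = trials$cs_type,
             anticipatory = ant, iti = iti, difference = ant - iti)
}

#' Bootstrap power curve for anticipatory-vs-ITI comparisons
#'
#' For each candidate trial count n, resamples n trials with replacement
#' `n_iter` times and records the fraction of resamples in which a paired
#' Student's t test on anticipatory vs ITI counts is significant at `alpha`.
#'
#' @param counts output of [per_trial_lick_counts()].
#' @param trial_range candidate trial counts.
#' @param n_iter bootstrap iterations per count (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return data.frame `n_trials`, `power`, with `n_iter` and `alpha` as
#'   attributes.
#' @export
bootstrap_power <- function(counts, trial_range = 1:50, n_iter = 1000,
                            alpha = 0.05, seed = 1L) {
  if (nrow(counts) < 2) stop_input("need at least 2 trials")
  if (n_iter < 1) stop_input("n_iter must be >= 1")
  d <- counts$anticipatory - counts$iti
  power <- with_seed(seed, vapply(trial_range, function(n) {
    if (n < 2) return(0)  # a paired t test is undefined on one trial
    idx <- matrix(sample.int(length(d), n * n_iter, replace = TRUE), nrow = n)
    dm <- matrix(d[idx], nrow = n)
    m <- colMeans(dm)
    s <- sqrt(colSums((dm - rep(m, each = n))^2) / (n - 1))
    tt <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tt), df = n - 1)
    # zero-variance resamples give NaN t -> counted as not significant
    mean(!is.na(p) & p < alpha)
  }, numeric(1)))
  out <- data.frame(n_trials = trial_range, power = power)
  attr(out, "n_iter") <- n_iter
  attr(out, "alpha") <- alpha
  out
}

# paired t on one subset of an acquisition session
.acq_test <- function(sub) {
  if (stats::sd(sub$anticipatory - sub$iti) == 0) {
    return(list(p = NA_real_, effect_ok = FALSE))
  }
  p <- stats::t.test(sub$anticipatory, sub$iti, paired = TRUE)$p.value
  list(p = p, effect_ok = mean(sub$anticipatory) > mean(sub$iti))
}

# two-sample t on difference scores for one subset pair
.disc_test <- function(subE, subA) {
  dE <- subE$difference; dA <- subA$difference
  if (stats::sd(c(dE, dA)) == 0) return(list(p = NA_real_, effect_ok = FALSE))
  p <- tryCatch(stats::t.test(dE, dA)$p.value, error = function(e) NA_real_)
  list(p = p, effect_ok = sum(subE$anticipatory) > sum(subA$anticipatory))
}

#' Assess acquisition or discrimination learning
#'
#' Acquisition: paired t tests of anticipatory vs ITI lick counts on the
#' first 20 and last 20 reward trials; a subset passes if p < alpha and the
#' anticipatory mean exceeds the ITI mean. Discrimination: two-sample t
#' tests on per-trial difference scores (CS-E vs CS-A) over the first 20,
#' last 20, and a seeded random 20 trials of each type; a subset passes if
#' p < alpha and raw CS-E licks exceed raw CS-A licks. In both modes the
#' subject must also show at least one anticipatory lick on more than half
#' of the reward trials; `learned` requires any subset pass plus this rate
#' check.
#'
#' @param counts_E per-trial counts ([per_trial_lick_counts()]) for reward
#'   trials.
#' @param counts_A counts for punishment trials (discrimination mode only).
#' @param mode "acquisition" or "discrimination".
#' @param n_subset trials per subset (default 20, from the bootstrap power
#'   analysis).
#' @param alpha significance level (default 0.01).
#' @param seed seed for the random subset (recorded in the outcome).
#' @return a `learning_outcome` list: mode, subsets data.frame (subset, p,
#'   effect_ok, pass), anticipatory_rate, rate_ok, learned, seed.
#' @export
assess_learning <- function(counts_E, counts_A = NULL,
                            mode = c("discrimination", "acquisition"),
                            n_subset = 20, alpha = 0.01, seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(counts_E) < n_subset) stop_input("fewer reward trials than n_subset")
  first <- function(x) x[seq_len(n_subset), , drop = FALSE]
  last <- function(x) x[nrow(x) - n_subset + seq_len(n_subset), , drop = FALSE]
  if (mode == "acquisition") {
    tests <- list(first_20 = .acq_test(first(counts_E)),
                  last_20 = .acq_test(last(counts_E)))
  } else {
    if (is.null(counts_A)) stop_input("discrimination mode needs counts_A")
    if (nrow(counts_A) < n_subset) stop_input("fewer punishment trials than n_subset")
    rnd <- with_seed(seed, list(
      E = counts_E[sample.int(nrow(counts_E), n_subset), , drop = FALSE],
      A = counts_A[sample.int(nrow(counts_A), n_subset), , drop = FALSE]))
    tests <- list(first_20 = .disc_test(first(counts_E), first(counts_A)),
                  last_20 = .disc_test(last(counts_E), last(counts_A)),
                  random_20 = .disc_test(rnd$E, rnd$A))
  }
  subsets <- data.frame(
    subset = names(tests),
    p = vapply(tests, function(x) x$p, numeric(1)),
    effect_ok = vapply(tests, function(x) x$effect_ok, logical(1)))
  subsets$pass <- !is.na(subsets$p) & subsets$p < alpha & subsets$effect_ok
  rate <- mean(counts_E$anticipatory >= 1)
  structure(list(mode = mode, subsets = subsets, alpha = alpha,
                 anticipatory_rate = rate, rate_ok = rate > 0.5,
                 learned = any(subsets$pass) && rate > 0.5, seed = seed),
            class = "learning_outcome")
}

#' @export
print.learning_outcome <- function(x, ...) {
  cat(sprintf("<learning_outcome: %s, learned = %s (anticipatory rate %.2f)>\n",
              x$mode, x$learned, x$anticipatory_rate))
  print(x$subsets, row.names = FALSE)
  invisible(x)
}

#' Label trials as hit / miss / false alarm / correct rejection
#'
#' Crosses CS type with the presence of anticipatory licking: a reward trial
#' with at least one lick in the anticipatory window is a hit, otherwise a
#' miss; a punishment trial with a lick is a false alarm, otherwise a
#' correct rejection.
#'
#' @param licks lick times (s).
#' @param trials trial table.
#' @return character vector of labels, one per trial.
#' @export
classify_trial_outcomes <- function(licks, trials) {
  ant <- count_in_windows(licks, trials$cs_onset_s, trials$us_onset_s)
  ifelse(trials$cs_type == "E",
         ifelse(ant >= 1, "hit", "miss"),
         ifelse(ant >= 1, "false_alarm", "correct_rejection"))
}
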