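test_that("trial table has the session structure: counts, jitter, spacing", {
  cfg <- sim_config(seed = 1)
  tab <- generate_trial_table(cfg, seed = 1)
  expect_equal(nrow(tab), 110)
  expect_equal(sum(tab$cs_type == "E"), 75)
  expect_equal(sum(tab$cs_type == "A"), 35)
  for (seed in 1:5) {
    tb <- generate_trial_table(cfg, seed = seed)
    jit <- tb$us_onset_s - tb$cs_onset_s
    expect_true(all(jit >= 1.0 & jit <= 1.5))
    gaps <- diff(tb$cs_onset_s)
    expect_true(all(gaps >= 4 + 16 & gaps <= 4 + 24))
    expect_true(all(diff(tb$cs_onset_s) > 0))
  }
  expect_identical(generate_trial_table(cfg, seed = 3),
                   generate_trial_table(cfg, seed = 3))
})

test_that("empty trial request yields an empty table", {
  cfg <- sim_config(n_reward_trials = 0, n_punish_trials = 0)
  tab <- generate_trial_table(cfg, seed = 1)
  expect_equal(nrow(tab), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(us_jitter_s = c(2, 5)), "jitter")
  expect_error(sim_config(iti_s = c(center = 3, halfwidth = 4)), "halfwidth")
  expect_error(sim_config(tag_reliability = 1.5), "tag_reliability")
  expect_error(sim_config(n_subjects = -1), "n_subjects")
})

test_that("flat-template unit matches the homogeneous-Poisson count oracle", {
  tp <- response_template("flat")
  empty <- make_trials(0)[0, ]
  attr(empty, "tone_duration_s") <- 4
  totals <- vapply(1:20, function(seed) {
    length(simulate_unit(tp, baseline_hz = 5, tonic_slope = 0, empty,
                         seed = seed, t_end = 100))
  }, numeric(1))
  # E[count] = 500, SD = sqrt(500); mean of 20 draws stays well within 3 SD
  expect_lt(abs(mean(totals) - 500), 3 * sqrt(500))
  expect_true(all(abs(totals - 500) < 5 * sqrt(500)))
})

test_that("zero-effect templates produce no spurious cue response", {
  # with no phasic effect the paired response-vs-baseline test must reject
  # at its nominal 5% rate: check calibration with a binomial-consistent band
  tp <- response_template("flat")
  trials <- make_trials(20, cs_type = rep("E", 20))
  rej <- vapply(1:200, function(seed) {
    st <- simulate_unit(tp, baseline_hz = 8, tonic_slope = 0, trials,
                        seed = seed)
    resp <- count_in_windows(st, trials$cs_onset_s, trials$cs_onset_s + 1)
    base <- count_in_windows(st, trials$cs_onset_s - 1, trials$cs_onset_s)
    if (sd(resp - base) == 0) return(FALSE)
    t.test(resp, base, paired = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("OLS on per-trial counts recovers the tonic drift slope", {
  tp <- response_template("flat")
  trials <- make_trials(40, cs_type = rep("E", 40))
  covered <- vapply(1:100, function(seed) {
    st <- simulate_unit(tp, baseline_hz = 5, tonic_slope = 0.1, trials,
                        seed = seed)
    counts <- count_in_windows(st, trials$cs_onset_s - 1, trials$cs_onset_s)
    fit <- lm(counts ~ idx, data = data.frame(idx = seq_len(40)))
    ci <- confint(fit, "idx")
    ci[1] <= 0.1 && 0.1 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("Fano factor of homogeneous window counts is ~1", {
  fanos <- vapply(1:100, function(seed) {
    st <- flat_spikes(5, 100, seed)
    counts <- count_in_windows(st, 0:99, 1:100)
    var(counts) / mean(counts)
  }, numeric(1))
  expect_lt(abs(mean(fanos) - 1), 0.05)
})

test_that("lick simulation elevates anticipatory counts on reward trials only", {
  trials <- make_trials(40, cs_type = rep(c("E", "A"), 20))
  licks <- simulate_licks(trials, iti_rate = 1, anticip_rate = 6, seed = 2)
  counts <- per_trial_lick_counts(licks, trials)
  cE <- counts[counts$cs_type == "E", ]
  expect_gt(mean(cE$anticipatory), mean(cE$iti))
  expect_identical(simulate_licks(trials, 1, 6, seed = 9),
                   simulate_licks(trials, 1, 6, seed = 9))
  expect_length(simulate_licks(trials, 0, 0, seed = 1), 0)
})

test_that("null lick rates give nominal paired-test false-positive rate", {
  trials <- make_trials(20, cs_type = rep("E", 20))
  rej <- vapply(1:1000, function(seed) {
    licks <- simulate_licks(trials, iti_rate = 3, anticip_rate = 3, seed = seed)
    counts <- per_trial_lick_counts(licks, trials)
    d <- counts$anticipatory - counts$iti
    if (sd(d) == 0) return(FALSE)
    t.test(counts$anticipatory, counts$iti, paired = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("simulate_study labels all subpopulations once per unit and is reproducible", {
  cfg <- sim_config(n_subjects = 3,
                    units_per_subpop = c(MGN_untagged = 2, MGN_to_BLA = 2,
                                         BLA_out = 2, BLA_in = 2),
                    seed = 5)
  st <- simulate_study(cfg)
  expect_length(st$sessions, 3)
  expect_setequal(unique(st$ground_truth$subpopulation),
                  c("MGN_untagged", "MGN_to_BLA", "BLA_out", "BLA_in"))
  # label closure: one ground-truth record per generated unit
  all_units <- unlist(lapply(st$sessions, function(s) s$units$unit_id))
  expect_identical(sort(st$ground_truth$unit_id), sort(all_units))
  expect_false(any(duplicated(st$ground_truth$unit_id)))
  # determinism: byte-identical serialized sessions
  st2 <- simulate_study(cfg)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_session(st$sessions[[1]], d1)
  write_session(st2$sessions[[1]], d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
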