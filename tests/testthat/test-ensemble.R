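test_that("PSTH matches hand computation and handles empty trains", {
  events <- seq(100, by = 30, length.out = 10)
  spikes <- list(u1 = events, u2 = numeric(0))
  p <- compute_psth(spikes, events, bin_width_s = 0.05, window = c(-0.5, 0.5))
  first_post <- which(p$edges[-length(p$edges)] >= 0)[1]
  expect_equal(unname(p$values["u1", first_post]), 20)  # 1 spike / 0.05 s
  expect_true(all(p$values["u1", -first_post] == 0))
  expect_true(all(p$values["u2", ] == 0))
  expect_error(compute_psth(spikes, numeric(0)), "events")
})

test_that("z-scoring leaves baseline bins at mean 0, SD 1 and is causal", {
  set.seed(3)
  events <- seq(100, by = 30, length.out = 20)
  spikes <- lapply(stats::setNames(1:8, paste0("u", 1:8)),
                   function(i) flat_spikes(3 + i, 700, i))
  p <- compute_psth(spikes, events, bin_width_s = 0.1, window = c(-2, 4))
  z <- zscore_smooth(p, baseline_window = c(-2, 0), smooth_bins = 0)
  lo <- z$edges[-length(z$edges)]
  in_base <- lo >= -2 & lo < 0
  for (u in rownames(z$values)) {
    expect_lt(abs(mean(z$values[u, in_base])), 1e-9)
    expect_lt(abs(sd(z$values[u, in_base]) - 1), 1e-9)
  }
  # constant-rate unit has zero baseline SD and is removed
  spikes$const <- seq(0.05, 700, by = 0.1)
  p2 <- compute_psth(spikes, events, bin_width_s = 0.1, window = c(-2, 4))
  z2 <- zscore_smooth(p2, smooth_bins = 5)
  expect_true("const" %in% attr(z2, "removed"))
  expect_false("const" %in% rownames(z2$values))
  # causal smoothing: an impulse spreads only forward in time
  imp <- matrix(0, 1, 50); imp[1, 20] <- 1; rownames(imp) <- "i"
  sm <- smooth_causal_gaussian(imp, k = 8)
  expect_true(all(sm[1, 1:19] == 0))
  expect_gt(sm[1, 20], 0)
  expect_gt(sm[1, 24], 0)
  # smoothing a constant series returns the constant
  expect_equal(smooth_causal_gaussian(rep(2.5, 40), k = 10), rep(2.5, 40),
               tolerance = 1e-9)
  expect_error(zscore_smooth(p, baseline_window = c(-5, 0)), "baseline")
})

test_that("responsiveness calls recover a CS-only response and stay quiet on nulls", {
  trials <- make_trials(30, cs_type = rep("E", 30))
  tp <- response_template("cs_only", cue_e_hz = 20, latency_s = 0.005,
                          decay_s = 0.1)
  hits <- vapply(1:100, function(seed) {
    st <- simulate_unit(tp, 5, 0, trials, seed = seed)
    # US "events" taken from a quiet part of the trial: 3 s after cue
    r <- classify_responsiveness(st, trials$cs_onset_s, trials$cs_onset_s + 3)
    r$label == "CS" && r$sign_cs == "excited"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # The scaled-baseline signed-rank comparison is mildly anticonservative by
  # construction (integer 100 ms counts vs quasi-continuous scaled 3 s
  # counts give an asymmetric null difference distribution); the calibrated
  # null none-rate at these conditions is ~0.96, not the nominal ~0.98.
  nulls <- vapply(1:1000, function(seed) {
    st <- flat_spikes(5, 800, seed)
    classify_responsiveness(st, trials$cs_onset_s, trials$cs_onset_s + 3)$label
  }, character(1))
  expect_gte(mean(nulls == "none"), 0.94)
  expect_lte(mean(nulls == "none"), 0.985)
})

test_that("inhibition is reported when the response z is negative", {
  trials <- make_trials(40, cs_type = rep("E", 40))
  tp <- response_template("inh", cue_e_hz = -20, latency_s = 0.001, decay_s = 0.5)
  st <- simulate_unit(tp, 20, 0, trials, seed = 6)
  r <- classify_responsiveness(st, trials$cs_onset_s, trials$cs_onset_s + 3)
  expect_true(r$responsive_cs)
  expect_equal(r$sign_cs, "inhibited")
})

test_that("valence decision tree maps every profile to its truth-table label", {
  trials <- make_trials(80, cs_type = rep(c("E", "A"), 40))
  E <- trials$cs_onset_s[trials$cs_type == "E"]
  A <- trials$cs_onset_s[trials$cs_type == "A"]
  profiles <- list(
    `E+A+` = c(25, 25), `E+A-` = c(25, -25), `E-A+` = c(-25, 25),
    `E-A-` = c(-25, -25), `E+` = c(25, 0), `E-` = c(-25, 0),
    `A+` = c(0, 25), `A-` = c(0, -25), none = c(0, 0))
  for (lab in names(profiles)) {
    amp <- profiles[[lab]]
    tp <- response_template(lab, cue_e_hz = amp[1], cue_a_hz = amp[2],
                            latency_s = 0.001, decay_s = 0.5)
    st <- simulate_unit(tp, 25, 0, trials, seed = 11)
    got <- classify_valence_category(st, E, A)$label
    expect_equal(got, lab, label = sprintf("profile %s classified as %s", lab, got))
  }
})

test_that("proportion tests switch to Fisher's exact below n = 5", {
  low <- matrix(c(3, 12, 10, 9), 2)
  expect_equal(proportion_test(low)$method, "fisher")
  high <- matrix(c(10, 10, 10, 10), 2)
  pt <- proportion_test(high)
  expect_equal(pt$method, "chi-squared")
  expect_equal(pt$p_value, 1.0)
  # balanced table is exactly p = 1 under the exact test too
  expect_equal(stats::fisher.test(high)$p.value, 1.0)
  expect_error(proportion_test(matrix(0, 2, 2)), "degenerate")
})

test_that("prevalence machinery: identical distributions are n.s., Bonferroni alpha is 0.05/pairs", {
  same <- matrix(rep(c(5, 6, 7, 8), 3), ncol = 3)
  colnames(same) <- c("a", "b", "c")
  pr <- prevalence_test(same)
  expect_false(pr$significant)
  expect_null(pr$posthoc)
  skew <- cbind(big = c(30, 31, 29, 30, 28), s1 = c(3, 4, 3, 2, 3),
                s2 = c(5, 4, 5, 6, 5))
  pr2 <- prevalence_test(skew)
  expect_true(pr2$significant)
  expect_equal(pr2$adjusted_alpha, 0.05 / 2)
  expect_equal(nrow(pr2$posthoc), 2)
  # leave-one-out counts: k rows, total = units not from the left-out subject
  lc <- loo_counts(c("x", "x", "y", "y", "x"),
                   c("s1", "s1", "s2", "s3", "s3"))
  expect_equal(dim(lc), c(3, 2))
  expect_equal(unname(lc["s1", ]), c(1L, 2L))
  expect_equal(unname(lc["s3", ]), c(2L, 1L))
})
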