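test_that("linkage matches the brute-force Ward oracle on small instances", {
  set.seed(20)
  for (rep in 1:50) {
    n <- sample(4:10, 1); p <- sample(2:5, 1)
    x <- matrix(rnorm(n * p), n)
    rownames(x) <- paste0("u", seq_len(n))
    oracle <- bf_ward(x)
    hc <- ward_cut(x, cutoff_fraction = 1)$hclust
    got <- hc_merges(hc)
    expect_equal(got$heights, oracle$heights, tolerance = 1e-8)
    for (k in seq_along(oracle$merges)) {
      expect_true(same_merge(got$pairs[[k]], oracle$merges[[k]]),
                  label = sprintf("merge %d of instance %d", k, rep))
    }
  }
})

test_that("well-separated blobs are cut into two pure clusters", {
  set.seed(21)
  x <- rbind(matrix(rnorm(20 * 3, mean = 0, sd = 0.3), 20),
             matrix(rnorm(20 * 3, mean = 20, sd = 0.3), 20))
  rownames(x) <- paste0("u", 1:40)
  cl <- ward_cut(x, cutoff_fraction = 0.23)
  expect_equal(length(cl$sizes), 2)
  expect_length(cl$discarded, 0)
  expect_equal(length(unique(cl$labels[1:20])), 1)
  expect_equal(length(unique(cl$labels[21:40])), 1)
  expect_false(cl$labels[1] == cl$labels[21])
})

test_that("clusters under the minimum size are discarded, not reassigned", {
  set.seed(22)
  x <- rbind(matrix(rnorm(20 * 3, 0, 0.3), 20),
             matrix(rnorm(20 * 3, 20, 0.3), 20),
             matrix(rnorm(2 * 3, -40, 0.3), 2))  # 2-member outlier group
  rownames(x) <- paste0("u", 1:42)
  cl <- ward_cut(x, cutoff_fraction = 0.23, min_cluster_size = 3)
  expect_setequal(cl$discarded, c("u41", "u42"))
  expect_true(all(is.na(cl$labels[c("u41", "u42")])))
  expect_equal(length(cl$sizes), 2)
})

test_that("degenerate geometry: identical points form one zero-height cluster", {
  x <- matrix(1, 6, 4); rownames(x) <- paste0("u", 1:6)
  cl <- ward_cut(x, cutoff_fraction = 0.5)
  expect_true(all(cl$hclust$height == 0))
  expect_equal(length(unique(cl$labels)), 1)
  expect_length(cl$discarded, 0)
  expect_error(ward_cut(x, cutoff_fraction = 1.5), "cutoff_fraction")
  expect_error(ward_cut(x[1, , drop = FALSE]), "2 units")
})

test_that("row order does not change memberships, only canonical labels", {
  set.seed(23)
  x <- rbind(matrix(rnorm(12 * 4, 0, 0.4), 12),
             matrix(rnorm(8 * 4, 10, 0.4), 8),
             matrix(rnorm(5 * 4, -10, 0.4), 5))
  rownames(x) <- paste0("u", 1:25)
  cl1 <- ward_cut(x, 0.3)
  perm <- sample(nrow(x))
  cl2 <- ward_cut(x[perm, ], 0.3)
  common <- rownames(x)
  expect_equal(ari(cl1$labels[common], cl2$labels[common]), 1)
  # canonical labels: cluster 1 is the largest
  expect_equal(unname(sort(cl1$sizes, decreasing = TRUE)[1]),
               unname(cl1$sizes[1]))
})

test_that("feature matrix concatenates conditions and drops degenerate units", {
  trials <- make_trials(40)
  E <- trials$cs_onset_s[trials$cs_type == "E"]
  A <- trials$cs_onset_s[trials$cs_type == "A"]
  spikes <- lapply(stats::setNames(1:6, paste0("u", 1:6)),
                   function(i) flat_spikes(5, 1100, i))
  spikes$metronome <- seq(0.05, 1100, by = 0.1)  # exactly 1 spike per 100 ms bin
  fm <- build_feature_matrix(spikes, list(E = E, A = A))
  nb <- (4 - (-2)) / 0.1
  expect_equal(ncol(fm$features), 2 * nb)
  expect_equal(fm$boundaries, c(1, nb + 1))
  expect_true("metronome" %in% fm$removed)
  expect_false("metronome" %in% rownames(fm$features))
  # pre-smoothing baseline columns have per-unit mean 0
  fm0 <- build_feature_matrix(spikes, list(E = E, A = A), smooth_bins = 0)
  base_cols <- 1:20  # [-2, 0) at 100 ms bins
  expect_lt(max(abs(rowMeans(fm0$features[, base_cols]))), 1e-9)
})

test_that("units from four templates are recovered with high ARI", {
  templates <- list(
    E = response_template("E", cue_e_hz = 30, latency_s = 0.01),
    A = response_template("A", cue_a_hz = 30, latency_s = 0.01),
    both = response_template("both", cue_e_hz = 30, cue_a_hz = 30,
                             latency_s = 0.01),
    inh = response_template("inh", cue_e_hz = -10, cue_a_hz = -10,
                            latency_s = 0.01, decay_s = 1))
  trials <- make_trials(60)
  truth <- rep(names(templates), each = 10)
  spikes <- list()
  for (i in seq_along(truth)) {
    spikes[[sprintf("u%02d", i)]] <-
      simulate_unit(templates[[truth[i]]], baseline_hz = 10, tonic_slope = 0,
                    trials, seed = 300 + i)
  }
  fm <- build_feature_matrix(spikes, list(
    E = trials$cs_onset_s[trials$cs_type == "E"],
    A = trials$cs_onset_s[trials$cs_type == "A"]))
  cl <- ward_cut(fm, cutoff_fraction = 0.23)
  kept <- !is.na(cl$labels)
  expect_gte(ari(cl$labels[kept], truth[kept]), 0.9)
})

test_that("cluster prevalence: k leave-one-out rows, dominant cluster detected", {
  set.seed(24)
  labels <- stats::setNames(c(rep(1L, 35), rep(2L, 8), rep(3L, 7)),
                            paste0("u", 1:50))
  subjects <- stats::setNames(rep(paste0("s", 1:5), 10), names(labels))
  res <- list(labels = labels, sizes = table(labels), discarded = character(0))
  class(res) <- "cluster_result"
  out <- cluster_prevalence_stats(res, subjects)
  expect_equal(nrow(out$loo_counts$all), 5)
  expect_true(out$tests$all$significant)
  expect_true(all(out$tests$all$posthoc$significant))
  expect_equal(out$tests$all$adjusted_alpha, 0.05 / 2)
  # equal-size clusters are exchangeable: n.s.
  eq <- res
  eq$labels <- stats::setNames(rep(1:2, 25), names(labels))
  out2 <- cluster_prevalence_stats(eq, subjects)
  expect_false(out2$tests$all$significant)
})
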