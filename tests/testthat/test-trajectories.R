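test_that("rank-2 population is captured by two components", {
  set.seed(10)
  b1 <- sin(seq(0, 3, length.out = 60)); b2 <- cos(seq(0, 5, length.out = 60))
  mix <- matrix(rnorm(40), 20, 2)
  z <- mix %*% rbind(b1, b2)  # 20 units x 60 bins, rank 2
  rownames(z) <- paste0("u", 1:20)
  ts <- compute_trajectories(list(E = z), n_components = 3)
  expect_gte(sum(ts$explained[1:2]), 0.999)
  expect_true(all(diff(ts$explained) <= 1e-12))
})

test_that("conditions share one basis and produce one trajectory each", {
  set.seed(11)
  mats <- lapply(1:4, function(i) {
    m <- matrix(rnorm(15 * 30), 15, 30); rownames(m) <- paste0("u", 1:15); m
  })
  names(mats) <- c("hit", "miss", "fa", "cr")
  ts <- compute_trajectories(mats, n_components = 3, smooth_bins = 10)
  expect_length(ts$trajectories, 4)
  expect_named(ts$trajectories, c("hit", "miss", "fa", "cr"))
  expect_true(all(vapply(ts$trajectories, ncol, 1L) == 3))
  rownames(mats[[2]]) <- paste0("v", 1:15)
  expect_error(compute_trajectories(mats), "unit set")
})

test_that("closed forms: polyline length and identical-condition distance", {
  line <- cbind(0:10, 0, 0)
  expect_equal(trajectory_length(line), 10)
  expect_true(all(trajectory_distance(line, line) == 0))
  set.seed(12)
  z <- matrix(rnorm(12 * 40), 12, 40); rownames(z) <- paste0("u", 1:12)
  ts <- compute_trajectories(list(a = z, b = z))
  expect_equal(max(trajectory_distance(ts$trajectories$a, ts$trajectories$b)),
               0, tolerance = 1e-10)
})

test_that("PCA projection reconstructs the centered data with all components", {
  set.seed(13)
  z <- matrix(rnorm(10 * 25), 10, 25); rownames(z) <- paste0("u", 1:10)
  ts <- compute_trajectories(list(E = z), n_components = 10)
  scores <- ts$trajectories$E
  recon <- scores %*% t(ts$rotation) +
    matrix(ts$center, nrow(scores), length(ts$center), byrow = TRUE)
  expect_equal(unname(recon), unname(t(z)), tolerance = 1e-8)
})

test_that("geometry is invariant to rigid rotation of the unit feature space", {
  set.seed(14)
  n_units <- 16
  mats <- list(E = matrix(rnorm(n_units * 40), n_units, 40),
               A = matrix(rnorm(n_units * 40), n_units, 40))
  mats <- lapply(mats, function(m) { rownames(m) <- paste0("u", 1:n_units); m })
  ts1 <- compute_trajectories(mats, n_components = 3)
  q <- qr.Q(qr(matrix(rnorm(n_units^2), n_units)))  # random orthogonal matrix
  rmats <- lapply(mats, function(m) { r <- q %*% m; rownames(r) <- rownames(m); r })
  ts2 <- compute_trajectories(rmats, n_components = 3)
  for (cn in names(mats)) {
    expect_equal(trajectory_length(ts1$trajectories[[cn]]),
                 trajectory_length(ts2$trajectories[[cn]]), tolerance = 1e-8)
  }
  expect_equal(trajectory_distance(ts1$trajectories$E, ts1$trajectories$A),
               trajectory_distance(ts2$trajectories$E, ts2$trajectories$A),
               tolerance = 1e-8)
  expect_equal(ts1$explained, ts2$explained, tolerance = 1e-8)
})

test_that("leave-one-out produces k values per condition", {
  set.seed(15)
  mats <- list(E = matrix(rnorm(20 * 30), 20, 30),
               A = matrix(rnorm(20 * 30), 20, 30))
  mats <- lapply(mats, function(m) { rownames(m) <- paste0("u", 1:20); m })
  subj <- rep(paste0("s", 1:5), each = 4)
  g <- trajectory_geometry(mats, subj, seq(-1, 1.9, by = 0.1))
  expect_equal(sum(g$lengths$condition == "E"), 5)
  expect_equal(sum(g$lengths$condition == "A"), 5)
  expect_error(trajectory_geometry(mats, rep("s1", 20), seq(-1, 1.9, 0.1)),
               "subjects")
})

test_that("fully separated groups give the exact 5-vs-5 rank-sum p-value", {
  stats <- structure(list(
    lengths = data.frame(left_out = rep(paste0("s", 1:5), 2),
                         condition = rep(c("E", "A"), each = 5),
                         length = c(10:14, 1:5)),
    distances = NULL,
    window_means = data.frame(left_out = rep(paste0("s", 1:5), 2),
                              pair = "E_vs_A",
                              window = rep(c("pre_cue", "post_cue"), each = 5),
                              mean_distance = c(1:5, 11:15))),
    class = "geometry_stats")
  cmp <- compare_geometry(stats)
  expect_equal(cmp$length_test$omnibus_p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(cmp$pre_vs_post$E_vs_A$omnibus_p, 2 / choose(10, 5),
               tolerance = 1e-12)
  # identical groups are not significant
  same <- stats
  same$lengths$length <- rep(c(1, 2, 3, 4, 5), 2)
  expect_false(compare_geometry(same)$length_test$significant)
})

test_that("populations diverging only after the cue separate post-cue distance", {
  bt <- seq(-2, 1.95, by = 0.05)
  post <- bt >= 0
  detected <- vapply(1:50, function(seed) {
    withr::with_seed(seed, {
      n <- 20
      base <- matrix(rnorm(n * length(bt), sd = 0.3), n)
      sigE <- outer(rnorm(n, 2), as.numeric(post) * (1 - exp(-(pmax(bt, 0)) / 0.3)))
      mats <- list(E = base + sigE, A = base)
      mats <- lapply(mats, function(m) { rownames(m) <- paste0("u", 1:n); m })
      g <- trajectory_geometry(mats, rep(paste0("s", 1:5), each = 4), bt)
      cmp <- compare_geometry(g)
      wm <- g$window_means
      post_gt_pre <- mean(wm$mean_distance[wm$window == "post_cue"]) >
        mean(wm$mean_distance[wm$window == "pre_cue"])
      cmp$pre_vs_post$E_vs_A$significant && post_gt_pre
    })
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})
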