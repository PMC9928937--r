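# Independent oracles and small fixture builders used across the suite.

# Brute-force O(n^3) Ward agglomeration: at every step merge the pair of
# clusters with the smallest Ward distance
#   d(A, B) = sqrt( 2|A||B| / (|A|+|B|) ) * ||centroid(A) - centroid(B)||,
# recording the merged member sets and heights. Written from the definition,
# independent of stats::hclust.
bf_ward <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters); best <- NULL; bestd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      A <- clusters[[i]]; B <- clusters[[j]]
      ca <- colMeans(x[A, , drop = FALSE]); cb <- colMeans(x[B, , drop = FALSE])
      d <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                  sum((ca - cb)^2))
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    merges[[length(merges) + 1L]] <- list(sort(clusters[[best[1]]]),
                                          sort(clusters[[best[2]]]))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Reconstruct the per-step merged member sets from an hclust tree.
hc_merges <- function(hc) {
  sets <- list(); out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    A <- if (a < 0) -a else sets[[a]]
    B <- if (b < 0) -b else sets[[b]]
    sets[[k]] <- sort(c(A, B))
    out[[k]] <- list(sort(A), sort(B))
  }
  list(pairs = out, heights = hc$height)
}

same_merge <- function(a, b) {
  (identical(a[[1]], b[[1]]) && identical(a[[2]], b[[2]])) ||
    (identical(a[[1]], b[[2]]) && identical(a[[2]], b[[1]]))
}

# Hand-built trial table: n trials alternating (or fixed) CS type, evenly
# spaced, with a fixed anticipatory duration.
make_trials <- function(n, cs_type = rep(c("E", "A"), length.out = n),
                        spacing = 25, anticip = 1.25, t0 = 30, tone = 4) {
  cs <- t0 + (seq_len(n) - 1) * spacing
  tab <- data.frame(trial = seq_len(n), cs_type = cs_type, cs_onset_s = cs,
                    us_onset_s = cs + anticip)
  attr(tab, "tone_duration_s") <- tone
  tab
}

# Homogeneous Poisson spike train on [0, t_end): the simplest independent
# generator, used where the unit must be unrelated to task events.
flat_spikes <- function(rate_hz, t_end, seed) {
  withr::with_seed(seed, {
    n <- rpois(1, rate_hz * t_end)
    sort(runif(n, 0, t_end))
  })
}

# Adjusted Rand index between two labelings (mclust's implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
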