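#' Population state-space trajectories by PCA
#'
#' Takes one z-scored PSTH matrix (units x bins) per condition, optionally
#' smooths each unit's series with the causal Gaussian, concatenates the
#' conditions along time, and fits a single PCA on the concatenated
#' bins-by-units matrix (time bins as observations, units as features,
#' features centered). Each condition's trajectory is its own bins projected
#' into the shared basis. Each PC is oriented so that its largest-magnitude
#' loading is positive, making the (otherwise arbitrary) sign reproducible.
#'
#' @param cond_mats named list of units x bins matrices sharing one unit set
#'   and bin grid.
#' @param n_components number of leading components retained in the
#'   trajectories (default 3).
#' @param smooth_bins previous-bin count for the causal Gaussian applied to
#'   each unit before PCA (25 for the 2-condition CS analysis, 10 for the
#'   4-condition outcome analysis); 0 if the input is already smoothed.
#' @return a `trajectory_set`: `trajectories` (named list of bins x
#'   n_components matrices), `rotation` (unit loadings), `explained`
#'   (variance fractions, all components), `center`, `n_components`,
#'   `smooth_bins`.
#' @export
compute_trajectories <- function(cond_mats, n_components = 3, smooth_bins = 0) {
  stopifnot(length(cond_mats) >= 1)
  units <- rownames(cond_mats[[1]])
  nb <- ncol(cond_mats[[1]])
  for (m in cond_mats) {
    if (!identical(rownames(m), units) || ncol(m) != nb) {
      stop_input("all conditions must share the unit set and bin grid")
    }
  }
  if (smooth_bins > 0) {
    cond_mats <- lapply(cond_mats, smooth_causal_gaussian, k = smooth_bins)
  }
  concat <- do.call(cbind, cond_mats)        # units x (bins * conditions)
  x <- t(concat)                             # observations x features
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign: largest |loading| positive per component
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  k <- min(n_components, ncol(pc$x))
  idx <- split(seq_len(nrow(x)), rep(seq_along(cond_mats), each = nb))
  trajs <- lapply(idx, function(i) pc$x[i, seq_len(k), drop = FALSE])
  names(trajs) <- names(cond_mats)
  structure(list(trajectories = trajs, rotation = pc$rotation,
                 explained = pc$sdev^2 / sum(pc$sdev^2), center = pc$center,
                 n_components = k, smooth_bins = smooth_bins),
            class = "trajectory_set")
}

#' Polyline length of a trajectory
#'
#' Sum of Euclidean distances between consecutive time points.
#' @param traj bins x components matrix.
#' @return non-negative scalar.
#' @export
trajectory_length <- function(traj) {
  if (nrow(traj) < 2) return(0)
  d <- diff(traj)
  sum(sqrt(rowSums(d^2)))
}

#' Per-bin Euclidean distance between two trajectories
#' @param t1,t2 bins x components matrices on the same time grid.
#' @return numeric vector, one distance per bin.
#' @export
trajectory_distance <- function(t1, t2) {
  stopifnot(nrow(t1) == nrow(t2), ncol(t1) == ncol(t2))
  sqrt(rowSums((t1 - t2)^2))
}

#' Leave-one-subject-out trajectory geometry
#'
#' For each subject, drops that subject's units, refits the PCA basis on the
#' remaining population, and records each condition's trajectory length and
#' every condition pair's per-bin distance series, plus mean distances in
#' the 1 s pre-cue and 1 s post-cue windows. The k per-condition lengths
#' (k = number of subjects) are the sampling distribution used by
#' [compare_geometry()].
#'
#' @param cond_mats named list of units x bins z-PSTH matrices.
#' @param subjects per-unit subject ids (matching rownames).
#' @param bin_times bin start times (event-aligned s), length = ncol.
#' @param n_components components used for lengths/distances (default 3).
#' @param smooth_bins smoothing passed to [compute_trajectories()].
#' @param pre_window,post_window windows (s) for window-averaged distances.
#' @return a `geometry_stats` list: `lengths` (data.frame left_out,
#'   condition, length), `distances` (left_out, pair, bin_time, distance),
#'   `window_means` (left_out, pair, window, mean_distance).
#' @export
trajectory_geometry <- function(cond_mats, subjects, bin_times,
                                n_components = 3, smooth_bins = 0,
                                pre_window = c(-1, 0), post_window = c(0, 1)) {
  units <- rownames(cond_mats[[1]])
  stopifnot(length(subjects) == length(units),
            length(bin_times) == ncol(cond_mats[[1]]))
  subj <- sort(unique(subjects))
  if (length(subj) < 2) stop_input("need >= 2 subjects for leave-one-out")
  pairs <- if (length(cond_mats) >= 2) {
    utils::combn(names(cond_mats), 2, simplify = FALSE)
  } else list()
  lengths <- list(); dists <- list(); wmeans <- list()
  for (s in subj) {
    keep <- subjects != s
    sub <- lapply(cond_mats, function(m) m[keep, , drop = FALSE])
    ts <- compute_trajectories(sub, n_components = n_components,
                               smooth_bins = smooth_bins)
    for (cn in names(ts$trajectories)) {
      lengths[[length(lengths) + 1L]] <- data.frame(
        left_out = s, condition = cn,
        length = trajectory_length(ts$trajectories[[cn]]))
    }
    for (pr in pairs) {
      d <- trajectory_distance(ts$trajectories[[pr[1]]], ts$trajectories[[pr[2]]])
      pname <- paste(pr, collapse = "_vs_")
      dists[[length(dists) + 1L]] <- data.frame(
        left_out = s, pair = pname, bin_time = bin_times, distance = d)
      for (wn in c("pre_cue", "post_cue")) {
        w <- if (wn == "pre_cue") pre_window else post_window
        inw <- bin_times >= w[1] & bin_times < w[2]
        wmeans[[length(wmeans) + 1L]] <- data.frame(
          left_out = s, pair = pname, window = wn,
          mean_distance = mean(d[inw]))
      }
    }
  }
  structure(list(lengths = do.call(rbind, lengths),
                 distances = do.call(rbind, dists),
                 window_means = do.call(rbind, wmeans)),
            class = "geometry_stats")
}

# rank-sum for 2 groups, Kruskal-Wallis + Bonferroni rank-sum post hocs for more
.group_compare <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  gl <- split(values, groups)
  if (length(gl) < 2) stop_input("need >= 2 groups")
  if (any(vapply(gl, length, integer(1)) < 2)) stop_input("need >= 2 values per group")
  if (length(gl) == 2) {
    p <- suppressWarnings(stats::wilcox.test(gl[[1]], gl[[2]], exact = TRUE)$p.value)
    return(list(test = "rank_sum", omnibus_p = p,
                significant = !is.na(p) && p < alpha, posthoc = NULL,
                adjusted_alpha = NA_real_))
  }
  kw <- stats::kruskal.test(gl)
  sig <- !is.na(kw$p.value) && kw$p.value < alpha
  posthoc <- NULL; adj <- NA_real_
  if (sig) {
    prs <- utils::combn(names(gl), 2, simplify = FALSE)
    adj <- alpha / length(prs)
    posthoc <- do.call(rbind, lapply(prs, function(pr) {
      p <- suppressWarnings(
        stats::wilcox.test(gl[[pr[1]]], gl[[pr[2]]], exact = FALSE)$p.value)
      data.frame(group1 = pr[1], group2 = pr[2], p_value = p,
                 significant = !is.na(p) && p < adj)
    }))
  }
  list(test = "kruskal_wallis", omnibus_p = kw$p.value, significant = sig,
       posthoc = posthoc, adjusted_alpha = adj)
}

#' Statistics on trajectory geometry
#'
#' Compares leave-one-out trajectory lengths across conditions and
#' window-averaged distances: rank-sum for two groups, Kruskal-Wallis with
#' Bonferroni-corrected rank-sum post hocs for three or more (e.g. the four
#' outcome conditions, or the six condition pairs).
#'
#' @param stats a [trajectory_geometry()] result.
#' @param alpha omnibus significance level.
#' @return list with `length_test`, `pre_vs_post` (per pair), and
#'   `pair_distance_test` (across pairs, when more than one).
#' @export
compare_geometry <- function(stats, alpha = 0.05) {
  length_test <- .group_compare(stats$lengths$length, stats$lengths$condition,
                                alpha)
  pairs <- unique(stats$window_means$pair)
  pre_vs_post <- lapply(pairs, function(pn) {
    sub <- stats$window_means[stats$window_means$pair == pn, ]
    .group_compare(sub$mean_distance, sub$window, alpha)
  })
  names(pre_vs_post) <- pairs
  pair_distance_test <- if (length(pairs) > 1) {
    sub <- stats$window_means[stats$window_means$window == "post_cue", ]
    .group_compare(sub$mean_distance, sub$pair, alpha)
  } else NULL
  list(length_test = length_test, pre_vs_post = pre_vs_post,
       pair_distance_test = pair_distance_test)
}
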