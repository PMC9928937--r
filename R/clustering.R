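#' Concatenated-condition feature matrix for phasic clustering
#'
#' Per condition (CS-E, CS-A events, and optionally more), computes each
#' unit's PSTH at 100 ms bins, z-scores it against the -2 s-to-cue-onset
#' baseline, smooths with the causal Gaussian over 10 previous bins, and
#' concatenates the conditions into one feature vector per unit. Units
#' removed by the z-step (zero baseline SD / non-finite values) in any
#' condition are dropped from the matrix and reported.
#'
#' @param spikes_list named list of spike-time vectors.
#' @param event_list named list of event-time vectors, one per condition
#'   (order defines the concatenation order).
#' @param bin_width_s PSTH bin width (default 0.1).
#' @param window PSTH window around the cue (default `c(-2, 4)`).
#' @param baseline_window z-score baseline (default `c(-2, 0)`).
#' @param smooth_bins causal-smoothing span (default 10 previous bins).
#' @return a `feature_matrix` list: `features` (units x bins*conditions),
#'   `boundaries` (first column of each condition block), `removed`,
#'   `bin_times`, `params`.
#' @export
build_feature_matrix <- function(spikes_list, event_list, bin_width_s = 0.1,
                                 window = c(-2, 4), baseline_window = c(-2, 0),
                                 smooth_bins = 10) {
  if (length(event_list) < 1 || any(!vapply(event_list, length, 1L)))
    stop_input("every condition needs at least one event")
  zs <- lapply(event_list, function(ev) {
    zscore_smooth(compute_psth(spikes_list, ev, bin_width_s, window),
                  baseline_window, smooth_bins)
  })
  removed <- unique(unlist(lapply(zs, attr, "removed")))
  keep <- setdiff(names(spikes_list), removed)
  mats <- lapply(zs, function(z) z$values[keep, , drop = FALSE])
  nb <- ncol(mats[[1]])
  feats <- do.call(cbind, mats)
  rownames(feats) <- keep
  structure(list(features = feats,
                 boundaries = (seq_along(mats) - 1) * nb + 1,
                 removed = removed,
                 bin_times = zs[[1]]$edges[-length(zs[[1]]$edges)],
                 params = list(bin_width_s = bin_width_s, window = window,
                               baseline_window = baseline_window,
                               smooth_bins = smooth_bins)),
            class = "feature_matrix")
}

#' Ward hierarchical clustering with fractional dendrogram cutoff
#'
#' Agglomerative clustering with Ward linkage on the Euclidean metric. The
#' tree is cut at `cutoff_fraction` times the maximum merge height; clusters
#' with fewer than `min_cluster_size` members are discarded (their units are
#' flagged, not reassigned). Retained cluster labels are canonicalised by
#' decreasing size, ties broken by smallest member index.
#'
#' @param x numeric matrix (units x features) or a `feature_matrix`.
#' @param cutoff_fraction fraction of the maximum linkage height at which
#'   the tree is cut: 0.23 for the phasic analyses, 0.20 for the tonic one.
#' @param min_cluster_size smallest retained cluster (default 3).
#' @return a `cluster_result`: `hclust` (the stats::hclust tree),
#'   `cutoff_fraction`, `cutoff_height`, `labels` (named integer, NA =
#'   discarded), `discarded` (unit ids), `sizes`.
#' @export
ward_cut <- function(x, cutoff_fraction = 0.23, min_cluster_size = 3) {
  if (inherits(x, "feature_matrix")) x <- x$features
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_input("need >= 2 units to cluster")
  if (!(cutoff_fraction > 0 && cutoff_fraction <= 1)) {
    stop_input("cutoff_fraction must lie in (0, 1]")
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  hmax <- max(hc$height)
  cutoff <- cutoff_fraction * hmax
  raw <- if (hmax == 0) rep(1L, nrow(x)) else stats::cutree(hc, h = cutoff)
  names(raw) <- rownames(x)
  sizes <- table(raw)
  keep_ids <- as.integer(names(sizes)[sizes >= min_cluster_size])
  labels <- ifelse(raw %in% keep_ids, raw, NA_integer_)
  # canonicalise: order by size desc, tie by smallest member index
  if (length(keep_ids)) {
    first_idx <- vapply(keep_ids, function(k) min(which(raw == k)), integer(1))
    ord <- keep_ids[order(-as.integer(sizes[as.character(keep_ids)]), first_idx)]
    relab <- stats::setNames(seq_along(ord), ord)
    labels <- ifelse(is.na(labels), NA_integer_,
                     relab[as.character(labels)])
  }
  labels <- stats::setNames(as.integer(labels), rownames(x))
  structure(list(hclust = hc, cutoff_fraction = cutoff_fraction,
                 cutoff_height = cutoff, labels = labels,
                 discarded = rownames(x)[is.na(labels)],
                 sizes = table(labels),
                 min_cluster_size = min_cluster_size),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d clusters (cut %.3g = %.2f x max height), %d units discarded>\n",
              length(x$sizes), x$cutoff_height, x$cutoff_fraction,
              length(x$discarded)))
  print(x$sizes)
  invisible(x)
}

#' Cluster prevalence statistics and composition tables
#'
#' Within each region, builds the leave-one-subject-out per-cluster count
#' matrix, applies a Kruskal-Wallis test across clusters, and (when
#' significant) rank-sum post hocs of the largest-mean cluster against the
#' others at a Bonferroni-adjusted threshold. Discarded units are excluded.
#' Also tabulates each cluster's composition over an optional grouping
#' (e.g. the four subpopulations).
#'
#' @param result a [ward_cut()] result.
#' @param subjects named (or aligned) per-unit subject ids.
#' @param regions optional per-unit region ids; default one region.
#' @param groups optional per-unit composition grouping.
#' @param alpha omnibus significance level.
#' @return list: per-region `tests` (from [prevalence_test()]) and
#'   `loo_counts`, plus `composition` (cluster x group table or NULL).
#' @export
cluster_prevalence_stats <- function(result, subjects, regions = NULL,
                                     groups = NULL, alpha = 0.05) {
  labels <- result$labels
  ids <- names(labels)
  subjects <- stats::setNames(subjects, ids)[ids]
  regions <- if (is.null(regions)) rep("all", length(ids)) else regions
  tests <- list(); loos <- list()
  for (rg in unique(regions)) {
    in_rg <- regions == rg & !is.na(labels)
    if (length(unique(labels[in_rg])) < 2) {
      tests[[rg]] <- list(omnibus_p = NA_real_, significant = FALSE,
                          posthoc = NULL, adjusted_alpha = NA_real_)
      loos[[rg]] <- NULL
      next
    }
    lc <- loo_counts(labels[in_rg], subjects[in_rg])
    tests[[rg]] <- prevalence_test(lc, alpha)
    loos[[rg]] <- lc
  }
  composition <- if (!is.null(groups)) {
    keep <- !is.na(labels)
    table(cluster = labels[keep], group = groups[keep])
  } else NULL
  list(tests = tests, loo_counts = loos, composition = composition)
}
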