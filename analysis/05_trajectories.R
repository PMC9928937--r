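#!/usr/bin/env Rscript
# Population state-space trajectories per region: PCA on baseline-z-scored
# 50 ms PSTHs (CS-E and CS-A concatenated, causal smoothing over 25 previous
# bins), leave-one-subject-out lengths and pairwise distances, and the
# rank-sum / Kruskal-Wallis comparisons of the geometry.

library(pavlophys)

sessions <- lapply(list.dirs("results/sessions", recursive = FALSE),
                   read_session)
units <- do.call(rbind, lapply(sessions, `[[`, "units"))
subj_of <- setNames(units$subject, units$unit_id)

all_lengths <- list()
for (rg in c("MGN", "BLA")) {
  zmats <- list()
  for (cond in c("E", "A")) {
    mats <- lapply(sessions, function(s) {
      u <- intersect(units$unit_id[units$region == rg], s$units$unit_id)
      ev <- s$trials$cs_onset_s[s$trials$cs_type == cond]
      zscore_smooth(compute_psth(s$spikes[u], ev, bin_width_s = 0.05,
                                 window = c(-2, 4)), smooth_bins = 0)$values
    })
    zmats[[cond]] <- do.call(rbind, mats)
  }
  shared <- Reduce(intersect, lapply(zmats, rownames))
  zmats <- lapply(zmats, function(x) x[shared, , drop = FALSE])
  ts <- compute_trajectories(zmats, n_components = 3, smooth_bins = 25)
  message(sprintf("%s: PC1-2 capture %.0f%% of variance (%d units)", rg,
                  100 * sum(ts$explained[1:2]), length(shared)))
  for (cond in c("E", "A")) {
    write.csv(data.frame(region = rg, condition = cond,
                         bin = seq_len(nrow(ts$trajectories[[cond]])),
                         ts$trajectories[[cond]]),
              sprintf("results/trajectory_%s_%s.csv", rg, cond),
              row.names = FALSE)
  }
  geom <- trajectory_geometry(zmats, subj_of[shared],
                              bin_times = seq(-2, 3.95, by = 0.05),
                              n_components = 3, smooth_bins = 25)
  cmp <- compare_geometry(geom)
  message(sprintf(
    "%s: length E vs A rank-sum p = %.3g; pre- vs post-cue distance p = %.3g",
    rg, cmp$length_test$omnibus_p, cmp$pre_vs_post$E_vs_A$omnibus_p))
  all_lengths[[rg]] <- cbind(region = rg, geom$lengths)
  write.csv(geom$window_means, sprintf("results/trajectory_windows_%s.csv", rg),
            row.names = FALSE)
}
write.csv(do.call(rbind, all_lengths), "results/trajectory_lengths.csv",
          row.names = FALSE)
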