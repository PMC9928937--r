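#!/usr/bin/env Rscript
# Phasic response clustering: concatenated CS-E/CS-A z-PSTH features
# (100 ms bins, -2 s baseline, causal smoothing over 10 prior bins), Ward
# linkage cut at 23% of the maximum merge height, clusters under 3 members
# discarded, with leave-one-subject-out prevalence statistics per region and
# composition over the ground-truth subpopulations.

library(pavlophys)

sessions <- lapply(list.dirs("results/sessions", recursive = FALSE),
                   read_session)
units <- do.call(rbind, lapply(sessions, `[[`, "units"))
subj_of <- setNames(units$subject, units$unit_id)
region_of <- setNames(units$region, units$unit_id)
gt <- read.csv("results/ground_truth.csv")

feats <- lapply(sessions, function(s) {
  build_feature_matrix(s$spikes, list(
    E = s$trials$cs_onset_s[s$trials$cs_type == "E"],
    A = s$trials$cs_onset_s[s$trials$cs_type == "A"]))$features
})
fmat <- do.call(rbind, feats)
cl <- ward_cut(fmat, cutoff_fraction = 0.23, min_cluster_size = 3)
message(sprintf("%d clusters from %d units (%d discarded as <3-member)",
                length(cl$sizes), nrow(fmat), length(cl$discarded)))

write.csv(data.frame(unit_id = names(cl$labels), cluster = cl$labels),
          "results/phasic_clusters.csv", row.names = FALSE)
write.csv(data.frame(merge = seq_along(cl$hclust$height),
                     height = cl$hclust$height),
          "results/phasic_linkage_heights.csv", row.names = FALSE)

stats <- cluster_prevalence_stats(
  cl, subj_of[rownames(fmat)], region_of[rownames(fmat)],
  groups = setNames(gt$subpopulation, gt$unit_id)[rownames(fmat)])
for (rg in names(stats$tests)) {
  tst <- stats$tests[[rg]]
  message(sprintf("%s: cluster-prevalence Kruskal-Wallis p = %.3g%s", rg,
                  tst$omnibus_p,
                  if (isTRUE(tst$significant)) " (significant)" else ""))
}
write.csv(as.data.frame(stats$composition), "results/phasic_composition.csv",
          row.names = FALSE)
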