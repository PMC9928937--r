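#!/usr/bin/env Rscript
# A-priori response categorisation: per-unit CS/US responsiveness and the
# nine-way valence/arousal category from the per-CS signed-rank tests, with
# the region-level proportion and prevalence statistics.

library(pavlophys)

sessions <- lapply(list.dirs("results/sessions", recursive = FALSE),
                   read_session)

rows <- list(); resp_rows <- list()
for (s in sessions) {
  E <- s$trials$cs_onset_s[s$trials$cs_type == "E"]
  A <- s$trials$cs_onset_s[s$trials$cs_type == "A"]
  us <- s$trials$us_onset_s
  for (i in seq_len(nrow(s$units))) {
    u <- s$units$unit_id[i]
    rows[[u]] <- cbind(unit_id = u, subject = s$subject_id,
                       region = s$units$region[i],
                       classify_valence_category(s$spikes[[u]], E, A))
    resp_rows[[u]] <- cbind(unit_id = u, region = s$units$region[i],
                            classify_responsiveness(s$spikes[[u]],
                                                    s$trials$cs_onset_s, us))
  }
}
val <- do.call(rbind, rows)
write.csv(val, "results/valence_categories.csv", row.names = FALSE)
write.csv(do.call(rbind, resp_rows), "results/responsiveness.csv",
          row.names = FALSE)

tab <- table(val$region, val$label)
write.csv(as.data.frame(tab), "results/valence_category_counts.csv",
          row.names = FALSE)
message("category counts by region:")
print(tab)

for (rg in c("MGN", "BLA")) {
  sel <- val$region == rg
  pr <- prevalence_test(loo_counts(val$label[sel], val$subject[sel]))
  message(sprintf(
    "%s: Kruskal-Wallis on leave-one-out category counts p = %.3g%s", rg,
    pr$omnibus_p,
    if (pr$significant) sprintf(" (post hocs at alpha = %.3g)",
                                pr$adjusted_alpha) else ""))
}
# multimodal (responsive to both CS and US) proportions between regions
resp <- do.call(rbind, resp_rows)
both_tab <- table(resp$region, resp$label == "both")
pt <- proportion_test(both_tab)
message(sprintf("multimodal proportion MGN vs BLA: %s p = %.3g",
                pt$method, pt$p_value))
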