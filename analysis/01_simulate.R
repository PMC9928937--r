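#!/usr/bin/env Rscript
# Generate the synthetic study all downstream analyses run on: 3 subjects,
# 40 units each across the four subpopulations, 75 reward + 35 punishment
# trials per session, plus a post-task laser epoch for phototagging.
# Sessions are written in the plain-text container format with ground truth.

library(pavlophys)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)

dir.create("results/sessions", recursive = TRUE, showWarnings = FALSE)
for (s in study$sessions) {
  write_session(s, file.path("results/sessions", s$subject_id))
}
write.csv(study$ground_truth, "results/ground_truth.csv", row.names = FALSE)

message(sprintf("simulated %d sessions, %d units total (seed %d)",
                length(study$sessions), nrow(study$ground_truth), seed))
message("subpopulations: ",
        paste(names(table(study$ground_truth$subpopulation)),
              table(study$ground_truth$subpopulation),
              sep = "=", collapse = ", "))
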