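#!/usr/bin/env Rscript
# Photoidentification: classify every unit from its response to the 5 ms
# 1 Hz laser pulses (signed-rank p < 0.001 and peak z > 3.5 within 10 ms for
# MGN projectors; rank-sum p < 0.001 within 50 ms for in-network BLA), and
# score the calls against the simulator's ground truth.

library(pavlophys)

sessions <- lapply(list.dirs("results/sessions", recursive = FALSE),
                   read_session)
tags <- do.call(rbind, lapply(sessions, tag_session))
write.csv(tags, "results/phototag.csv", row.names = FALSE)

gt <- read.csv("results/ground_truth.csv")
m <- merge(tags, gt[, c("unit_id", "subpopulation")], by = "unit_id")
sens <- mean(m$class[m$subpopulation == "MGN_to_BLA"] == "MGN_to_BLA")
fpr <- mean(m$class[m$subpopulation == "MGN_untagged"] == "MGN_to_BLA")
bsens <- mean(m$class[m$subpopulation == "BLA_in"] == "BLA_in")
message(sprintf("MGN->BLA tagging: sensitivity %.2f, false-positive rate %.2f",
                sens, fpr))
message(sprintf("in-network BLA: sensitivity %.2f", bsens))
message(sprintf("median evoked latency of tagged units: %.1f ms",
                median(m$latency_ms[m$class == "MGN_to_BLA"])))
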