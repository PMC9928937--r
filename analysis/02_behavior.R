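#!/usr/bin/env Rscript
# Behavioural analysis: per-trial lick counts, the bootstrap power curve for
# the anticipatory-vs-ITI comparison, the discrimination learning criterion,
# and hit/miss/false-alarm/correct-rejection trial labels per subject.

library(pavlophys)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

sessions <- lapply(list.dirs("results/sessions", recursive = FALSE),
                   read_session)

learning <- list(); outcomes <- list(); power <- list()
for (s in sessions) {
  counts <- per_trial_lick_counts(s$licks, s$trials)
  lo <- assess_learning(counts[counts$cs_type == "E", ],
                        counts[counts$cs_type == "A", ],
                        "discrimination", seed = seed)
  learning[[s$subject_id]] <- cbind(subject = s$subject_id, lo$subsets,
                                    learned = lo$learned,
                                    anticipatory_rate = lo$anticipatory_rate)
  outcomes[[s$subject_id]] <- data.frame(
    subject = s$subject_id, trial = s$trials$trial, cs_type = s$trials$cs_type,
    outcome = classify_trial_outcomes(s$licks, s$trials))
  pw <- bootstrap_power(counts[counts$cs_type == "E", ], trial_range = 1:50,
                        n_iter = 1000, seed = seed)
  power[[s$subject_id]] <- cbind(subject = s$subject_id, pw)
  message(sprintf("%s: learned = %s (anticipatory-lick rate %.2f)",
                  s$subject_id, lo$learned, lo$anticipatory_rate))
}

write.csv(do.call(rbind, learning), "results/behavior_learning.csv",
          row.names = FALSE)
write.csv(do.call(rbind, outcomes), "results/trial_outcomes.csv",
          row.names = FALSE)
pw_all <- do.call(rbind, power)
write.csv(pw_all, "results/bootstrap_power.csv", row.names = FALSE)
p20 <- pw_all$power[pw_all$n_trials == 20]
message(sprintf("bootstrap power at 20 trials: %s",
                paste(sprintf("%.2f", p20), collapse = ", ")))
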