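#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
# Generates covariates, hippocampal outcomes and epoch-level accelerometer
# streams for 485 participants x 7 days under the default calibration, and
# writes the raw-data CSVs consumed by the screening stage.

library(timeusecoda)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_participants = 485L, seed = 2017L)
print(cfg)

cohort <- generate_cohort(cfg)
outcomes <- generate_outcomes(cohort)
epochs <- generate_epochs(cohort)

participants <- merge(cohort$covariates,
                      outcomes[, c("participant_id", "right_hipp_mm3",
                                   "left_hipp_mm3")],
                      by = "participant_id")
write.csv(participants, file.path(out, "participants.csv"),
          row.names = FALSE)
write_epochs_csv(epochs$epochs, file.path(out, "epochs.csv"))
write.csv(cohort$truth, file.path(out, "ground_truth.csv"),
          row.names = FALSE)
write.csv(epochs$daily_truth, file.path(out, "daily_truth.csv"),
          row.names = FALSE)

cat(sprintf("simulated %d participants, %d epoch records -> %s\n",
            nrow(participants), nrow(epochs$epochs), out))
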