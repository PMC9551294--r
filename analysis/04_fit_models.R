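#!/usr/bin/env Rscript
# Stage 4: compositional regression suite.
# Fits models 1-5 (nested covariate adjustment) for right and left
# hippocampal volume and the volume/ICV sensitivity outcomes, each with
# every behaviour pivot-first, and writes the publication-layout table.

library(timeusecoda)
library(data.table)

participants <- fread("results/data/participants.csv", data.table = FALSE)
comp <- fread("results/screening/compositions.tsv", data.table = FALSE)

analysis <- merge(comp, participants, by = "participant_id")
analysis$bmi_cat <- factor(analysis$bmi_cat,
                           levels = c("normal", "under", "over"))
analysis[, behaviour_parts()] <- replace_zeros(analysis[, behaviour_parts()])

suite <- run_model_suite(analysis)
fwrite(suite, "results/tables/coefficients_long.tsv", sep = "\t")
write_coefficient_table(suite, "results/tables/coefficients.tsv")

cat("Right hippocampal volume, model 5 (fully adjusted):\n")
print(fit_pivot_models(analysis, 5, "right_hipp_mm3"))
cat("\nLeft hippocampal volume, model 5:\n")
print(fit_pivot_models(analysis, 5, "left_hipp_mm3"))

m5 <- suite[suite$model == 5 & suite$side == "right" &
              suite$outcome_type == "volume", ]
cat(sprintf("\nzero-sum check: model-5 right z1 betas sum to %.2e\n",
            sum(m5$beta)))
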