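#!/usr/bin/env Rscript
# Stage 3: cohort descriptives and log-ratio dispersion.
# Writes the n (%) / mean (SD) characteristics table and the variation
# matrix of the three behaviours, and reports the compositional centre.

library(timeusecoda)
library(data.table)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

participants <- fread("results/data/participants.csv", data.table = FALSE)
activity <- fread("results/screening/participants.tsv", data.table = FALSE)
comp <- fread("results/screening/compositions.tsv", data.table = FALSE)

analysis <- merge(comp, participants, by = "participant_id")
act <- activity[match(analysis$participant_id, activity$participant_id), ]
analysis$wear_mean <- act$wear_mean
analysis$sb_mean <- act$sb_mean
analysis$lpa_mean <- act$lpa_mean
analysis$mvpa_mean <- act$mvpa_mean
analysis$bmi_cat <- factor(analysis$bmi_cat,
                           levels = c("normal", "under", "over"))

desc <- write_descriptives(analysis, "results/tables/descriptives.tsv")
print(desc, right = FALSE)

cm <- replace_zeros(analysis[, behaviour_parts()])
cat(sprintf("zero parts replaced: %d\n", attr(cm, "n_replaced")))

vm <- variation_matrix(cm)
write_variation_matrix(vm, "results/tables/variation_matrix.tsv")
cat("\nVariation matrix (variances of pairwise log-ratios):\n")
print(round(vm, 2))
cat("\nCompositional centre (%):\n")
print(round(100 * compositional_mean(cm), 1))
cat("Arithmetic-mean composition (%):\n")
print(round(100 * close_composition(colMeans(
  cbind(sb = analysis$sb_mean, lpa = analysis$lpa_mean,
        mvpa = analysis$mvpa_mean))), 1))
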