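#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic appendectomy cohort: 132 patients at the
# calibrated defaults (prevalence 121/132, histology mix 92/4/25, sex and age
# marginals matching the published cohort), seeded for exact reproducibility.
# Writes results/cohort_synthetic.csv for the later stages.

suppressPackageStartupMessages(library(appendiscore))
dir.create("results", showWarnings = FALSE)

params <- cohort_params()
cohort <- generate_cohort(params)  # n = 132, seed = 20220101

labels <- histo_positive(cohort$histopathology)
cat(sprintf("simulated %d patients (seed %d)\n", nrow(cohort), params$seed))
cat(sprintf("  histopathology-positive: %d (%.1f%%), negative appendectomy: %d (%.1f%%)\n",
            sum(labels), 100 * mean(labels), sum(!labels), 100 * mean(!labels)))
print(table(cohort$histopathology))
cat(sprintf("  male: %d  female: %d  age %.1f +- %.1f years\n",
            sum(cohort$sex == "male"), sum(cohort$sex == "female"),
            mean(cohort$age_years), sd(cohort$age_years)))

write_cohort(cohort, "results/cohort_synthetic.csv")
cat("wrote results/cohort_synthetic.csv\n")
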