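#!/usr/bin/env Rscript
# Stage 2 — apply the three clinical decision rules.
#
# Reads the simulated cohort and computes the Alvarado, AIR and RIPASA score,
# risk band and binary call (cutoffs >7, >5, >=7.5) for every patient.
# Writes results/scores.csv (one row per patient, input order preserved).

suppressPackageStartupMessages(library(appendiscore))

cohort <- read_cohort("results/cohort_synthetic.csv",
                      require_histopathology = TRUE)
scored <- score_cohort(cohort)

for (sys in c("alvarado", "air", "ripasa")) {
  s <- scored[[paste0(sys, "_score")]]
  cat(sprintf("%-8s mean %.2f (sd %.2f), %d/%d called positive\n",
              sys, mean(s), sd(s), sum(scored[[paste0(sys, "_positive")]]),
              nrow(scored)))
}

out <- cbind(scored, histopathology = cohort$histopathology)
utils::write.csv(out, "results/scores.csv", row.names = FALSE, quote = FALSE)
cat("wrote results/scores.csv\n")
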