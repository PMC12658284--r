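#!/usr/bin/env Rscript
# Connectivity stage: read the cohort back from its files, apply the
# seizure-selection filters, build 10-s phase windows, compute the 8x8
# LF-iCOH matrix of every window, adjust against the inter-ictal baseline,
# and reduce to the long-format synchrony table. Writes the table and the
# per-phase connectivity summaries under results/cohort/analysis/.

suppressMessages(library(ictalsync))

res <- run_analysis("results/cohort", patient_id = "sim01")

tab <- res$table
cat("Synchrony table:", nrow(tab), "rows (",
    sum(tab$level == "region"), "region,",
    sum(tab$level == "electrode"), "electrode )\n")
cat("Retained seizures:", res$report$n_retained, "of", res$report$n_input, "\n\n")

cat("Mean adjusted LF-iCOH by phase (electrode totals):\n")
el <- tab[tab$level == "electrode", ]
print(round(tapply(el$value, list(el$location, el$phase), mean), 3))
cat("\nTermination-phase elevation is concentrated at the coupled pair",
    "(C3, C4);\nsee results/cohort/analysis/ for the full tables.\n")
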