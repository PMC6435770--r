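#!/usr/bin/env Rscript
# Step 1 — simulate the referral cohort.
#
# Generates the default synthetic referral cohort: 372 probands, 13% Lynch
# carriers with gene mix MSH2 > MLH1 > MSH6 > PMS2, gene-specific onset and
# tumor-burden models, and a sporadic background with MLH1-methylation-driven
# MMR deficiency. Writes the PED/TSV exchange files consumed by the later
# steps.

suppressPackageStartupMessages(library(cfdrtriage))

seed <- 2026L
params <- cohort_params()  # the default study conditions
cohort <- generate_cohort(params, seed = seed)
paths <- write_cohort(cohort, "results/cohort")

pro <- cohort$truth[cohort$truth$is_proband, ]
cat(sprintf("simulated %d probands (seed %d)\n", params$n_probands, seed))
cat(sprintf("  latent carriers: %d (%.1f%%)\n", sum(pro$carrier),
            100 * mean(pro$carrier)))
print(table(gene = pro$gene[pro$carrier]))
cat("files:\n"); cat(paste(" ", paths, collapse = "\n"), "\n")
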