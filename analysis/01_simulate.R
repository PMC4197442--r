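#!/usr/bin/env Rscript
# Simulate the study cohort: 120 tumors in three latent Wnt-activity
# classes (low / medium / high, equal proportions), 19 WNT ligand genes
# carrying the class gradient, GLIS1/CUX1 elevated in the high class, the
# EMT block (VIM, CDH2, SNAI1, SNAI2, TWIST1 up; CDH1, OCLN down), additive
# Gaussian noise of 1 log2 unit. Writes the cohort and its ground truth
# under results/cohort/.

library(sigorder)

spec <- cohort_spec(seed = 1L)
cohort <- run_simulate(spec, out_dir = "results/cohort")

cat(sprintf("Simulated cohort: %d genes x %d samples\n",
            nrow(cohort$matrix), ncol(cohort$matrix)))
print(table(cohort$truth$true_class))
cat("Written to results/cohort/ (matrix.tsv, truth.tsv, spec.yaml)\n")
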