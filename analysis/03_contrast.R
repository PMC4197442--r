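#!/usr/bin/env Rscript
# Contrast the candidate upstream factors (CUX1, GLIS1) and the EMT markers
# between the top 25% and bottom 25% of the Wnt-ordered cohort, with
# Welch-corrected t-tests and star significance tiers.

library(sigorder)

sig <- system.file("extdata", "wnt_signature.txt", package = "sigorder")
factors <- c("CUX1", "GLIS1")
emt_up <- c("VIM", "CDH2", "SNAI1", "SNAI2", "TWIST1")
emt_down <- c("CDH1", "OCLN")

res <- run_contrast("results/cohort/matrix.tsv", sig,
                    c(factors, emt_up, emt_down),
                    fraction = 0.25, out_dir = "results/contrast")
tab <- res$contrasts[[1]]
cat("Top-25% vs bottom-25% Welch contrasts (high minus low):\n")
print(tab[, c("gene_id", "mean_low", "mean_high", "t_stat", "p_value",
              "direction", "tier")], digits = 3, row.names = FALSE)
n_up <- sum(tab$direction == "up" & tab$gene_id %in% c(factors, emt_up))
n_dn <- sum(tab$direction == "down" & tab$gene_id %in% emt_down)
cat(sprintf("\n%d/%d factor+mesenchymal genes up, %d/%d epithelial genes down\n",
            n_up, length(factors) + length(emt_up), n_dn, length(emt_down)))
cat("Tables written to results/contrast/\n")
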