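# sigorder

Signature-based rank-sum ordering and extreme-quartile contrasts for
expression cohorts.

## The problem

Some breast tumors activate the Wnt/β-catenin pathway autocrinely: the
tumor cells transcribe one or more of the 19 WNT ligand genes and
stimulate their own receptors. To find samples in this state — and the
transcription factors (CUX1, GLIS1) and epithelial–mesenchymal transition
markers that co-vary with it — a cohort must be scored over a whole gene
set per sample, without assuming discrete classes in advance.

`sigorder` does this with a rank-sum ordering. For a signature of *G*
genes over *n* samples, each gene *g* is ranked independently across
samples (rank 1 = lowest, average ranks under ties) and each sample *s*
gets the score

&nbsp;&nbsp;&nbsp;&nbsp;*S*<sub>s</sub> = Σ<sub>g</sub> *r*<sub>gs</sub>,&nbsp;&nbsp; *S*<sub>s</sub> ∈ [*G*, *Gn*],

after which the cohort is sorted by ascending *S*<sub>s</sub> — a pure
rank statistic, invariant to per-gene monotone transforms. On top of the
ordering the package provides:

* **extreme-quartile contrasts** — Welch-corrected t-tests of query genes
  between the bottom and top 25% of the ordering, with star tiers
  (p < 0.05 / 0.01 / 0.001) and a supplementary BH-FDR column;
* **Fisher's method** (−2 Σ ln *p*<sub>i</sub> on 2*k* df) to combine
  tests across independent cohorts, and "x out of y datasets" concordance
  tallies;
* **unsupervised hierarchical clustering** of samples over the signature
  (z-scored rows, Euclidean distance, Ward linkage by default);
* **eligibility screening** of cohorts (≥ 100 samples, ≥ 15 of the 19
  signature genes, a CUX1/GLIS1 probe);
* **a synthetic cohort generator** planting low/medium/high Wnt classes,
  co-regulated factor genes and an EMT block with known ground truth, so
  every stage is testable without downloads.

All I/O is plain text: TSV matrices and reports, one-gene-per-line
signatures, Newick trees, YAML sidecars.

## Worked example

Simulate a 120-tumor cohort, order it over the WNT ligand signature, and
contrast the candidate factors and EMT markers between the Wnt-high and
Wnt-low quartiles:

```r
library(sigorder)

cohort <- generate_cohort(cohort_spec(seed = 1))
sig    <- wnt_signature()                 # 19 ligands, min_present = 15
ord    <- order_samples(cohort$matrix, sig)

ordering_concordance(ord, setNames(cohort$truth$latent_score,
                                   cohort$truth$sample_id))
#> [1] 0.936822

contrast_genes(cohort$matrix, ord,
               c("CUX1", "GLIS1", "VIM", "CDH2", "SNAI1", "SNAI2",
                 "TWIST1", "CDH1", "OCLN"))[, c("gene_id", "mean_low",
                 "mean_high", "t_stat", "p_value", "direction", "tier")]
#>  gene_id mean_low mean_high t_stat  p_value direction tier
#>     CUX1   -1.718     0.668   8.28 2.14e-11        up  ***
#>    GLIS1    1.695     3.730   6.89 4.99e-09        up  ***
#>      VIM    1.664     4.169  10.04 3.35e-14        up  ***
#>     CDH2   -0.595     1.262   6.87 5.22e-09        up  ***
#>    SNAI1    2.032     4.388   8.70 5.74e-12        up  ***
#>    SNAI2    2.503     4.549   7.19 1.71e-09        up  ***
#>   TWIST1    0.983     3.010   6.98 3.35e-09        up  ***
#>     CDH1    0.805    -1.086  -7.78 1.86e-10      down  ***
#>     OCLN    0.104    -1.565  -6.85 7.36e-09      down  ***
```

The ordering recovers the planted Wnt gradient (Spearman 0.94), and the
quartile contrast reports every factor and mesenchymal gene up and both
epithelial genes down at p < 0.001 — the pattern the pipeline is built to
detect. `run_cluster()` cuts the cohort into the three Wnt-activity
groups (adjusted Rand index 0.83 against the planted classes in this
run), and `run_meta()` screens a panel of cohorts and tallies per-gene
concordance, e.g. `GLIS1 (up): 7 out of 8` when one panel member's GLIS1
effect is nulled.

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate.R` … `05_meta.R`); each writes its tables under `results/`.

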