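---
title: "Rank-sum signature ordering of expression cohorts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-sum signature ordering of expression cohorts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigorder)
```

## The problem

A sizeable fraction of breast tumors activate the Wnt/β-catenin pathway not
by mutation but autocrinely: the tumor cells themselves transcribe one or
more of the 19 WNT ligand genes, stimulating their own Frizzled/LRP
receptors. Identifying which samples of an expression cohort are in this
high-Wnt state — and which other genes co-vary with it — requires a score
that aggregates a whole gene set per sample without assuming discrete
classes a priori.

`sigorder` implements the rank-sum approach to this problem. For a cohort
of $n$ samples and a signature of $G$ genes present in the matrix, each
gene $g$ is ranked independently across samples ($r_{gs} \in \{1 \ldots
n\}$, rank 1 = lowest expression, average ranks under ties) and each
sample receives the score

$$ S_s \;=\; \sum_{g=1}^{G} r_{gs}, \qquad S_s \in [G,\, Gn], $$

after which the cohort is sorted by ascending $S_s$. This is the first
stage of a two-sample U-statistic computed per sample, so the ordering is
a pure rank statistic: invariant to any per-gene monotone transform (and
hence to per-gene normalization or log-base choice), equivariant under
sample permutation, and exactly reversed by global negation. With average
ranks and no missing values, $\sum_s S_s = G\,n(n+1)/2$ — a conservation
identity the test suite uses as an invariant.

Downstream of the ordering, the package provides the extreme-quantile
contrast (bottom vs top 25% by default) with Welch-corrected t-tests,
Fisher's method for combining tests across independent cohorts,
unsupervised hierarchical clustering over the signature, a cohort
eligibility screen, concordance tallying across a panel of datasets, and
a synthetic cohort generator that plants all of this structure with a
known truth.

## Numerical and procedural choices

**Ties within a gene** receive the average of the ranks they span. This is
the standard rank-statistic convention; it keeps the conservation identity
and makes scores independent of input order.

**Missing expression values.** A sample missing a value for gene $g$
receives that gene's neutral mid-rank $(n+1)/2$, so missingness neither
promotes nor demotes a sample; the remaining samples are ranked among
themselves. Conservation holds exactly only without missing data.

**Ties in the total score** are broken by input sample order (stable
sort). Total scores are sums of (half-)integers, so ties are common even
with continuous data; a deterministic tie-break makes outputs byte-
reproducible. Consequently, negation reverses the order and column
permutation preserves it only *up to tie blocks*, which is how the
property tests compare orderings.

**Signature genes absent from a matrix** are dropped, not imputed,
provided at least `min_present` remain (15 of 19 for the shipped Wnt
signature — the same floor used to screen public datasets). Below the
floor the dataset is ineligible and the error names the missing genes.

**Extreme groups** take the first and last $\lfloor f \cdot n \rfloor$
samples of the ascending ordering ($f = 0.25$ by default, in $(0, 0.5]$).
Flooring guarantees disjoint equal-sized groups for every $n$; the middle
samples are excluded. A minimum of 2 samples per group is enforced.

**Welch test.** The statistic is $t = (\bar{y} - \bar{x}) / \sqrt{s_x^2 /
n_x + s_y^2 / n_y}$ with $n-1$-denominator sample variances and
Welch–Satterthwaite degrees of freedom; p-values are two-sided (the
conservative choice where sidedness is not dictated). Two degenerate cases
are resolved explicitly rather than refused: both groups constant and
equal gives $t = 0, p = 1$; both constant but unequal is reported at the
smallest representable positive p with a `degenerate` flag, since the
observed separation is infinite under the model. Star tiers use the
thresholds 0.05 / 0.01 / 0.001 on the raw per-gene p-values; a
Benjamini–Hochberg FDR column is emitted as supplementary output but never
gates the tiers, matching the per-gene reporting convention of this
analysis style.

**Fisher combination** uses $\chi^2 = -2\sum_i \ln p_i$ on $2k$ degrees of
freedom; $k = 1$ is the identity, and adding an uninformative $p = 1$ test
can only increase the combined p.

**Hierarchical clustering** operates on the signature rows only, z-scored
per gene by default so each gene contributes on a common scale, with
Euclidean distances between samples. The linkage default is Ward's
minimum-variance criterion (`ward.D2`). This was a genuinely open design
point — the underlying analyses never state a metric or linkage — and we
initially considered average linkage; on cohorts simulated at this
package's default effect sizes, however, average linkage chains and shears
off singleton samples, failing to recover the planted three-class
partition that the procedure exists to find (mean adjusted Rand index
≈ 0.65 over 20 simulations, versus ≈ 0.85 for Ward). Ward on z-scored
Euclidean distances is also the common default for expression-subtype
discovery. Both metric and linkage remain configurable, and every written
output records the choice in its YAML sidecar.

**Heatmap export is display-only.** Row z-scaling for display never feeds
back into any statistic; constant rows are flagged and left unscaled;
column order must be an explicit permutation (dendrogram leaf order or
rank-sum order), never inferred.

**Probe collapsing.** Where a matrix carries several probes per gene, the
default merges them by per-sample maximum (preserving detection of an
expressed isoform, a common database convention); mean and median are
selectable. The choice is exposed because the upstream platforms do not
record how their probes were merged.

## The synthetic cohort model

The generator emulates the structure the analysis assumes in real tumor
cohorts, with defaults chosen once as a realistic operating point:

* $n = 120$ samples in three latent classes (low / medium / high Wnt
  activity) with equal proportions — comfortably above the 100-sample
  eligibility floor and comparable to the public breast cancer cohorts
  this analysis style targets.
* Signature shifts of 0 / +1 / +2.5 log2 units per class. Every sample
  additionally draws a uniform latent intensity spreading its class shift
  over a further 0.5 log2 units, so the cohort carries a recoverable
  *total order*, not just a partition. (A gradient confined to one class
  would leave the remaining samples exactly tied, and no ordering method
  could — even noiselessly — recover more than the partition; the global
  gradient makes "the ordering recovers the truth" a well-posed target in
  every regime.) The sample's true latent score, written to `truth.tsv`,
  is exactly this signature shift.
* GLIS1 and CUX1 elevated by +2 log2 units in the high class; VIM, CDH2,
  SNAI1, SNAI2, TWIST1 at +2 and CDH1, OCLN at −2 in the high class.
  These are *fixed* class shifts, deliberately not scaled by the latent
  intensity: a fixed shift is an exactly known truth against which the
  quartile contrast's recovered mean difference can be judged (the
  package's validation requires recovery within ±0.3 log2 units). The
  magnitudes are artifact parameters chosen for clear planted structure,
  not estimates from any real cohort.
* Additive Gaussian noise, SD 1 log2 unit per measurement, and per-gene
  baselines with SD 1 — the standard approximation for normalized
  log-scale microarray intensities. No count model is used, and no
  probe-level, dye or batch artifacts are simulated.
* Per-gene random streams are seeded from the cohort seed and the gene
  name, so extending a spec with new genes never perturbs existing
  values; identical spec + seed is bit-identical.
* Optional uniform missingness, signature dropout (to exercise the
  15-of-19 rule), and panel generation with planted eligibility failures
  (under-sized cohorts, missing factor probes) round out the test
  surface.

What passing tests on these cohorts does **not** show: robustness to
heavy-tailed or skewed noise, correlated gene–gene residuals, batch
structure, platform-specific probe effects, or class proportions far from
the defaults. The generator is a validation harness for the pipeline's
logic and calibration, not a faithful microarray simulator.

## Validation strategy and problem sizes

The test suite checks every stage against an independent route: the
ordering against an exhaustive pairwise-comparison oracle (all tiny
matrices over a 3-value alphabet, plus thousands of random matrices up to
19 × 120); the Welch triple (t, df, p) against `stats::t.test` to 1e-10
and its null rejection rate over 2000 replicates against the nominal 5%
level; the Fisher tail against a closed-form chi-square survival function;
average-linkage trees against a brute-force $O(n^3)$ agglomeration; and
the planted-structure recoveries (ordering concordance, contrast
directions and effect sizes, three-class ARI, x-out-of-y tallies) over
20–50 simulated cohorts each. These sizes keep the whole suite under a
minute while leaving the statistical assertions well-powered.

## Known limitations

* The signature is unsigned: every gene is assumed to rise with the state
  of interest. Directional (signed) signatures are not supported.
* No moderated (shrinkage) statistics, survival models or covariate
  adjustment — contrasts are plain Welch tests per gene.
* The eligibility screen reflects one fixed recipe (sample floor,
  signature coverage, factor probe); other screens must be composed from
  the primitives.
* Clustering never reorders genes; gene display order is the curated list
  the user supplies.
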