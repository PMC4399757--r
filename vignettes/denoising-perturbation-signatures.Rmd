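---
title: "Denoising perturbation signatures: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising perturbation signatures: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartclq)
```

## The model

A perturbation signature is a sign map $\sigma_g \in \{+1,-1\}$ over genes:
$+1$ for genes upregulated in response to an experimental perturbation of a
single gene, $-1$ for downregulated ones. The method's premise is that if
the perturbation's transcriptional program varies across an in-vivo
expression dataset, that variation leaves a specific second-order
fingerprint: for any two signature genes $a, b$, the correlation of their
expression across samples should carry the sign $\sigma_a \sigma_b$. Genes
in the signature that instead reflect in-vitro confounding show no such
patterned correlation and can be identified and discarded — entirely
without phenotype labels.

The pipeline is: (1) test all $\binom{m}{2}$ pairwise correlations among
the $m$ signature genes present in the training matrix and keep the
significant ones; (2) test whether the number of sign-consistent
significant pairs is larger than expected for a random signature of the
same size and up/down composition (Monte Carlo, $B$ runs, empirical
p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(1+B)$); (3) for
signatures passing the screen, remove the sign-inconsistent edges, drop
isolated genes, and keep the largest connected component; (4) enumerate
all maximum cliques of that component and merge them into the clique
module; (5) score each sample by
$S_s = \sum_g k_g \sigma_g z_{gs} / \sum_g k_g$ over the module genes,
where $z_{gs}$ is the gene's z-score across the samples of the dataset
being scored and $k_g$ its degree within the module.

Step (5)'s weighting follows from steps (1)–(4): a gene's degree counts
how many sign-consistent significant partners it has, so highly connected
genes are the ones whose behaviour the data corroborates most broadly.

## Parameters that matter

| Parameter | Default | Role |
|---|---|---|
| `alpha` (edge level) | 0.05 | Per-signature significance level for pairwise correlations |
| `correction` | `bonferroni` | Multiplicity correction over the signature's own pair count |
| `method` | `pearson` | Correlation estimator (on z-scores); `spearman` available |
| `B` | 1000 | Monte Carlo runs; minimum attainable p is $1/(B+1)$ |
| `consistency_alpha` | 0.001 | Screen threshold; with $B=1000$ it is met exactly when the observed count beats every null run |
| `min_genes` / `min_frac` | 5 / 0.5 | Scoring applicability: required overlap between module and dataset |
| `budget` | $10^6$ | Cap on clique-enumeration expansions |

With $B = 1000$ the smallest achievable empirical p is $1/1001 \approx
0.000999$, so the default screen threshold 0.001 is attainable but only by
beating all null runs — the two defaults are chosen as a matched pair.

## Design choices in the open spots

**Count, not fraction, in the Monte Carlo comparison.** The reported
`score` is the interpretable fraction of significant edges that are
consistent, but the null comparison uses the *count* of consistent
significant edges. Matched random signatures typically have very few
significant edges under the null; a single lucky edge gives them fraction
1.0, and a fraction-based comparison would judge a signature with hundreds
of consistent edges no better than those. Counts, whose null distribution
concentrates near zero, separate the two regimes; null runs with no
significant edge contribute a count of 0, so sparse null networks cannot
inflate significance.

**The null model.** Random signatures are matched to the (up, down)
composition of the observed signature's genes *as present in the data*,
drawn uniformly without replacement from all genes of the training matrix.
This keeps the null networks' pair counts identical to the observed one,
which the count comparison relies on.

**Edge significance.** A two-sided test of the correlation coefficient via
the $t$ reference distribution, Bonferroni-corrected within the
signature's own pair set at $\alpha = 0.05$. Bonferroni (rather than FDR)
is deliberately conservative: a false edge contaminates the clique
structure, while a missed weak edge mostly costs module size.

**Quantile normalization ties.** Tied values within a sample receive the
mean of the reference values at the ranks the tie group occupies. This is
one of several dialects in circulation; it is fixed here so results are
reproducible to the digit.

**z-scores.** Standard deviations use the $n-1$ denominator. Zero-variance
genes are removed (not zero-filled) so they can never enter a correlation
network; their identifiers are kept on the result.

**Maximum cliques, not maximal cliques.** The module merges all cliques of
*maximum cardinality*, found by Bron–Kerbosch with pivoting plus a
best-size bound. Branch-and-bound work is capped (`budget`); on overflow
the best cliques found so far are merged and a warning of class
`dartclq_budget_warning` is raised — degenerate dense components should be
visible, not fatal. Degrees $k_g$ are computed in the module's induced
subgraph, not the full component.

**The proportionality constant.** The score's normalizer is
$\sum_g k_g$ over the genes actually present, which makes scores (a) live
on the z-score scale, (b) invariant to rescaling all degrees, and (c)
correctly renormalized when module genes are missing from a new dataset
(missing genes drop out of numerator and denominator together; degrees are
never recomputed outside training).

**The naive baseline.** The undenoised comparator correlates (Spearman,
midranks) the signature's $\pm 1$ sign vector with the sample's z-values
over all present signature genes. In-vitro fold changes are not part of
the signature encoding, so signs are the only weights available to it.
Samples with constant values across the signature genes get score 0 and a
degenerate-sample count.

**GMT pairing.** A gene listed in both the `_UP` and `_DN` entry of one
pair has ambiguous direction and is dropped (counted and reported);
entries without a partner are skipped rather than treated as one-sided
signatures, matching the paired-experiment design the method assumes.

**Per-drug correlation p-values** in the drug-sensitivity ranking use the
$t$ approximation (recorded in the result's `p_value_method`); with
dozens of cell lines per drug the exact-vs-approximate distinction is
immaterial, and the inhibitor skew test — the quantity of interest — is an
exact rank-sum test whenever group sizes permit.

## The synthetic generator

`simulate_perturbation_dataset()` draws the minimal structure under which
the consistency logic is exactly correct: a latent activity $a_s \sim
N(0,1)$ and responsive genes $x_{gs} = \sigma_g \beta a_s +
\varepsilon_{gs}$ with i.i.d. Gaussian noise, plus contaminant signature
genes and background genes that are pure noise. Defaults: 200 samples, 15
up + 15 down responsive genes, 70 contaminants (so 70 % of the emitted
signature is noise), 2000 background genes, `noise_sd` 1, and $\beta =
\sqrt{1.5}$, making the population correlation between responsive genes
$\beta^2/(\beta^2 + 1) = 0.6$ — strong but far from degenerate, the regime
where denoising is useful and testable. Two responsive genes correlate at
$\sigma_g \sigma_h \cdot 0.6$; contaminants correlate with nothing, which
is exactly the violation the screen is meant to remove.

What the generator does *not* emulate: microarray noise physics, batch and
platform effects, correlated background pathways (e.g. proliferation or
microenvironment programs that could masquerade as consistent structure),
heavy-tailed expression, or missing values. Tests passing on this fixture
therefore demonstrate algorithmic correctness — the machinery finds
exactly the structure it defines — not robustness to everything real
cohorts contain.

## Validation experiments and their problem sizes

The test-suite and `scripts/acceptance.R` experiments run at these sizes,
chosen so a full run takes on the order of a minute:

- *Negative control*: 90 random signatures (per-direction sizes uniform in
  30–120 genes, bracketing typical curated collections at reduced scale)
  on a pure-noise 2000-gene × 200-sample matrix, $B = 1000$ each; the
  expected number passing the 0.001 screen is 0.
- *Calibration*: 200 random 40-gene signatures, $B = 200$, with per-pair
  (uncorrected) edge testing so every null network has edges to count —
  under the default Bonferroni correction a null network carries on
  average $\alpha = 0.05$ significant edges, i.e. almost all null networks
  are empty and unusable, and there would be no p-values to calibrate.
  The empirical p-values' deviation from uniformity (Kolmogorov–Smirnov)
  stays below 0.15 despite the $1/201$ discreteness of the add-one
  formula.
- *Recovery*: the default fixture above; module recall of responsive
  genes, contaminant leakage, and Spearman correlation between estimated
  and true activity, compared against the naive baseline.
- *Transfer*: modules trained on one fixture applied to an independent
  draw from the same generative truth.

A shared correlation cache (`cor_cache()`) makes these Monte Carlo loops
cheap: the training matrix is standardized once and each null run reduces
to indexing a precomputed correlation matrix, with a closed-form critical
$|r|$ replacing per-pair p-value computation for fixed-threshold
corrections.

## Known limitations

- Consistency is a property of the *training* dataset; a signature
  inconsistent there may be consistent in a different tissue or subtype,
  and subsetting samples before training is the caller's responsibility.
- Activity scores are relative within a dataset (z-scoring is per
  dataset); they are not calibrated across datasets.
- The correlation machinery requires complete matrices; missing values
  must be handled upstream.
- Maximum-clique enumeration is exponential in the worst case; the budget
  fallback keeps runs alive on pathological components but then returns an
  approximation and says so.
- With very small sample counts ($n \lesssim 20$) the edge tests lose
  power and modules collapse; the method is designed for cohort-scale
  training sets.
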