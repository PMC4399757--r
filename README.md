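# dartclq

Denoising in-vitro perturbation gene expression signatures with relevance
correlation networks and clique modules, and scoring per-sample perturbation
activity in in-vivo expression data.

## The problem

A perturbation signature records which genes went up and which went down
when a single gene was experimentally activated or silenced in a cell model
(e.g. the paired `*_UP` / `*_DN` entries of oncogenic gene-set collections).
Used directly on tumor or cell-line transcriptomes, such signatures perform
poorly: many member genes reflect confounding in-vitro variation rather than
the perturbation's downstream program. `dartclq` denoises a signature
against an independent expression dataset before any scoring:

1. **Consistency screen.** Encode the signature as a sign map
   σ<sub>g</sub> ∈ {+1, −1}. Two genes with the same sign should be
   positively correlated across samples in which the perturbation's program
   varies; genes with opposite signs should be anti-correlated. Count the
   signature's significant pairwise correlations whose sign matches
   σ<sub>a</sub>σ<sub>b</sub>, and compare that count against B = 1000
   size- and direction-matched random signatures (empirical p-value,
   add-one formula). Signatures with P < 0.001 are deemed consistent; the
   rest are discarded.
2. **Pruning.** Remove significant edges whose correlation sign contradicts
   the prediction, drop isolated genes, and keep the largest connected
   component.
3. **Clique module.** Enumerate all maximum cliques of the pruned network
   (branch-and-bound with pivoting) and merge them into the approximate
   clique module CLQ-MOD — in practice a tight, highly connected gene core,
   typically far smaller than the signature.
4. **Activity score.** For sample *s*,

   S<sub>s</sub> = Σ<sub>g∈CLQ-MOD</sub> k<sub>g</sub> σ<sub>g</sub> z<sub>gs</sub> / Σ<sub>g</sub> k<sub>g</sub>

   a degree-weighted, sign-directed average of the module genes' z-scored
   expression (k<sub>g</sub> = the gene's degree within the module, frozen
   from training).

Baselines (scoring over the full pruned component, and a naive Spearman
correlation of the sign vector against each sample), downstream statistics
(rank-sum group comparisons, drug-sensitivity correlation ranking with an
inhibitor skew test, Fisher's combined probability test), and a synthetic
generator with known latent activity are included. The package is aimed at
computational biologists working with signature collections in GMT format
and gene-by-sample expression matrices as TSV.

## Worked example

```r
library(dartclq)
ds <- simulate_perturbation_dataset(synthetic_config(seed = 42))
ds$signature
#> Signed signature 'SYNTH_PERT': 100 genes (51 up, 49 down)

z  <- z_normalize(ds$expr)
ct <- consistency_test(z, ds$signature, B = 1000, seed = 7)
ct
#> Consistency of 'SYNTH_PERT': score 1.000 over 435 significant edge(s); empirical P = 0.000999 (B = 1000)

pruned <- prune_to_consistent(build_relevance_network(z, ds$signature))
mod    <- build_clique_module(pruned, ds$signature)
mod
#> Clique module 'SYNTH_PERT': 30 gene(s); 1 maximum clique(s) of size 30

act <- score_module(mod, z)
round(head(act$scores, 4), 3)
#>   S001   S002   S003   S004
#>  1.054 -0.538  0.443  0.555
cor(act$scores, ds$true_activity, method = "spearman")
#> [1] 0.9851736
```

The fixture plants 30 responsive genes (co-varying with a latent activity)
among 70 contaminant signature genes and 2000 background genes. The
consistency screen passes at the smallest attainable p (1/1001 < 0.001,
i.e. the observed consistent-edge count beat all 1000 random signatures);
the pruned network and the merged maximum cliques recover exactly the 30
responsive genes; and the module score tracks the latent activity at
Spearman ρ ≈ 0.99, versus ≈ 0.91 for the naive whole-signature baseline.

The same workflow is available from a shell via the thin wrapper
`inst/scripts/dartclq` (subcommands `simulate`, `denoise`, `score`,
`associate`), e.g.

```sh
dartclq denoise --gmt signatures.gmt --expr training.tsv --out run/ --seed 1
dartclq score --modules run/modules.json --expr cohort.tsv --out activity.tsv
```

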