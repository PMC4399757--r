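Package: dartclq
Title: Denoising Perturbation Signatures with Relevance Networks and Clique Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoises in-vitro perturbation gene expression signatures against
    an in-vivo expression dataset and estimates per-sample perturbation
    activity. Paired UP/DN gene sets are read from GMT files into signed
    signatures; pairwise expression correlations among signature genes are
    tested for consistency with the signs predicted by the signature, with
    significance assessed by a Monte Carlo test over size- and
    direction-matched random signatures; consistent networks are pruned and
    the union of their maximum cliques defines a clique gene module, over
    which a degree-weighted, sign-directed average of z-scored expression
    yields a per-sample activity score. Baseline scorers (full pruned
    component, naive Spearman), a synthetic-data generator with known latent
    activity, rank-sum and Fisher combination statistics, and
    drug-sensitivity correlation ranking with an inhibitor skew test are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    limma,
    optparse,
    yaml
Config/testthat/edition: 3
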