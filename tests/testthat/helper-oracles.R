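# Independent oracles and small fixture builders used across the suite.

# All maximum cliques by exhaustive bitmask enumeration (n <= 14).
brute_force_max_cliques <- function(nodes, edges) {
  n <- length(nodes)
  stopifnot(n <= 14L)
  adj <- integer(n)
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$gene_a[k], nodes)
    j <- match(edges$gene_b[k], nodes)
    adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
    adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
  }
  S <- seq_len(2L^n - 1L)
  ok <- rep(TRUE, length(S))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    in_s <- bitwAnd(S, bit) > 0L
    rest <- S - in_s * bit
    ok <- ok & (!in_s | bitwAnd(adj[v], rest) == rest)
  }
  bits <- vapply(seq_len(n) - 1L, function(b) bitwAnd(S, bitwShiftL(1L, b)) > 0L,
                 logical(length(S)))
  sizes <- rowSums(bits)
  best <- max(sizes[ok])
  hits <- which(ok & sizes == best)
  out <- lapply(hits, function(s) sort(nodes[bits[s, ]]))
  out[order(vapply(out, paste, character(1L), collapse = "\r"))]
}

# Direct recount of consistent/significant edge fractions with cor.test.
oracle_consistency <- function(z, sig, alpha = 0.05,
                               correction = c("bonferroni", "none", "bh")) {
  correction <- match.arg(correction)
  genes <- intersect(names(sig$signs), rownames(z))
  pairs <- utils::combn(genes, 2L)
  r <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ct <- stats::cor.test(z[pairs[1L, k], ], z[pairs[2L, k], ])
    r[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  p_adj <- stats::p.adjust(p, method = c(bonferroni = "bonferroni",
                                         none = "none", bh = "BH")[[correction]])
  keep <- p_adj <= alpha
  pred <- sig$signs[pairs[1L, ]] * sig$signs[pairs[2L, ]]
  n_con <- sum(keep & sign(r) == pred)
  list(n_significant = sum(keep), n_consistent = n_con,
       score = if (sum(keep)) n_con / sum(keep) else NA_real_)
}

# Exact rank-sum P by enumeration of all group assignments (tie-free input).
enum_ranksum_p <- function(x, y, alternative) {
  nx <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(r), nx)
  ws <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  switch(alternative,
    greater = mean(ws >= w_obs),
    less = mean(ws <= w_obs),
    two_sided = min(1, 2 * min(mean(ws >= w_obs), mean(ws <= w_obs))))
}

# A hand-built (already pruned) relevance network from an edge list.
toy_network <- function(edges, nodes = NULL, signs = NULL, name = "toy") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges$r)) edges$r <- 1
  if (is.null(edges$p_raw)) edges$p_raw <- 0
  if (is.null(edges$p_adj)) edges$p_adj <- 0
  if (is.null(edges$predicted_sign)) edges$predicted_sign <- as.integer(sign(edges$r))
  if (is.null(edges$consistent)) edges$consistent <- sign(edges$r) == edges$predicted_sign
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (is.null(signs)) signs <- stats::setNames(rep(1L, length(nodes)), nodes)
  structure(
    list(signature_name = name, nodes = nodes, signs = signs, edges = edges,
         n_pairs_tested = length(nodes) * (length(nodes) - 1L) / 2L,
         n_samples = 100L,
         params = list(alpha = 0.05, correction = "bonferroni", method = "pearson"),
         pruned = TRUE, usable = nrow(edges) > 0L),
    class = "relevance_network"
  )
}

toy_module <- function(genes, signs, degrees, name = "toy") {
  structure(
    list(signature_name = name, genes = genes,
         signs = stats::setNames(as.integer(signs), genes),
         degrees = stats::setNames(as.integer(degrees), genes),
         max_clique_size = max(degrees) + 1L, n_max_cliques = 1L,
         provenance = list()),
    class = "clique_module"
  )
}

# Erdos-Renyi edge list on labelled nodes.
random_graph_edges <- function(n, p) {
  nodes <- sprintf("g%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(gene_a = pairs[1L, keep], gene_b = pairs[2L, keep],
             stringsAsFactors = FALSE)
}

# Matrix with gene/sample dimnames from a plain numeric matrix.
gene_matrix <- function(m, genes = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- if (is.null(genes)) sprintf("G%02d", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) sprintf("S%02d", seq_len(ncol(m))) else samples
  m
}

sig_from <- function(...) {
  signs <- c(...)
  signed_signature("SIG", stats::setNames(as.integer(signs), names(signs)))
}
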