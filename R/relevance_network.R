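#' Precompute standardized expression for repeated correlation queries
#'
#' The Monte Carlo consistency test evaluates thousands of random signatures
#' against the same training matrix. This helper standardizes the matrix once
#' (rows centered and scaled to unit Euclidean norm, after rank-transforming
#' for Spearman) so that any gene subset's correlation matrix is a single
#' crossproduct; when the universe is small enough the full gene-by-gene
#' correlation matrix is cached densely and queries reduce to indexing.
#'
#' @param z Numeric matrix, genes in rows (typically from
#'   \code{\link{z_normalize}}).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param genes Gene universe to cache; defaults to all rows of \code{z}.
#' @param max_dense Cache the dense correlation matrix when the universe has
#'   at most this many genes (default 4000; 4000^2 doubles = 128 MB).
#' @return An object of class \code{dartclq_cor_cache}.
#' @export
cor_cache <- function(z, method = c("pearson", "spearman"),
                      genes = rownames(z), max_dense = 4000L) {
  method <- match.arg(method)
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  genes <- intersect(genes, rownames(z))
  x <- z[genes, , drop = FALSE]
  if (method == "spearman")
    x <- t(apply(x, 1L, rank))
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0))
    stop("zero-variance gene(s) in correlation universe: ",
         paste(utils::head(genes[nrm == 0], 3L), collapse = ", "))
  x <- x / nrm
  C <- if (length(genes) <= max_dense) tcrossprod(x) else NULL
  structure(list(X = x, C = C, genes = genes, n_samples = ncol(z), method = method),
            class = "dartclq_cor_cache")
}

.cache_cor <- function(cache, genes) {
  if (!is.null(cache$C)) return(cache$C[genes, genes, drop = FALSE])
  tcrossprod(cache$X[genes, , drop = FALSE])
}

# critical |r| equivalent to a two-sided per-pair threshold p_thresh at df = n-2
.r_crit <- function(p_thresh, df) {
  tc <- stats::qt(p_thresh / 2, df, lower.tail = FALSE)
  tc / sqrt(tc^2 + df)
}

.cor_pvalue <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t, df, lower.tail = FALSE)
}

stop_unusable <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("dartclq_unusable_error", "error", "condition")))
}

#' Build the signature-restricted correlation relevance network
#'
#' Nodes are the signature's genes present in the expression matrix; edges
#' are the unordered gene pairs whose pairwise correlation across samples is
#' significant at level \code{alpha} after the chosen multiple-testing
#' correction over the signature's own pair count. Each edge carries the
#' observed correlation, its raw and adjusted p-value, the sign predicted by
#' the signature (\eqn{\sigma_a \sigma_b}) and a consistency flag (observed
#' correlation sign equals the predicted sign).
#'
#' @param z Z-scored expression matrix (genes x samples), e.g. from
#'   \code{\link{z_normalize}}; at least 3 samples.
#' @param sig A \code{\link{signed_signature}}.
#' @param alpha Significance level for edges (default 0.05).
#' @param correction Multiple-testing correction over the signature's pairs:
#'   \code{"bonferroni"} (default), \code{"bh"} or \code{"none"}.
#' @param method Correlation method, \code{"pearson"} (default, on z-scores)
#'   or \code{"spearman"}.
#' @return An object of class \code{relevance_network}: signature name,
#'   \code{nodes}, an edge data frame (\code{gene_a}, \code{gene_b}, \code{r},
#'   \code{p_raw}, \code{p_adj}, \code{predicted_sign}, \code{consistent}),
#'   \code{n_pairs_tested}, \code{n_samples} and the parameters used.
#' @export
build_relevance_network <- function(z, sig, alpha = 0.05,
                                    correction = c("bonferroni", "bh", "none"),
                                    method = c("pearson", "spearman")) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  stopifnot(inherits(sig, "signed_signature"), is.matrix(z))
  if (ncol(z) < 3L) stop("need >= 3 samples")
  genes <- intersect(names(sig$signs), rownames(z))
  if (length(genes) < 2L)
    stop_unusable(sprintf("signature '%s' has %d gene(s) in the data; need >= 2",
                          sig$name, length(genes)),
                  n_present = length(genes))
  signs <- sig$signs[genes]
  x <- z[genes, , drop = FALSE]
  if (method == "spearman") x <- t(apply(x, 1L, rank))
  C <- stats::cor(t(x))
  n <- ncol(z)
  df <- n - 2L
  ut <- upper.tri(C)
  idx <- which(ut, arr.ind = TRUE)
  r <- C[ut]
  p_raw <- .cor_pvalue(r, df)
  p_adj <- stats::p.adjust(p_raw, method = c(bonferroni = "bonferroni",
                                             bh = "BH", none = "none")[[correction]])
  pred <- signs[idx[, 1L]] * signs[idx[, 2L]]
  significant <- p_adj <= alpha
  edges <- data.frame(
    gene_a = genes[idx[significant, 1L]],
    gene_b = genes[idx[significant, 2L]],
    r = r[significant],
    p_raw = p_raw[significant],
    p_adj = p_adj[significant],
    predicted_sign = as.integer(pred[significant]),
    consistent = sign(r[significant]) == pred[significant],
    stringsAsFactors = FALSE
  )
  structure(
    list(signature_name = sig$name, nodes = genes, signs = signs, edges = edges,
         n_pairs_tested = length(r), n_samples = n,
         params = list(alpha = alpha, correction = correction, method = method),
         pruned = FALSE, usable = nrow(edges) > 0L),
    class = "relevance_network"
  )
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf(
    "Relevance network '%s'%s: %d node(s), %d significant edge(s) of %d pair(s) tested\n",
    x$signature_name, if (x$pruned) " (pruned)" else "",
    length(x$nodes), nrow(x$edges), x$n_pairs_tested
  ))
  invisible(x)
}

#' Write a relevance network as an edge-list TSV
#'
#' @param net A \code{relevance_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Consistent/significant edge counts for a gene subset directly from a
# correlation cache. Null runs with no significant edge count 0 consistent
# edges (maximally unsupportive).
.fast_score <- function(cache, genes, signs, alpha, correction) {
  m <- length(genes)
  C <- .cache_cor(cache, genes)
  df <- cache$n_samples - 2L
  P <- m * (m - 1L) / 2
  if (correction %in% c("bonferroni", "none")) {
    p_thresh <- if (correction == "bonferroni") alpha / P else alpha
    rc <- .r_crit(p_thresh, df)
    M <- C * outer(signs, signs)
    n_sig <- (sum(abs(M) >= rc) - m) / 2     # diagonal contributes m ones
    n_con <- (sum(M >= rc) - m) / 2
  } else {
    ut <- upper.tri(C)
    r <- C[ut]
    p_adj <- stats::p.adjust(.cor_pvalue(r, df), method = "BH")
    pred <- (outer(signs, signs))[ut]
    keep <- p_adj <= alpha
    n_sig <- sum(keep)
    n_con <- sum(keep & sign(r) == pred)
  }
  c(n_consistent = n_con, n_significant = n_sig)
}

#' Monte Carlo consistency test of a signature against expression data
#'
#' A signature is consistent with the expression data when the significant
#' pairwise correlations among its genes carry the signs the signature
#' predicts (\eqn{\sigma_a \sigma_b}). The test counts the signature's
#' consistent significant edges and compares that count against \code{B}
#' random signatures matched to the same size and up/down composition (drawn
#' from \code{universe} as in \code{\link{generate_random_signature}}); the
#' empirical p-value uses the add-one formula \eqn{(1 + \#\{null \ge
#' obs\})/(1 + B)}, so with \eqn{B = 1000} the attainable minimum is
#' \eqn{1/1001 < 0.001}. Comparing counts rather than the consistent
#' fraction matters: under the null most matched signatures have very few
#' significant edges and would reach fraction 1 on a single lucky edge,
#' while their consistent-edge counts stay near zero. Null runs with no
#' significant edge count 0. The reported \code{score} is the consistent
#' fraction of the observed signature's significant edges; a signature whose
#' own network has no significant edge is flagged unusable and gets neither
#' score nor p-value.
#'
#' @inheritParams build_relevance_network
#' @param B Number of Monte Carlo runs (>= 100; the reference analysis uses
#'   1000).
#' @param seed Integer seed making the run deterministic.
#' @param universe Gene universe for the random signatures; defaults to all
#'   genes of \code{z}.
#' @param cache Optional \code{\link{cor_cache}} over \code{universe} (and
#'   the signature's genes), shared across many tests of the same matrix.
#' @return An object of class \code{consistency_result}: \code{score},
#'   \code{n_significant_edges}, \code{n_consistent_edges},
#'   \code{empirical_p}, \code{usable}, \code{n_genes_in_data}, \code{B},
#'   \code{seed}.
#' @export
consistency_test <- function(z, sig, B = 1000L, seed = 1L, alpha = 0.05,
                             correction = c("bonferroni", "bh", "none"),
                             method = c("pearson", "spearman"),
                             universe = rownames(z), cache = NULL) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  if (B < 100L) stop("B must be >= 100")
  if (is.null(cache)) {
    need <- union(universe, intersect(names(sig$signs), rownames(z)))
    cache <- cor_cache(z, method = method, genes = need)
  } else {
    if (!inherits(cache, "dartclq_cor_cache") || cache$method != method)
      stop("cache does not match the requested correlation method")
  }
  universe <- intersect(universe, cache$genes)
  genes <- intersect(names(sig$signs), cache$genes)
  if (length(genes) < 2L)
    stop_unusable(sprintf("signature '%s' has %d gene(s) in the data; need >= 2",
                          sig$name, length(genes)),
                  n_present = length(genes))
  signs <- as.numeric(sig$signs[genes])
  obs <- .fast_score(cache, genes, signs, alpha, correction)
  m <- length(genes)
  n_up <- sum(signs == 1)
  usable <- obs[["n_significant"]] > 0
  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      g <- sample(universe, m, replace = FALSE)
      s <- c(rep(1, n_up), rep(-1, m - n_up))
      .fast_score(cache, g, s, alpha, correction)[["n_consistent"]]
    }, numeric(1L))
  })
  score <- if (usable) obs[["n_consistent"]] / obs[["n_significant"]] else NA_real_
  emp_p <- if (usable) (1 + sum(null_counts >= obs[["n_consistent"]])) / (1 + B) else NA_real_
  structure(
    list(signature_name = sig$name, score = score,
         n_significant_edges = as.integer(obs[["n_significant"]]),
         n_consistent_edges = as.integer(obs[["n_consistent"]]),
         empirical_p = emp_p, usable = usable, n_genes_in_data = m,
         B = as.integer(B), seed = as.integer(seed),
         params = list(alpha = alpha, correction = correction, method = method)),
    class = "consistency_result"
  )
}

#' @export
print.consistency_result <- function(x, ...) {
  if (x$usable)
    cat(sprintf("Consistency of '%s': score %.3f over %d significant edge(s); empirical P = %.4g (B = %d)\n",
                x$signature_name, x$score, x$n_significant_edges, x$empirical_p, x$B))
  else
    cat(sprintf("Consistency of '%s': no significant edges; unusable\n", x$signature_name))
  invisible(x)
}

#' Prune a relevance network to its consistent core
#'
#' Removes edges whose observed correlation sign disagrees with the sign
#' predicted by the signature, drops nodes left isolated, and restricts to
#' the largest connected component of what remains (ties in component size
#' broken by higher edge count, then by lexicographically smallest gene set).
#' The result is the denoised network over which activity can be scored.
#'
#' @param net A \code{relevance_network} from
#'   \code{\link{build_relevance_network}}.
#' @return A pruned \code{relevance_network} (\code{pruned = TRUE});
#'   \code{usable = FALSE} with empty edges when no consistent edge exists.
#' @export
prune_to_consistent <- function(net) {
  stopifnot(inherits(net, "relevance_network"))
  e <- net$edges[net$edges$consistent, , drop = FALSE]
  if (nrow(e) == 0L) {
    net$edges <- e
    net$nodes <- character(0)
    net$pruned <- TRUE
    net$usable <- FALSE
    return(net)
  }
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    members <- lapply(cand, function(k) names(comp$membership)[comp$membership == k])
    n_edges <- vapply(members, function(v)
      sum(e$gene_a %in% v & e$gene_b %in% v), integer(1L))
    cand <- cand[n_edges == max(n_edges)]
    if (length(cand) > 1L) {
      keys <- vapply(members[match(cand, which(sizes == max(sizes)))],
                     function(v) paste(sort(v), collapse = "\r"), character(1L))
      cand <- cand[order(keys)][1L]
      message("component size tie broken lexicographically in '", net$signature_name, "'")
    }
  }
  keep <- names(comp$membership)[comp$membership == cand[1L]]
  net$edges <- e[e$gene_a %in% keep & e$gene_b %in% keep, , drop = FALSE]
  net$nodes <- intersect(net$nodes, keep)
  net$signs <- net$signs[net$nodes]
  net$pruned <- TRUE
  net$usable <- TRUE
  net
}
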