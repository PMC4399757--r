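#' Random-signature negative control experiment
#'
#' Runs the randomization control behind the consistency screen: a set of
#' random signatures, matched in size and up/down composition to a panel of
#' templates, is pushed through the Monte Carlo consistency test against an
#' expression matrix. Because the signatures are random, none should reach
#' the consistency threshold; the count that do is the experiment's result.
#' When no explicit templates are given, template compositions are drawn
#' uniformly over \code{size_range} genes per direction, mimicking a panel of
#' heterogeneous curated signatures.
#'
#' @param z Z-scored expression matrix (genes x samples).
#' @param n_signatures Number of random signatures to test (default 90).
#' @param templates Optional list of \code{\link{signed_signature}} whose
#'   (up, down) compositions are matched one-to-one; overrides
#'   \code{n_signatures} and \code{size_range}.
#' @param B Monte Carlo runs per signature (default 1000).
#' @param seed Master seed; signature draws and their null runs derive from
#'   it.
#' @param threshold Consistency significance threshold (default 0.001).
#' @param size_range Per-direction gene-count range for drawn templates
#'   (default 30 to 120).
#' @inheritParams build_relevance_network
#' @return A list with \code{results} (data frame: name, n_up, n_dn,
#'   n_genes, n_significant_edges, score, empirical_p, usable, pass) and
#'   \code{n_passing}.
#' @export
null_signature_experiment <- function(z, n_signatures = 90L, templates = NULL,
                                      B = 1000L, seed = 1L, threshold = 0.001,
                                      size_range = c(30L, 120L), alpha = 0.05,
                                      correction = "bonferroni",
                                      method = "pearson") {
  stopifnot(is.matrix(z), ncol(z) >= 3L)
  universe <- rownames(z)
  cache <- cor_cache(z, method = method)
  if (is.null(templates)) {
    sizes <- withr::with_seed(derive_seed(seed, 0L), cbind(
      n_up = sample(seq(size_range[1L], size_range[2L]), n_signatures, replace = TRUE),
      n_dn = sample(seq(size_range[1L], size_range[2L]), n_signatures, replace = TRUE)
    ))
  } else {
    sizes <- cbind(
      n_up = vapply(templates, function(s) sum(s$signs == 1L), integer(1L)),
      n_dn = vapply(templates, function(s) sum(s$signs == -1L), integer(1L))
    )
    n_signatures <- nrow(sizes)
  }
  rows <- vector("list", n_signatures)
  for (i in seq_len(n_signatures)) {
    n_up <- sizes[i, "n_up"]
    n_dn <- sizes[i, "n_dn"]
    genes <- withr::with_seed(derive_seed(seed, 2L * i - 1L),
                              sample(universe, n_up + n_dn))
    sig <- signed_signature(
      sprintf("RND%03d", i),
      stats::setNames(c(rep(1L, n_up), rep(-1L, n_dn)), genes))
    ct <- consistency_test(z, sig, B = B, seed = derive_seed(seed, 2L * i),
                           alpha = alpha, correction = correction,
                           method = method, cache = cache)
    rows[[i]] <- data.frame(
      name = sig$name, n_up = n_up, n_dn = n_dn, n_genes = n_up + n_dn,
      n_significant_edges = ct$n_significant_edges, score = ct$score,
      empirical_p = ct$empirical_p, usable = ct$usable,
      pass = ct$usable && ct$empirical_p < threshold,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  list(results = results, n_passing = sum(results$pass))
}
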