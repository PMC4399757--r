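activity_profile <- function(signature_name, method, scores, n_used, n_missing,
                             n_degenerate = 0L) {
  structure(
    list(signature_name = signature_name, method = method, scores = scores,
         n_genes_used = as.integer(n_used), n_genes_missing = as.integer(n_missing),
         n_degenerate_samples = as.integer(n_degenerate)),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile '%s' (%s): %d sample(s), %d gene(s) used, %d missing\n",
              x$signature_name, x$method, length(x$scores),
              x$n_genes_used, x$n_genes_missing))
  invisible(x)
}

.check_overlap <- function(present, total, min_genes, min_frac, what, name) {
  need <- max(min_genes, ceiling(min_frac * total))
  if (length(present) < need)
    stop_unusable(sprintf(
      "%s '%s' not applicable: %d of %d genes present, need >= %d",
      what, name, length(present), total, need),
      n_present = length(present), n_total = total)
}

.weighted_score <- function(genes, signs, degrees, z) {
  w <- as.numeric(degrees) * as.numeric(signs)
  drop(crossprod(z[genes, , drop = FALSE], w)) / sum(degrees)
}

#' Score per-sample perturbation activity over a clique module
#'
#' The activity of a perturbation signature in sample \eqn{s} is the
#' degree-weighted, sign-directed average of z-scored module-gene expression:
#' \deqn{S_s = \frac{\sum_g k_g \sigma_g z_{gs}}{\sum_g k_g}}
#' where \eqn{k_g} is the gene's degree in the module (frozen from training)
#' and \eqn{\sigma_g} its signature sign. Module genes absent from \code{z}
#' are dropped together with their degrees, so the normalizer always matches
#' the genes actually used. \code{z} must be z-normalized over the dataset
#' being scored; scores are therefore relative within a dataset.
#'
#' @param mod A \code{\link{build_clique_module}} result.
#' @param z Z-scored expression matrix of the dataset to score.
#' @param min_genes,min_frac Applicability threshold: at least
#'   \code{max(min_genes, ceiling(min_frac * module size))} module genes must
#'   be present (defaults 5 and 0.5).
#' @return An \code{activity_profile} with one score per sample.
#' @export
score_module <- function(mod, z, min_genes = 5L, min_frac = 0.5) {
  stopifnot(inherits(mod, "clique_module"), is.matrix(z))
  present <- intersect(mod$genes, rownames(z))
  .check_overlap(present, length(mod$genes), min_genes, min_frac,
                 "module", mod$signature_name)
  s <- .weighted_score(present, mod$signs[present], mod$degrees[present], z)
  activity_profile(mod$signature_name, "clq", s,
                   length(present), length(mod$genes) - length(present))
}

#' Score activity over the full pruned component (DART baseline)
#'
#' Same weighted average as \code{\link{score_module}}, but genes and degrees
#' come from the entire pruned largest component rather than the merged
#' maximum cliques — the pre-clique variant of the estimator.
#'
#' @param net A pruned \code{relevance_network}.
#' @param sig The \code{\link{signed_signature}}.
#' @param z Z-scored expression matrix of the dataset to score.
#' @inheritParams score_module
#' @return An \code{activity_profile} (method \code{"dart_full"}).
#' @export
score_dart_full <- function(net, sig, z, min_genes = 5L, min_frac = 0.5) {
  stopifnot(inherits(net, "relevance_network"), is.matrix(z))
  if (!net$usable || nrow(net$edges) == 0L)
    stop_unusable(sprintf("network '%s' has no consistent edges", net$signature_name))
  genes <- net$nodes
  tab <- table(factor(c(net$edges$gene_a, net$edges$gene_b), levels = genes))
  degrees <- stats::setNames(as.integer(tab), genes)
  present <- intersect(genes, rownames(z))
  .check_overlap(present, length(genes), min_genes, min_frac,
                 "component", net$signature_name)
  s <- .weighted_score(present, sig$signs[present], degrees[present], z)
  activity_profile(net$signature_name, "dart_full", s,
                   length(present), length(genes) - length(present))
}

#' Naive Spearman baseline activity score
#'
#' For each sample, the Spearman rank correlation between the signature's
#' sign vector (+1/-1) and the sample's z-values over all present signature
#' genes — no denoising, every signature gene contributes. Samples whose
#' values are constant across the signature genes have an undefined
#' correlation; they score 0 and are counted in
#' \code{n_degenerate_samples}.
#'
#' @param sig A \code{\link{signed_signature}}.
#' @param z Z-scored expression matrix of the dataset to score.
#' @param min_genes Minimum number of signature genes that must be present
#'   (default 5).
#' @return An \code{activity_profile} (method \code{"naive_spearman"}).
#' @export
score_naive_spearman <- function(sig, z, min_genes = 5L) {
  stopifnot(inherits(sig, "signed_signature"), is.matrix(z))
  present <- intersect(names(sig$signs), rownames(z))
  if (length(present) < min_genes)
    stop_unusable(sprintf("signature '%s' not applicable: %d gene(s) present, need >= %d",
                          sig$name, length(present), min_genes),
                  n_present = length(present))
  sr <- rank(as.numeric(sig$signs[present]))
  zr <- apply(z[present, , drop = FALSE], 2L, rank)
  s <- suppressWarnings(drop(stats::cor(sr, zr)))
  degenerate <- is.na(s)
  s[degenerate] <- 0
  names(s) <- colnames(z)
  activity_profile(sig$name, "naive_spearman", s,
                   length(present), length(sig$signs) - length(present),
                   n_degenerate = sum(degenerate))
}

#' Write activity profiles as a signatures-by-samples TSV
#'
#' One row per profile (columns \code{signature}, \code{method}, then one
#' column per sample), values printed with 10 significant digits.
#'
#' @param profiles A single \code{activity_profile} or a list of them (all
#'   scored on the same samples).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_activity <- function(profiles, path) {
  if (inherits(profiles, "activity_profile")) profiles <- list(profiles)
  samples <- names(profiles[[1L]]$scores)
  lines <- c(paste(c("signature", "method", samples), collapse = "\t"),
             vapply(profiles, function(p) {
               stopifnot(identical(names(p$scores), samples))
               paste(c(p$signature_name, p$method,
                       sprintf("%.10g", p$scores)), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
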