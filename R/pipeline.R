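#' Assemble a pipeline run configuration
#'
#' Bundles the parameters of a denoising run. Paths may be omitted when the
#' corresponding objects are passed to \code{\link{run_denoise}} directly.
#'
#' @param gmt Path to a paired-GMT signature file (optional).
#' @param expression Path to a training expression TSV (optional).
#' @param out_dir Output directory (optional; no files written when NULL).
#' @param alpha_edge Edge significance level (default 0.05).
#' @param correction Edge multiple-testing correction (default
#'   \code{"bonferroni"}).
#' @param method Correlation method (default \code{"pearson"}).
#' @param B Monte Carlo runs for the consistency test (default 1000).
#' @param consistency_alpha Consistency significance threshold (default
#'   0.001): only signatures with empirical P below it yield modules.
#' @param min_overlap,min_frac Scoring applicability thresholds.
#' @param seed Master seed; per-signature seeds are derived from it.
#' @param quantile_norm Quantile-normalize the expression matrix before
#'   z-scoring (default FALSE).
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(gmt = NULL, expression = NULL, out_dir = NULL,
                       alpha_edge = 0.05, correction = "bonferroni",
                       method = "pearson", B = 1000L,
                       consistency_alpha = 0.001, min_overlap = 5L,
                       min_frac = 0.5, seed = 1L, quantile_norm = FALSE) {
  if (B < 100L) stop("B must be >= 100")
  if (consistency_alpha <= 0 || consistency_alpha >= 1)
    stop("consistency_alpha must lie in (0, 1)")
  for (p in c(gmt, expression))
    if (!is.null(p) && !file.exists(p)) stop("path not found: ", p)
  structure(list(gmt = gmt, expression = expression, out_dir = out_dir,
                 alpha_edge = alpha_edge, correction = correction,
                 method = method, B = as.integer(B),
                 consistency_alpha = consistency_alpha,
                 min_overlap = as.integer(min_overlap), min_frac = min_frac,
                 seed = as.integer(seed), quantile_norm = quantile_norm),
            class = "run_config")
}

# deterministic per-signature seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

#' Run the signature denoising pipeline
#'
#' For every paired signature: Monte Carlo consistency test against the
#' training matrix; signatures passing the consistency threshold are pruned
#' to their consistent largest component and merged into clique modules. A
#' failure for one signature is recorded and the run continues. When
#' \code{cfg$out_dir} is set, writes \code{consistency_report.tsv},
#' \code{modules.json} and \code{manifest.json} (reruns with identical
#' config and seed are byte-identical).
#'
#' @param cfg A \code{\link{run_config}}.
#' @param signatures A \code{signature_collection} (read from
#'   \code{cfg$gmt} when NULL).
#' @param expr Expression matrix (loaded from \code{cfg$expression} when
#'   NULL).
#' @return A list with \code{report} (one row per signature: name,
#'   n_genes_in_data, n_significant_edges, score, empirical_p, usable,
#'   consistent, error), \code{modules} (named list of
#'   \code{clique_module}), \code{networks} (pruned networks for the
#'   consistent signatures) and \code{signatures}.
#' @export
run_denoise <- function(cfg, signatures = NULL, expr = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(signatures)) {
    if (is.null(cfg$gmt)) stop("no signatures given and no gmt path in config")
    signatures <- read_gmt_pairs(cfg$gmt)
  }
  if (inherits(signatures, "signed_signature"))
    signatures <- list(signatures = list(signatures), skipped = character(0))
  if (is.null(expr)) {
    if (is.null(cfg$expression)) stop("no expression given and no path in config")
    expr <- load_expression(cfg$expression)
  }
  if (!length(signatures$signatures)) stop("no paired signatures to process")
  if (cfg$quantile_norm) expr <- quantile_normalize(expr)
  z <- z_normalize(expr)
  cache <- cor_cache(z, method = cfg$method)

  sigs <- signatures$signatures
  rows <- vector("list", length(sigs))
  modules <- list()
  networks <- list()
  for (i in seq_along(sigs)) {
    sig <- sigs[[i]]
    row <- data.frame(name = sig$name, n_genes_in_data = NA_integer_,
                      n_significant_edges = NA_integer_, score = NA_real_,
                      empirical_p = NA_real_, usable = FALSE,
                      consistent = FALSE, error = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      ct <- consistency_test(z, sig, B = cfg$B, seed = derive_seed(cfg$seed, i),
                             alpha = cfg$alpha_edge, correction = cfg$correction,
                             method = cfg$method, cache = cache)
      row$n_genes_in_data <- ct$n_genes_in_data
      row$n_significant_edges <- ct$n_significant_edges
      row$score <- ct$score
      row$empirical_p <- ct$empirical_p
      row$usable <- ct$usable
      if (ct$usable && ct$empirical_p < cfg$consistency_alpha) {
        net <- build_relevance_network(z, sig, alpha = cfg$alpha_edge,
                                       correction = cfg$correction,
                                       method = cfg$method)
        pruned <- prune_to_consistent(net)
        if (pruned$usable) {
          modules[[sig$name]] <- build_clique_module(pruned, sig)
          networks[[sig$name]] <- pruned
          row$consistent <- TRUE
        }
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  report <- do.call(rbind, rows)
  out <- list(report = report, modules = modules, networks = networks,
              signatures = signatures, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    rep_out <- report
    rep_out$score <- sprintf("%.10g", rep_out$score)
    rep_out$empirical_p <- sprintf("%.10g", rep_out$empirical_p)
    utils::write.table(rep_out, file.path(cfg$out_dir, "consistency_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_modules_json(out, file.path(cfg$out_dir, "modules.json"))
    manifest <- list(
      package = "dartclq",
      version = as.character(utils::packageVersion("dartclq")),
      parameters = unclass(cfg),
      n_signatures = length(sigs),
      n_consistent = sum(report$consistent),
      skipped_entries = signatures$skipped
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  }
  out
}

#' Write denoising results (modules plus provenance) as JSON
#'
#' Each entry records the clique module (per-gene id, sign and degree), the
#' full pruned component (for the DART-baseline scorer), the complete
#' signature sign map (for the naive Spearman baseline) and provenance.
#'
#' @param res A \code{\link{run_denoise}} result, or a list with elements
#'   \code{modules}, \code{networks}, \code{signatures}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_modules_json <- function(res, path) {
  sig_by_name <- res$signatures$signatures
  names(sig_by_name) <- vapply(sig_by_name, `[[`, character(1L), "name")
  entries <- lapply(names(res$modules), function(nm) {
    mod <- res$modules[[nm]]
    net <- res$networks[[nm]]
    sig <- sig_by_name[[nm]]
    comp_genes <- net$nodes
    tab <- table(factor(c(net$edges$gene_a, net$edges$gene_b), levels = comp_genes))
    list(
      name = nm,
      max_clique_size = mod$max_clique_size,
      n_max_cliques = mod$n_max_cliques,
      genes = lapply(seq_along(mod$genes), function(j)
        list(id = mod$genes[j], sign = unname(mod$signs[j]),
             degree = unname(mod$degrees[j]))),
      component = list(genes = comp_genes,
                       signs = unname(sig$signs[comp_genes]),
                       degrees = unname(as.integer(tab))),
      signature = list(genes = names(sig$signs), signs = unname(sig$signs)),
      provenance = mod$provenance
    )
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a modules JSON written by \code{\link{write_modules_json}}
#'
#' @param path Path to the JSON file.
#' @return A named list; each entry holds \code{module} (a
#'   \code{clique_module}), \code{component} (genes/signs/degrees) and
#'   \code{signature} (a \code{\link{signed_signature}}).
#' @export
read_modules_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(e) {
    genes <- vapply(e$genes, `[[`, character(1L), "id")
    signs <- stats::setNames(vapply(e$genes, function(g) as.integer(g$sign), integer(1L)), genes)
    degrees <- stats::setNames(vapply(e$genes, function(g) as.integer(g$degree), integer(1L)), genes)
    mod <- structure(
      list(signature_name = e$name, genes = genes, signs = signs,
           degrees = degrees, max_clique_size = e$max_clique_size,
           n_max_cliques = e$n_max_cliques, provenance = e$provenance),
      class = "clique_module")
    comp <- list(genes = unlist(e$component$genes),
                 signs = as.integer(unlist(e$component$signs)),
                 degrees = as.integer(unlist(e$component$degrees)))
    sig <- signed_signature(e$name, stats::setNames(as.integer(unlist(e$signature$signs)),
                                                    unlist(e$signature$genes)))
    list(module = mod, component = comp, signature = sig)
  })
  names(out) <- vapply(raw, `[[`, character(1L), "name")
  out
}

#' Score a dataset with trained modules
#'
#' Z-normalizes the expression matrix of the dataset being scored (activity
#' scores are relative within a dataset) and computes one activity profile
#' per applicable module with the requested scorer. Modules that do not meet
#' the gene-overlap threshold are reported as not applicable rather than
#' failing the run.
#'
#' @param modules Path to a modules JSON, or the list returned by
#'   \code{\link{read_modules_json}}, or a \code{\link{run_denoise}} result.
#' @param expr Expression matrix or path to an expression TSV.
#' @param method Scorer: \code{"clq"} (clique module, default),
#'   \code{"dart"} (full pruned component) or \code{"spearman"} (naive
#'   baseline over the whole signature).
#' @param min_overlap,min_frac Applicability thresholds (see
#'   \code{\link{score_module}}).
#' @param out Optional path for an activity TSV.
#' @return A list with \code{profiles} (named list of
#'   \code{activity_profile}), \code{scores} (signatures x samples matrix)
#'   and \code{not_applicable} (named character vector of reasons). Errors
#'   if no module is applicable.
#' @export
run_score <- function(modules, expr, method = c("clq", "dart", "spearman"),
                      min_overlap = 5L, min_frac = 0.5, out = NULL) {
  method <- match.arg(method)
  if (is.character(modules) && length(modules) == 1L)
    modules <- read_modules_json(modules)
  if (!is.null(modules$modules)) {  # a run_denoise result
    res <- modules
    modules <- lapply(names(res$modules), function(nm) {
      sigs <- res$signatures$signatures
      names(sigs) <- vapply(sigs, `[[`, character(1L), "name")
      net <- res$networks[[nm]]
      tab <- table(factor(c(net$edges$gene_a, net$edges$gene_b), levels = net$nodes))
      list(module = res$modules[[nm]],
           component = list(genes = net$nodes,
                            signs = as.integer(sigs[[nm]]$signs[net$nodes]),
                            degrees = as.integer(tab)),
           signature = sigs[[nm]])
    })
    names(modules) <- names(res$modules)
  }
  if (is.character(expr)) expr <- load_expression(expr)
  z <- z_normalize(expr)
  profiles <- list()
  not_applicable <- character(0)
  for (nm in names(modules)) {
    entry <- modules[[nm]]
    prof <- tryCatch({
      switch(method,
        clq = score_module(entry$module, z, min_genes = min_overlap,
                           min_frac = min_frac),
        dart = {
          comp <- entry$component
          present <- intersect(comp$genes, rownames(z))
          .check_overlap(present, length(comp$genes), min_overlap, min_frac,
                         "component", nm)
          s <- .weighted_score(present,
                               stats::setNames(comp$signs, comp$genes)[present],
                               stats::setNames(comp$degrees, comp$genes)[present], z)
          activity_profile(nm, "dart_full", s, length(present),
                           length(comp$genes) - length(present))
        },
        spearman = score_naive_spearman(entry$signature, z,
                                        min_genes = min_overlap))
    }, dartclq_unusable_error = function(e) conditionMessage(e))
    if (is.character(prof)) not_applicable[nm] <- prof else profiles[[nm]] <- prof
  }
  if (!length(profiles))
    stop("no applicable module for this dataset (",
         length(not_applicable), " not applicable)")
  scores <- do.call(rbind, lapply(profiles, `[[`, "scores"))
  rownames(scores) <- names(profiles)
  if (!is.null(out)) write_activity(profiles, out)
  list(profiles = profiles, scores = scores, not_applicable = not_applicable)
}
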