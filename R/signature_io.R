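#' Construct a signed perturbation signature
#'
#' A signed signature encodes the direction of transcriptional response to a
#' perturbation: each gene carries a sign of +1 (upregulated in response to
#' the perturbation) or -1 (downregulated). Gene identifiers are treated as
#' opaque, case-sensitive strings; no identifier translation is attempted.
#'
#' @param name Signature name (the shared prefix of the paired UP/DN entries).
#' @param signs Named integer vector, one entry per gene, values in
#'   \code{c(-1L, 1L)}.
#' @param source_names Character vector of length 2 giving the original UP and
#'   DN entry names, if the signature came from a GMT file.
#' @return An object of class \code{signed_signature} with elements
#'   \code{name}, \code{signs} and \code{source_names}.
#' @export
signed_signature <- function(name, signs, source_names = c(NA_character_, NA_character_)) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a single non-empty string")
  genes <- names(signs)
  if (is.null(genes) || anyNA(genes) || any(!nzchar(genes)))
    stop("'signs' must be a named vector with non-empty gene names")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in signature '", name, "'")
  signs <- as.integer(signs)
  if (anyNA(signs) || !all(signs %in% c(-1L, 1L)))
    stop("every sign must be exactly +1 or -1")
  if (length(signs) < 2L)
    stop("a signature needs at least 2 genes, got ", length(signs))
  names(signs) <- genes
  structure(
    list(name = name, signs = signs, source_names = as.character(source_names)),
    class = "signed_signature"
  )
}

#' @export
print.signed_signature <- function(x, ...) {
  cat(sprintf(
    "Signed signature '%s': %d genes (%d up, %d down)\n",
    x$name, length(x$signs), sum(x$signs == 1L), sum(x$signs == -1L)
  ))
  invisible(x)
}

#' Read paired UP/DN gene sets from a GMT file
#'
#' Parses a GMT file (Broad dialect: one gene set per line, tab-separated;
#' field 1 the set name, field 2 a description that is ignored, fields 3+ the
#' genes) and pairs entries named \code{<X>_UP} / \code{<X>_DN} into signed
#' signatures named \code{X}. Genes from the UP entry receive sign +1, genes
#' from the DN entry sign -1. A gene listed in both entries of one pair has
#' ambiguous direction and is dropped (the count is reported via
#' \code{message()} and in the result). Entries without a partner, entries
#' lacking either suffix, and pairs left with fewer than 2 unambiguous genes
#' are recorded in \code{skipped} rather than returned as signatures.
#'
#' @param path Path to a GMT file.
#' @param up_suffix,dn_suffix Suffixes identifying the upregulated and
#'   downregulated member of a pair. Defaults \code{"_UP"} / \code{"_DN"}.
#' @return An object of class \code{signature_collection}: a list with
#'   \code{signatures} (list of \code{\link{signed_signature}}),
#'   \code{skipped} (character vector of entry names not used) and
#'   \code{n_conflicts} (named integer vector of dropped ambiguous genes per
#'   signature).
#' @export
read_gmt_pairs <- function(path, up_suffix = "_UP", dn_suffix = "_DN") {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT format error: line %d has %d field(s); expected >= 3 (name, description, genes)",
                 line_no[bad[1L]], lengths(fields)[bad[1L]]))
  set_names <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(set_names))
    stop("GMT format error: duplicate entry name '",
         set_names[duplicated(set_names)][1L], "'")
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(genes) <- set_names

  is_up <- endsWith(set_names, up_suffix)
  is_dn <- endsWith(set_names, dn_suffix)
  base_up <- substr(set_names[is_up], 1L, nchar(set_names[is_up]) - nchar(up_suffix))
  base_dn <- substr(set_names[is_dn], 1L, nchar(set_names[is_dn]) - nchar(dn_suffix))
  paired <- intersect(base_up, base_dn)

  skipped <- character(0)
  n_conflicts <- integer(0)
  signatures <- list()
  for (b in paired) {
    up_name <- paste0(b, up_suffix)
    dn_name <- paste0(b, dn_suffix)
    up <- genes[[up_name]]
    dn <- genes[[dn_name]]
    conflict <- intersect(up, dn)
    up <- setdiff(up, conflict)
    dn <- setdiff(dn, conflict)
    if (length(conflict)) n_conflicts[b] <- length(conflict)
    if (length(up) + length(dn) < 2L) {
      skipped <- c(skipped, up_name, dn_name)
      next
    }
    signs <- c(rep(1L, length(up)), rep(-1L, length(dn)))
    names(signs) <- c(up, dn)
    signatures[[b]] <- signed_signature(b, signs, source_names = c(up_name, dn_name))
  }
  unpaired <- set_names[!(is_up & base_from(set_names, up_suffix) %in% paired) &
                        !(is_dn & base_from(set_names, dn_suffix) %in% paired)]
  skipped <- unique(c(skipped, unpaired))
  if (length(n_conflicts))
    message(sum(n_conflicts), " gene(s) with conflicting direction dropped across ",
            length(n_conflicts), " signature(s)")
  structure(
    list(signatures = signatures, skipped = skipped, n_conflicts = n_conflicts),
    class = "signature_collection"
  )
}

base_from <- function(x, suffix) {
  out <- rep(NA_character_, length(x))
  hit <- endsWith(x, suffix)
  out[hit] <- substr(x[hit], 1L, nchar(x[hit]) - nchar(suffix))
  out
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("Signature collection: %d paired signature(s), %d skipped entr%s\n",
              length(x$signatures), length(x$skipped),
              if (length(x$skipped) == 1L) "y" else "ies"))
  invisible(x)
}

#' Write a signature collection back to paired GMT entries
#'
#' Each signature yields two GMT lines, \code{<name>_UP} and \code{<name>_DN},
#' holding its +1 and -1 genes respectively. Re-reading with
#' \code{\link{read_gmt_pairs}} reproduces identical sign mappings.
#'
#' @param x A \code{signature_collection} or a single \code{signed_signature}.
#' @param path Output file path.
#' @param up_suffix,dn_suffix Suffixes to append; defaults match
#'   \code{\link{read_gmt_pairs}}.
#' @return \code{path}, invisibly.
#' @export
write_gmt_pairs <- function(x, path, up_suffix = "_UP", dn_suffix = "_DN") {
  sigs <- if (inherits(x, "signed_signature")) list(x) else x$signatures
  lines <- unlist(lapply(sigs, function(s) {
    up <- names(s$signs)[s$signs == 1L]
    dn <- names(s$signs)[s$signs == -1L]
    c(paste(c(paste0(s$name, up_suffix), "na", up), collapse = "\t"),
      paste(c(paste0(s$name, dn_suffix), "na", dn), collapse = "\t"))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a size- and direction-matched random signature
#'
#' Draws genes uniformly without replacement from \code{universe} and assigns
#' them exactly the template's counts of +1 and -1 signs. This is the null
#' model used by the Monte Carlo consistency test: random signatures matched
#' to the size and up/down composition of a real one.
#'
#' @param template A \code{\link{signed_signature}} whose composition is to be
#'   matched.
#' @param universe Character vector of gene identifiers to draw from; must
#'   contain at least as many genes as the template.
#' @param seed Optional integer; when given, the draw is deterministic and
#'   the caller's random-number state is left untouched.
#' @return A \code{signed_signature} named \code{<template name>.random}.
#' @export
generate_random_signature <- function(template, universe, seed = NULL) {
  stopifnot(inherits(template, "signed_signature"))
  universe <- unique(as.character(universe))
  m <- length(template$signs)
  if (length(universe) < m)
    stop("universe has ", length(universe), " genes; template needs ", m)
  draw <- function() sample(universe, m, replace = FALSE)
  genes <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  n_up <- sum(template$signs == 1L)
  signs <- c(rep(1L, n_up), rep(-1L, m - n_up))
  names(signs) <- genes
  signed_signature(paste0(template$name, ".random"), signs)
}
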