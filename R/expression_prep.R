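#' Load a gene-by-sample expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row holds sample
#' identifiers, whose first column holds gene (or probe) identifiers, and
#' whose body is numeric. Rows sharing an identifier — typically multiple
#' probes mapping to the same gene — are collapsed to their per-sample
#' arithmetic mean when \code{collapse = TRUE}. Missing values are rejected:
#' the downstream correlation machinery assumes complete matrices.
#'
#' @param path Path to the TSV file.
#' @param collapse Average rows with duplicate identifiers (default
#'   \code{TRUE}). With \code{collapse = FALSE}, duplicate identifiers are an
#'   error.
#' @return A numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @export
load_expression <- function(path, collapse = TRUE) {
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs a gene-id column plus >= 1 sample column")
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  ids <- df[[1L]]
  mat <- matrix(NA_real_, nrow(df), length(sample_ids),
                dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    raw <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at data row %d, sample '%s'",
                   raw[bad[1L]], bad[1L], sample_ids[j]))
    mat[, j] <- v
  }
  if (anyDuplicated(ids)) {
    if (!collapse)
      stop("duplicate gene identifier(s) with collapse = FALSE: ",
           paste(utils::head(unique(ids[duplicated(ids)]), 3L), collapse = ", "))
    g <- factor(ids, levels = unique(ids))
    mat <- rowsum(mat, g, reorder = FALSE) / as.integer(table(g))
    rownames(mat) <- levels(g)
  } else {
    rownames(mat) <- ids
  }
  mat
}

#' Write an expression (or z-score) matrix as TSV
#'
#' Inverse of \code{\link{load_expression}}: header \code{gene_id} followed by
#' sample identifiers; values rounded to \code{digits} significant digits so
#' that output is byte-identical across platforms.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param digits Significant digits to keep (default 10).
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(m, path, digits = 10L) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  body <- apply(signif(m, digits), 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = "\t"))
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Quantile-normalize samples of an expression matrix
#'
#' Forces every sample (column) onto a common empirical distribution: each
#' sample's sorted values are replaced by the mean of the sorted values across
#' all samples, preserving within-sample rank order. Tied values within a
#' sample receive the mean of the reference values at the ranks the tie group
#' occupies.
#'
#' @param m Numeric matrix, genes in rows, at least 2 sample columns.
#' @return The normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(m)) stop("missing values are not supported")
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    xs <- m[o, j]
    grp <- cumsum(c(TRUE, xs[-1L] != xs[-length(xs)]))
    out[o, j] <- stats::ave(ref, grp)
  }
  out
}

#' Z-score genes across samples
#'
#' Centers each gene (row) to mean 0 and scales to unit variance using the
#' unbiased (n-1) standard deviation. Genes with zero variance carry no
#' correlation information and are removed; their identifiers are attached as
#' the \code{"dropped_genes"} attribute of the result.
#'
#' @param m Numeric matrix, genes in rows, at least 3 sample columns.
#' @return The z-scored matrix (possibly fewer rows), with attribute
#'   \code{dropped_genes}.
#' @export
z_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 3L) stop("z-normalization needs >= 3 samples")
  if (anyNA(m) || any(!is.finite(m))) stop("values must be finite")
  n <- ncol(m)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (n - 1))
  # relative tolerance: a numerically-constant row must not blow up into noise
  degenerate <- s <= sqrt(.Machine$double.eps) * pmax(abs(mu), 1)
  dropped <- rownames(m)[degenerate]
  if (length(dropped))
    message("dropping ", length(dropped), " zero-variance gene(s)")
  z <- (m[!degenerate, , drop = FALSE] - mu[!degenerate]) / s[!degenerate]
  attr(z, "dropped_genes") <- dropped
  z
}
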