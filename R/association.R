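#' Wilcoxon rank sum comparison of two groups
#'
#' Two-sample rank-sum test with midranks for ties: exact p-values by
#' enumeration for small tie-free samples, normal approximation with tie and
#' continuity correction otherwise (the behaviour of
#' \code{\link[stats]{wilcox.test}}, which this wraps). Used both for group
#' comparisons of activity scores and for the inhibitor skew test of drug
#' correlation rankings.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"} (x relative to y).
#' @return An object of class \code{ranksum_result}: \code{statistic} (the
#'   Mann-Whitney U of \code{x}), \code{p_value}, \code{alternative},
#'   \code{n1}, \code{n2}, \code{exact}.
#' @export
ranksum_test <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt))
  structure(
    list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
         alternative = alternative, n1 = length(x), n2 = length(y),
         exact = grepl("exact", wt$method, fixed = TRUE)),
    class = "ranksum_result"
  )
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Rank sum test (%s%s): W = %g, n = (%d, %d), P = %.4g\n",
              x$alternative, if (x$exact) ", exact" else ", approximate",
              x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Rank drugs by correlation of sensitivity with perturbation activity
#'
#' For each drug, the Spearman rank correlation (t-approximation p-value)
#' between the activity score and drug sensitivity (e.g. -log10 GI50) over
#' the pairwise-complete shared cell lines; drugs with fewer than
#' \code{min_pairs} complete pairs are excluded. The ranking is sorted by
#' correlation, strongest positive first. When a target class of drugs is
#' given (e.g. inhibitors of the perturbed pathway), a one-sided rank sum
#' test asks whether the in-class drugs' correlations are skewed towards
#' positive values relative to the rest.
#'
#' @param act An \code{activity_profile} or a named numeric vector of
#'   per-cell-line activity scores.
#' @param response Numeric matrix or data frame, drugs in rows (rownames),
#'   cell lines in columns; \code{NA} allowed.
#' @param target_class Character vector of drug names forming the class to
#'   test for positive skew (may be empty).
#' @param min_pairs Minimum pairwise-complete sample count per drug
#'   (default 5).
#' @return An object of class \code{drug_correlation_ranking}: \code{table}
#'   (drug_name, spearman_r, p_value, n_cell_lines, in_target_class, sorted
#'   by correlation descending), \code{skew_p}, \code{excluded}.
#' @export
correlate_activity_with_response <- function(act, response,
                                             target_class = character(0),
                                             min_pairs = 5L) {
  scores <- if (inherits(act, "activity_profile")) act$scores else act
  if (is.null(names(scores))) stop("activity scores must be named by cell line")
  response <- as.matrix(response)
  if (is.null(rownames(response))) stop("response matrix needs drug rownames")
  unknown <- setdiff(target_class, rownames(response))
  if (length(unknown))
    stop("target_class drug(s) not in response table: ",
         paste(unknown, collapse = ", "))
  shared <- intersect(names(scores), colnames(response))
  if (!length(shared)) stop("no shared samples between activity and response")
  rows <- list(); excluded <- character(0)
  for (d in rownames(response)) {
    r <- response[d, shared]
    ok <- !is.na(r)
    if (sum(ok) < min_pairs) {
      excluded <- c(excluded, d)
      next
    }
    ct <- suppressWarnings(stats::cor.test(scores[shared][ok], r[ok],
                                           method = "spearman", exact = FALSE))
    rows[[d]] <- data.frame(drug_name = d, spearman_r = unname(ct$estimate),
                            p_value = ct$p.value, n_cell_lines = sum(ok),
                            in_target_class = d %in% target_class,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no drug with >= ", min_pairs, " complete pairs")
  if (length(excluded))
    message(length(excluded), " drug(s) excluded with < ", min_pairs, " pairs")
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$spearman_r), , drop = FALSE]
  rownames(tab) <- NULL
  skew_p <- NA_real_
  if (any(tab$in_target_class) && any(!tab$in_target_class))
    skew_p <- ranksum_test(tab$spearman_r[tab$in_target_class],
                           tab$spearman_r[!tab$in_target_class],
                           alternative = "greater")$p_value
  structure(list(table = tab, skew_p = skew_p, excluded = excluded,
                 p_value_method = "t-approximation"),
            class = "drug_correlation_ranking")
}

#' @export
print.drug_correlation_ranking <- function(x, ...) {
  cat(sprintf("Drug correlation ranking: %d drug(s)%s\n", nrow(x$table),
              if (is.na(x$skew_p)) "" else sprintf("; skew P = %.4g", x$skew_p)))
  print(utils::head(x$table, 10L))
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via \eqn{X = -2 \sum_i \ln p_i}, referred to
#' a chi-square distribution with \eqn{2k} degrees of freedom; returns the
#' upper-tail probability. A single p-value is returned unchanged.
#'
#' @param p_values Numeric vector of p-values, each in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) stop("need at least one p-value")
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("every p-value must lie in (0, 1]")
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}
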