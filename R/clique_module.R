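#' Enumerate all maximum cliques of a pruned relevance network
#'
#' Finds every clique of maximum cardinality using branch-and-bound
#' (Bron-Kerbosch with pivoting, pruning branches that cannot reach the best
#' size seen). Enumeration work is capped at \code{budget} node expansions;
#' on overflow a warning (condition class \code{dartclq_budget_warning}) is
#' issued and the best-size cliques found so far are returned.
#'
#' @param net A pruned, connected \code{relevance_network} (or any
#'   \code{relevance_network}; only its edge list is used).
#' @param budget Maximum number of recursive expansions (default 1e6).
#' @return A list of character vectors, each a maximum clique with members
#'   sorted; cliques ordered lexicographically. Attribute
#'   \code{budget_exceeded} reports whether the cap was hit.
#' @export
enumerate_max_cliques <- function(net, budget = 1e6) {
  stopifnot(inherits(net, "relevance_network"))
  nodes <- net$nodes
  if (length(nodes) < 2L || nrow(net$edges) == 0L)
    stop("cannot enumerate cliques of an empty network")
  ia <- match(net$edges$gene_a, nodes)
  ib <- match(net$edges$gene_b, nodes)
  adj <- vector("list", length(nodes))
  for (v in seq_along(nodes))
    adj[[v]] <- sort(unique(c(ib[ia == v], ia[ib == v])))

  state <- new.env(parent = emptyenv())
  state$best <- 0L
  state$cliques <- list()
  state$expansions <- 0L
  state$overflow <- FALSE

  rec <- function(R, P, X) {
    if (state$overflow) return(invisible())
    state$expansions <- state$expansions + 1L
    if (state$expansions > budget) {
      state$overflow <- TRUE
      return(invisible())
    }
    # record R itself: any clique reaching the final best size is a maximum
    # clique, and this keeps the budget-overflow fallback non-empty
    if (length(R) > state$best) {
      state$best <- length(R)
      state$cliques <- list(R)
    } else if (length(R) == state$best && length(R) > 0L) {
      state$cliques <- c(state$cliques, list(R))
    }
    if (!length(P) && !length(X)) return(invisible())
    if (length(R) + length(P) < state$best) return(invisible())
    px <- c(P, X)
    gain <- vapply(px, function(u) sum(P %in% adj[[u]]), integer(1L))
    u <- px[which.max(gain)]
    for (v in setdiff(P, adj[[u]])) {
      nv <- adj[[v]]
      rec(c(R, v), P[P %in% nv], X[X %in% nv])
      P <- P[P != v]
      X <- c(X, v)
    }
    invisible()
  }
  rec(integer(0), seq_along(nodes), integer(0))

  if (state$overflow)
    warning(warningCondition(
      sprintf("clique enumeration budget (%g expansions) exceeded in '%s'; falling back to the %d best clique(s) of size %d found so far",
              budget, net$signature_name, length(state$cliques), state$best),
      class = "dartclq_budget_warning"))
  out <- lapply(state$cliques, function(ix) sort(nodes[ix]))
  out <- unique(out)
  out <- out[order(vapply(out, paste, character(1L), collapse = "\r"))]
  attr(out, "budget_exceeded") <- state$overflow
  out
}

#' Merge maximum cliques into the approximate clique gene module
#'
#' The module (CLQ-MOD) is the union of all maximum cliques of the pruned
#' network; in practice maximum cliques overlap strongly, so the union is a
#' highly connected near-clique. Each module gene carries its signature sign
#' \eqn{\sigma_g} and its degree \eqn{k_g} within the module's induced
#' subgraph — the weights of the activity score.
#'
#' @param net A pruned \code{relevance_network}.
#' @param sig The \code{\link{signed_signature}} the network was built from.
#' @param budget Passed to \code{\link{enumerate_max_cliques}}.
#' @return An object of class \code{clique_module}: \code{genes} (sorted),
#'   \code{signs}, \code{degrees}, \code{max_clique_size},
#'   \code{n_max_cliques}, \code{provenance}.
#' @export
build_clique_module <- function(net, sig, budget = 1e6) {
  stopifnot(inherits(net, "relevance_network"), inherits(sig, "signed_signature"))
  cliques <- enumerate_max_cliques(net, budget = budget)
  genes <- sort(unique(unlist(cliques)))
  if (length(cliques) > 1L &&
      any(vapply(cliques[-1L], function(cl) !length(intersect(cl, cliques[[1L]])), logical(1L))))
    message("disjoint maximum cliques merged in '", net$signature_name, "'")
  sub <- net$edges[net$edges$gene_a %in% genes & net$edges$gene_b %in% genes, , drop = FALSE]
  tab <- table(factor(c(sub$gene_a, sub$gene_b), levels = genes))
  degrees <- as.integer(tab)
  names(degrees) <- genes
  signs <- sig$signs[genes]
  structure(
    list(signature_name = net$signature_name, genes = genes, signs = signs,
         degrees = degrees,
         max_clique_size = length(cliques[[1L]]),
         n_max_cliques = length(cliques),
         provenance = c(net$params, list(n_training_samples = net$n_samples))),
    class = "clique_module"
  )
}

#' @export
print.clique_module <- function(x, ...) {
  cat(sprintf("Clique module '%s': %d gene(s); %d maximum clique(s) of size %d\n",
              x$signature_name, length(x$genes), x$n_max_cliques, x$max_clique_size))
  invisible(x)
}
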