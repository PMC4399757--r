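#' Configuration for the synthetic perturbation dataset generator
#'
#' The generator emulates the structure the denoising model assumes: a latent
#' per-sample perturbation activity \eqn{a_s \sim N(0,1)} drives a set of
#' responsive signature genes with signed loadings
#' (\eqn{x_{gs} = \sigma_g \beta a_s + \varepsilon_{gs}}), while contaminant
#' signature genes (listed in the signature but carrying no association) and
#' background genes are pure noise. Defaults: 200 samples, 15 up + 15 down
#' responsive genes, 70 contaminants, 2000 background genes, unit noise, and
#' \eqn{\beta = \sqrt{1.5}} so that the population correlation between two
#' responsive genes, \eqn{\beta^2/(\beta^2 + \mathrm{noise\_sd}^2)}, is 0.6.
#'
#' @param n_samples Number of samples.
#' @param n_background_genes Background (non-signature) genes.
#' @param n_true_up,n_true_dn Responsive signature genes with +1 / -1 signs.
#' @param n_contaminant Signature genes with zero loading (random +/-1 signs
#'   in the emitted signature).
#' @param effect_size Loading magnitude \eqn{\beta} in units of the signal
#'   standard deviation; 0 gives a pure-null dataset.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise (> 0).
#' @param seed Integer seed; the dataset is deterministic given the config.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_samples = 200L, n_background_genes = 2000L,
                             n_true_up = 15L, n_true_dn = 15L,
                             n_contaminant = 70L, effect_size = sqrt(1.5),
                             noise_sd = 1, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_background_genes = as.integer(n_background_genes),
              n_true_up = as.integer(n_true_up), n_true_dn = as.integer(n_true_dn),
              n_contaminant = as.integer(n_contaminant),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  counts <- unlist(cfg[c("n_samples", "n_background_genes", "n_true_up",
                         "n_true_dn", "n_contaminant")])
  if (anyNA(unlist(cfg)) || any(counts < 0L))
    stop("all counts must be non-negative and nothing NA")
  if (cfg$n_samples < 3L) stop("need >= 3 samples")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$effect_size > 0 && cfg$n_true_up + cfg$n_true_dn < 2L)
    stop("need >= 2 responsive genes when effect_size > 0")
  structure(cfg, class = "synthetic_config")
}

#' Simulate an expression dataset with known perturbation activity
#'
#' Draws a dataset under the single-factor model of
#' \code{\link{synthetic_config}} and packages it with its ground truth: the
#' latent activity, the emitted signed signature (responsive genes with their
#' true signs plus contaminants with random signs), and a per-gene label.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return An object of class \code{synthetic_dataset}: \code{expr}
#'   (genes x samples matrix), \code{true_activity} (named per-sample
#'   vector), \code{signature} (\code{\link{signed_signature}}, \code{NULL}
#'   when the config has no signature genes), \code{truth} (data frame
#'   gene/label with labels responsive, contaminant, background),
#'   \code{config}.
#' @export
simulate_perturbation_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_resp <- cfg$n_true_up + cfg$n_true_dn
  resp_ids <- if (n_resp) sprintf("RSP%03d", seq_len(n_resp)) else character(0)
  cont_ids <- if (cfg$n_contaminant) sprintf("CNT%03d", seq_len(cfg$n_contaminant)) else character(0)
  bg_ids <- if (cfg$n_background_genes) sprintf("BGD%04d", seq_len(cfg$n_background_genes)) else character(0)
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  resp_signs <- c(rep(1L, cfg$n_true_up), rep(-1L, cfg$n_true_dn))

  out <- withr::with_seed(cfg$seed, {
    a <- stats::rnorm(cfg$n_samples)
    n_genes <- n_resp + cfg$n_contaminant + cfg$n_background_genes
    noise <- matrix(stats::rnorm(n_genes * cfg$n_samples, sd = cfg$noise_sd),
                    n_genes, cfg$n_samples)
    expr <- noise
    if (n_resp)
      expr[seq_len(n_resp), ] <- expr[seq_len(n_resp), ] +
        (resp_signs * cfg$effect_size) %o% a
    cont_signs <- if (cfg$n_contaminant)
      sample(c(-1L, 1L), cfg$n_contaminant, replace = TRUE) else integer(0)
    list(a = a, expr = expr, cont_signs = cont_signs)
  })
  expr <- out$expr
  dimnames(expr) <- list(c(resp_ids, cont_ids, bg_ids), sample_ids)
  names(out$a) <- sample_ids

  signature <- NULL
  if (n_resp + cfg$n_contaminant >= 2L) {
    signs <- c(resp_signs, out$cont_signs)
    names(signs) <- c(resp_ids, cont_ids)
    signature <- signed_signature("SYNTH_PERT", signs)
  }
  truth <- data.frame(
    gene = rownames(expr),
    label = rep(c("responsive", "contaminant", "background"),
                c(n_resp, cfg$n_contaminant, cfg$n_background_genes)),
    stringsAsFactors = FALSE
  )
  structure(list(expr = expr, true_activity = out$a, signature = signature,
                 truth = truth, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d gene(s) x %d sample(s); %d responsive, %d contaminant, %d background (seed %d)\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$truth$label == "responsive"),
              sum(x$truth$label == "contaminant"),
              sum(x$truth$label == "background"), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits \code{expr.tsv} (expression, 10 significant digits),
#' \code{signature.gmt} (the signature as an \code{_UP}/\code{_DN} pair),
#' \code{truth.tsv} (gene labels) and \code{activity.tsv} (latent activity).
#'
#' @param ds A \code{synthetic_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(ds$expr, file.path(dir, "expr.tsv"))
  if (!is.null(ds$signature))
    write_gmt_pairs(ds$signature, file.path(dir, "signature.gmt"))
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("sample\tactivity",
               paste(names(ds$true_activity),
                     sprintf("%.10g", ds$true_activity), sep = "\t")),
             file.path(dir, "activity.tsv"))
  invisible(dir)
}
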