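test_that("perfectly correlated gene pairs form consistent significant edges", {
  m <- gene_matrix(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8)), genes = c("A", "B"))
  sig <- sig_from(A = 1, B = 1)
  net <- build_relevance_network(z_normalize(m), sig)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$r, 1)
  expect_identical(net$edges$predicted_sign, 1L)
  expect_true(net$edges$consistent)
  expect_identical(net$n_pairs_tested, 1L)
})

test_that("noise-free anti-correlation yields the forced sign pattern", {
  x <- c(0.3, -1.2, 2.1, 0.4, -0.9)
  m <- gene_matrix(rbind(A = x, B = x, C = -x), genes = c("A", "B", "C"))
  net <- build_relevance_network(z_normalize(m), sig_from(A = 1, B = 1, C = -1))
  e <- net$edges
  expect_identical(nrow(e), 3L)
  key <- paste(e$gene_a, e$gene_b)
  expect_equal(e$r[key == "A B"], 1)
  expect_equal(e$r[key == "A C"], -1)
  expect_equal(e$r[key == "B C"], -1)
  expect_true(all(e$consistent))
})

test_that("independent genes produce almost no Bonferroni edges (seeded simulation)", {
  n_edges <- withr::with_seed(1, {
    vapply(1:100, function(rep) {
      m <- matrix(stats::rnorm(50 * 100), 50L,
                  dimnames = list(sprintf("G%02d", 1:50), sprintf("S%03d", 1:100)))
      sig <- signed_signature("S", stats::setNames(
        sample(c(-1L, 1L), 50L, replace = TRUE), rownames(m)))
      nrow(build_relevance_network(z_normalize(m), sig)$edges)
    }, integer(1L))
  })
  # per-replicate false-edge count is ~Poisson(alpha = 0.05); frozen oracle run
  expect_identical(sum(n_edges == 0L), 92L)
  expect_identical(sum(n_edges), 8L)
  expect_lte(sum(n_edges), stats::qpois(0.999, 100 * 0.05))
})

test_that("consistency counts match a direct cor.test recount on small data", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      n_genes <- sample(4:8, 1L)
      m <- gene_matrix(matrix(stats::rnorm(n_genes * 20), n_genes, 20L))
      # plant some structure so edges exist
      m[2L, ] <- m[1L, ] + stats::rnorm(20, sd = 0.3)
      m[3L, ] <- -m[1L, ] + stats::rnorm(20, sd = 0.3)
      signs <- stats::setNames(sample(c(-1L, 1L), n_genes, replace = TRUE),
                               rownames(m))
      list(z = z_normalize(m), sig = signed_signature("S", signs))
    })
    for (correction in c("bonferroni", "none")) {
      ref <- oracle_consistency(dat$z, dat$sig, alpha = 0.05, correction = correction)
      ct <- consistency_test(dat$z, dat$sig, B = 100L, seed = seed,
                             correction = correction)
      expect_identical(ct$n_significant_edges, as.integer(ref$n_significant))
      expect_identical(ct$n_consistent_edges, as.integer(ref$n_consistent))
      if (ref$n_significant > 0) expect_equal(ct$score, ref$score)
      net <- build_relevance_network(dat$z, dat$sig, correction = correction)
      expect_identical(nrow(net$edges), as.integer(ref$n_significant))
      expect_identical(sum(net$edges$consistent), as.integer(ref$n_consistent))
    }
  }
})

test_that("the consistent fraction follows the predicted-sign bookkeeping", {
  x <- seq(-2, 2, length.out = 20)
  dat <- withr::with_seed(2, rbind(
    A = x + stats::rnorm(20, sd = 0.1),
    B = x + stats::rnorm(20, sd = 0.1),
    C = -x + stats::rnorm(20, sd = 0.1),
    D = x + stats::rnorm(20, sd = 0.1)
  ))
  colnames(dat) <- sprintf("S%02d", 1:20)
  # D labelled downregulated although it tracks x: its 3 edges are inconsistent
  sig <- sig_from(A = 1, B = 1, C = -1, D = -1)
  net <- build_relevance_network(z_normalize(dat), sig, correction = "none")
  expect_identical(nrow(net$edges), 6L)
  expect_identical(sum(net$edges$consistent), 3L)
  ct <- consistency_test(z_normalize(dat), sig, B = 100L, seed = 1L,
                         correction = "none")
  expect_equal(ct$score, 3 / 6)
})

test_that("an observed count beating every null gives the add-one minimum p", {
  ds <- simulate_perturbation_dataset(synthetic_config(
    n_samples = 100L, n_background_genes = 200L, n_true_up = 5L, n_true_dn = 5L,
    n_contaminant = 10L, seed = 5L))
  z <- z_normalize(ds$expr)
  ct <- consistency_test(z, ds$signature, B = 100L, seed = 6L)
  expect_equal(ct$score, 1)
  expect_identical(ct$n_significant_edges, 45L)
  expect_equal(ct$empirical_p, 1 / 101)
  # determinism of the Monte Carlo draw
  ct2 <- consistency_test(z, ds$signature, B = 100L, seed = 6L)
  expect_identical(ct$empirical_p, ct2$empirical_p)
})

test_that("signatures with no significant edges are unusable, not scored", {
  m <- withr::with_seed(3, gene_matrix(matrix(stats::rnorm(10 * 30), 10L, 30L)))
  sig <- signed_signature("S", stats::setNames(rep(c(1L, -1L), 5L), rownames(m)))
  ct <- consistency_test(z_normalize(m), sig, B = 100L, seed = 1L)
  expect_false(ct$usable)
  expect_true(is.na(ct$score))
  expect_true(is.na(ct$empirical_p))
  expect_error(
    build_relevance_network(z_normalize(m), sig_from(zz1 = 1, zz2 = -1)),
    class = "dartclq_unusable_error")
})

test_that("pruning keeps consistent edges, drops isolates, keeps the largest component", {
  edges <- data.frame(
    gene_a = c("A", "A", "B", "D"),
    gene_b = c("B", "C", "C", "E"),
    r = c(0.8, -0.7, 0.5, 0.9),
    predicted_sign = c(1L, -1L, -1L, 1L),
    stringsAsFactors = FALSE
  )
  net <- toy_network(edges, nodes = c("A", "B", "C", "D", "E", "F"),
                     signs = c(A = 1L, B = 1L, C = -1L, D = 1L, E = 1L, F = 1L))
  net$edges$consistent <- sign(net$edges$r) == net$edges$predicted_sign
  pruned <- prune_to_consistent(net)
  # BC is inconsistent (observed +, predicted -); F isolated; {D,E} smaller component
  expect_setequal(pruned$nodes, c("A", "B", "C"))
  expect_identical(nrow(pruned$edges), 2L)
  expect_true(all(pruned$edges$consistent))
  expect_true(pruned$usable)
})

test_that("pruning a fully inconsistent network flags it unusable", {
  edges <- data.frame(gene_a = "A", gene_b = "B", r = 0.9,
                      predicted_sign = -1L, consistent = FALSE,
                      stringsAsFactors = FALSE)
  pruned <- prune_to_consistent(toy_network(edges))
  expect_false(pruned$usable)
  expect_identical(nrow(pruned$edges), 0L)
})

test_that("pruned networks are sign-consistent subgraphs of their input", {
  for (seed in 1:5) {
    ds <- simulate_perturbation_dataset(synthetic_config(
      n_samples = 80L, n_background_genes = 100L, n_true_up = 8L, n_true_dn = 7L,
      n_contaminant = 20L, seed = seed))
    net <- build_relevance_network(z_normalize(ds$expr), ds$signature,
                                   correction = "none")
    pruned <- prune_to_consistent(net)
    in_key <- paste(net$edges$gene_a, net$edges$gene_b)
    out_key <- paste(pruned$edges$gene_a, pruned$edges$gene_b)
    expect_true(all(out_key %in% in_key))
    expect_true(all(pruned$nodes %in% net$nodes))
    sg <- ds$signature$signs
    expect_true(all(sign(pruned$edges$r) ==
                    sg[pruned$edges$gene_a] * sg[pruned$edges$gene_b]))
  }
})
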