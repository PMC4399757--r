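write_gmt_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("paired UP/DN entries become signed signatures; leftovers are skipped", {
  path <- write_gmt_lines(c(
    "A_UP\tna\tg1\tg2",
    "A_DN\tna\tg3",
    "B_UP\tna\tg4\tg5\tg6",
    "B_DN\tna\tg7\tg8",
    "LONER_UP\tna\tg9\tg10",
    "NOSUFFIX\tna\tg11\tg12"
  ))
  col <- read_gmt_pairs(path)
  expect_length(col$signatures, 2L)
  expect_setequal(col$skipped, c("LONER_UP", "NOSUFFIX"))
  a <- col$signatures[["A"]]
  expect_identical(a$signs, c(g1 = 1L, g2 = 1L, g3 = -1L))
  expect_identical(a$source_names, c("A_UP", "A_DN"))
  b <- col$signatures[["B"]]
  expect_identical(sum(b$signs == 1L), 3L)
  expect_identical(sum(b$signs == -1L), 2L)
})

test_that("genes listed in both halves of a pair are dropped and counted", {
  path <- write_gmt_lines(c("A_UP\tna\tg1\tg2", "A_DN\tna\tg2\tg3"))
  expect_message(col <- read_gmt_pairs(path), "conflicting direction")
  expect_identical(col$signatures[["A"]]$signs, c(g1 = 1L, g3 = -1L))
  expect_identical(col$n_conflicts, c(A = 1L))
})

test_that("a pair collapsing below 2 unambiguous genes is skipped, not returned", {
  path <- write_gmt_lines(c("A_UP\tna\tg1\tg2", "A_DN\tna\tg1\tg2",
                            "B_UP\tna\tg1", "B_DN\tna\tg2"))
  col <- suppressMessages(read_gmt_pairs(path))
  expect_length(col$signatures, 1L)  # B survives with 2 genes
  expect_true(all(c("A_UP", "A_DN") %in% col$skipped))
})

test_that("malformed GMT lines raise an error naming the line", {
  path <- write_gmt_lines(c("A_UP\tna\tg1\tg2", "broken\tonlytwo"))
  expect_error(read_gmt_pairs(path), "line 2")
  expect_error(read_gmt_pairs(file.path(tempdir(), "does-not-exist.gmt")),
               "cannot read")
})

test_that("a realistic mixed file pairs correctly at scale", {
  # 12 entries: 10 pair into 5 signatures, 2 are unpaired
  lines <- character(0)
  for (i in 1:5) {
    lines <- c(lines,
               sprintf("P%d_UP\tna\t%s", i, paste0("u", i, "_", 1:4, collapse = "\t")),
               sprintf("P%d_DN\tna\t%s", i, paste0("d", i, "_", 1:3, collapse = "\t")))
  }
  lines <- c(lines, "ODD_UP\tna\tx1\tx2", "STRAY_DN\tna\ty1\ty2")
  col <- read_gmt_pairs(write_gmt_lines(lines))
  expect_length(col$signatures, 5L)
  expect_length(col$skipped, 2L)
  expect_true(all(vapply(col$signatures, function(s)
    sum(s$signs == 1L) == 4L && sum(s$signs == -1L) == 3L, logical(1L))))
})

test_that("writing and re-reading a collection reproduces identical sign maps", {
  for (seed in 1:4) {
    col <- withr::with_seed(seed, {
      sigs <- lapply(1:3, function(i) {
        genes <- sample(sprintf("gene%03d", 1:200), sample(5:40, 1))
        signs <- stats::setNames(sample(c(-1L, 1L), length(genes), replace = TRUE), genes)
        if (length(unique(signs)) == 1L) signs[1L] <- -signs[1L]
        signed_signature(sprintf("SIG%d", i), signs)
      })
      list(signatures = stats::setNames(sigs, sprintf("SIG%d", 1:3)),
           skipped = character(0))
    })
    path <- withr::local_tempfile(fileext = ".gmt")
    write_gmt_pairs(structure(col, class = "signature_collection"), path)
    back <- read_gmt_pairs(path)
    for (nm in names(col$signatures))
      expect_identical(sort(back$signatures[[nm]]$signs),
                       sort(col$signatures[[nm]]$signs))
  }
})

test_that("gmt parsing agrees with the fgsea reader on well-formed files", {
  path <- write_gmt_lines(c("A_UP\tna\tg1\tg2\tg5", "A_DN\tna\tg3\tg4"))
  ref <- fgsea::gmtPathways(path)
  col <- read_gmt_pairs(path)
  expect_setequal(names(col$signatures[["A"]]$signs[col$signatures[["A"]]$signs == 1L]),
                  ref[["A_UP"]])
  expect_setequal(names(col$signatures[["A"]]$signs[col$signatures[["A"]]$signs == -1L]),
                  ref[["A_DN"]])
})

test_that("signed_signature enforces its invariants", {
  expect_error(signed_signature("X", c(g1 = 1L)), "at least 2")
  expect_error(signed_signature("X", c(g1 = 1L, g2 = 2L)), "exactly \\+1 or -1")
  expect_error(signed_signature("X", stats::setNames(c(1L, -1L, 1L), c("a", "b", "a"))),
               "duplicate")
})

test_that("random signatures match the template's size and direction exactly", {
  template <- sig_from(a = 1, b = 1, c = 1, d = -1, e = -1)
  universe <- sprintf("u%03d", 1:100)
  for (seed in 1:100) {
    rnd <- generate_random_signature(template, universe, seed = seed)
    expect_identical(sum(rnd$signs == 1L), 3L)
    expect_identical(sum(rnd$signs == -1L), 2L)
    expect_true(all(names(rnd$signs) %in% universe))
    expect_false(anyDuplicated(names(rnd$signs)) > 0L)
  }
})

test_that("random signature generation is deterministic and leaves RNG state alone", {
  template <- sig_from(a = 1, b = -1, c = -1)
  universe <- sprintf("u%03d", 1:50)
  r1 <- generate_random_signature(template, universe, seed = 11L)
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  r2 <- generate_random_signature(template, universe, seed = 11L)
  after <- stats::runif(1)
  expect_identical(r1$signs, r2$signs)
  expect_identical(before, after)
})

test_that("a universe equal to the template's genes yields a sign permutation", {
  template <- sig_from(a = 1, b = 1, c = -1, d = -1, e = -1)
  rnd <- generate_random_signature(template, names(template$signs), seed = 3L)
  expect_setequal(names(rnd$signs), names(template$signs))
  expect_identical(sort(unname(rnd$signs)), sort(unname(template$signs)))
  expect_error(generate_random_signature(template, c("x", "y")), "universe")
})
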