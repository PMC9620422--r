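test_that("ranked lists order by decreasing statistic with lexicographic ties", {
  rk <- ranked_list(c("b", "a", "c"), c(1, 1, 2))
  expect_equal(rk$genes, c("c", "a", "b"))
  expect_error(ranked_list(c("a", "a"), c(1, 2)), "duplicate")
  expect_error(ranked_list("a", NA_real_), "missing")

  tab <- deg_table(c("x", "y"), c(-1, 3), pvalue = c(0.4, 0.01))
  expect_equal(rank_from_deg(tab)$genes, c("y", "x"))
  expect_equal(rank_from_deg(tab, "signed_logp")$statistic[2], -log10(0.4) * -1)
})

test_that("extreme-of-list sets attain ES of +1 and -1 at exponent 0", {
  rk <- ranked_list(sprintf("g%02d", 1:10), 10:1)
  top <- enrichment_score(rk, c("g01", "g02"), weight_exponent = 0)
  expect_equal(top$es, 1)
  expect_setequal(top$leading_edge, c("g01", "g02"))
  bottom <- enrichment_score(rk, c("g09", "g10"), weight_exponent = 0)
  expect_equal(bottom$es, -1)
  expect_setequal(bottom$leading_edge, c("g09", "g10"))
  expect_error(enrichment_score(rk, "absent"), "intersect")
})

test_that("ES equals the brute-force running-sum oracle exhaustively", {
  # all 3-gene subsets over lists of 3..9 genes, both exponents (the full
  # sweep to length 12 runs in the acceptance suite)
  set.seed(5)
  for (L in 3:9) {
    genes <- sprintf("g%02d", 1:L)
    stat <- sort(rnorm(L, 0, 2), decreasing = TRUE)
    rk <- ranked_list(genes, stat)
    sets <- utils::combn(genes, min(3, L - 1), simplify = FALSE)
    for (s in sets) {
      for (expo in c(0, 1)) {
        expect_es_matches_oracle(rk, s, expo)
      }
    }
  }
})

test_that("reversing the ranked list negates ES at exponent 0", {
  set.seed(17)
  for (i in 1:20) {
    L <- sample(6:30, 1)
    genes <- sprintf("g%02d", 1:L)
    rk <- ranked_list(genes, seq(L, 1))
    rev_rk <- ranked_list(genes, seq(1, L))
    s <- sample(genes, sample(2:(L - 2), 1))
    es_f <- enrichment_score(rk, s, 0)
    es_r <- enrichment_score(rev_rk, s, 0)
    expect_equal(abs(es_r$es), abs(es_f$es), tolerance = 1e-12)
    # at an exact tie between the extrema the positive-wins convention
    # breaks the sign flip, so assert it only away from ties
    tie <- abs(max(es_f$running_sum) + min(es_f$running_sum)) < 1e-9
    if (!tie) expect_equal(es_r$es, -es_f$es, tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, bounded and mean-centered", {
  rk <- ranked_list(sprintf("g%03d", 1:100), rnorm(100))
  a <- permutation_null(rk, 10, 50, seed = 3)
  b <- permutation_null(rk, 10, 50, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, permutation_null(rk, 10, 50, seed = 4)))

  one <- permutation_null(rk, 10, 1, seed = 1)
  expect_length(one, 1)
  expect_true(abs(one) <= 1)

  expect_error(permutation_null(rk, 0, 10, seed = 1), "gene_set_size")
  expect_error(permutation_null(rk, 100, 10, seed = 1), "gene_set_size")

  set.seed(42)
  rk2 <- ranked_list(sprintf("g%03d", 1:100), rnorm(100))
  m <- mean(permutation_null(rk2, 10, 5000, seed = 7))
  expect_lt(abs(m), 0.05)
})

test_that("the permutation null leaves the caller's RNG state untouched", {
  rk <- ranked_list(sprintf("g%03d", 1:50), rnorm(50))
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(permutation_null(rk, 5, 20, seed = 9))
  expect_identical(runif(3), expected)
})

test_that("NES and permutation p follow the stated formulas", {
  # hand-built null [0.2, 0.4] with es 0.4: nes = 0.4/0.3, p = 2/3
  r <- nes_and_significance(0.4, c(0.2, 0.4))
  expect_equal(r$nes, 0.4 / 0.3)
  expect_equal(r$pvalue_perm, 2 / 3)

  # null all equal to es
  r2 <- nes_and_significance(0.3, rep(0.3, 10))
  expect_equal(r2$nes, 1)
  expect_equal(r2$pvalue_perm, 1)

  expect_equal(nes_and_significance(0, c(-0.5, 0.5))$nes, 0)

  # no same-sign null values: NES undefined, p = 1
  r3 <- nes_and_significance(0.4, c(-0.2, -0.3))
  expect_true(is.na(r3$nes))
  expect_equal(r3$pvalue_perm, 1)

  # mixed signs: only the same-sign side is used
  r4 <- nes_and_significance(-0.4, c(0.9, -0.2, -0.4, -0.8))
  expect_equal(r4$nes, -0.4 / mean(c(0.2, 0.4, 0.8)))
  expect_equal(r4$pvalue_perm, (1 + 2) / (1 + 3))
})

test_that("collection-level GSEA: single-set FDR, order invariance, skipping", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:60)
  rk <- ranked_list(genes, rnorm(60))
  one <- gsea_collection(rk, gene_set_collection(list(A = genes[1:8])),
                         n_perm = 50, seed = 2)
  expect_equal(one$fdr_perm, one$pvalue_perm)
  expect_true(abs(one$es) <= 1)
  expect_gte(one$pvalue_perm, 1 / 51)

  sets <- list(A = genes[1:8], B = genes[10:25], C = genes[30:40])
  res_fwd <- gsea_collection(rk, gene_set_collection(sets), n_perm = 50, seed = 2)
  res_rev <- gsea_collection(rk, gene_set_collection(rev(sets)), n_perm = 50, seed = 2)
  expect_identical(res_fwd, res_rev)

  with_alien <- gene_set_collection(c(sets, list(Z = "alien_gene")))
  expect_message(res2 <- gsea_collection(rk, with_alien, n_perm = 20, seed = 2),
                 "skipping")
  expect_setequal(res2$term, c("A", "B", "C"))
})

test_that("a mean-shifted gene set attains the top NES in seeded replicates", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    genes <- sprintf("g%04d", 1:500)
    stat <- rnorm(500)
    sets <- c(list(SHIFTED = sample(genes, 30)),
              stats::setNames(lapply(1:9, function(i) sample(genes, 30)),
                              paste0("RND", 1:9)))
    stat[genes %in% sets$SHIFTED] <- stat[genes %in% sets$SHIFTED] + 1
    res <- gsea_collection(ranked_list(genes, stat), gene_set_collection(sets),
                           n_perm = 100, seed = s)
    res$term[1] == "SHIFTED"
  }, logical(1))
  expect_gte(sum(wins), 18)
})
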