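test_that("Pearson edges match the product-moment and t formulas", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_with_pvalue(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_pvalue(x, -x)$r, -1)
  y <- c(2.3, 1.9, 3.4, 2.8, 4.4, 3.9)
  e <- pearson_with_pvalue(x, y)
  # from-scratch product-moment and t-distribution evaluation
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(4) / sqrt(1 - r_hand^2)
  expect_equal(e$r, r_hand, tolerance = 1e-12)
  expect_equal(e$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_identical(e$n, 6L)
  expect_error(pearson_with_pvalue(rep(1, 6), y), "zero variance")
  expect_error(pearson_with_pvalue(1:2, 1:2), "at least 3")
})

test_that("top-k TF network matches a brute-force ranking", {
  set.seed(21)
  genes <- matrix(rnorm(20 * 8), 20, 8,
                  dimnames = list(sprintf("g%02d", 1:20), NULL))
  tf <- matrix(rnorm(8), 1, 8, dimnames = list("tf1", NULL))
  k <- 5
  edges <- tf_correlation_network(tf, genes, k = k)
  r_all <- apply(genes, 1, function(g) cor(tf[1, ], g))
  oracle <- names(sort(-abs(r_all)))[1:k]
  expect_identical(edges$target, oracle)
  expect_equal(edges$r, unname(r_all[oracle]), tolerance = 1e-12)
  expect_identical(edges$rank, 1:5)
  # invariance under a uniform affine transform of expression
  edges2 <- tf_correlation_network(tf * 2 + 5, genes * 1.7 + 3, k = k)
  expect_identical(edges2$target, edges$target)
  expect_equal(edges2$r, edges$r, tolerance = 1e-12)
  # an exact affine copy wins at k = 1
  genes2 <- rbind(genes, copy = 3 * tf[1, ] + 2)
  expect_identical(tf_correlation_network(tf, genes2, k = 1)$target, "copy")
  # fewer candidates than k: all returned, with a warning
  expect_warning(all_edges <- tf_correlation_network(tf, genes, k = 50),
                 "only 20")
  expect_identical(nrow(all_edges), 20L)
  # two TFs at k = 5 give at most 10 edges
  tf2 <- rbind(tf, tf2 = rnorm(8))
  expect_lte(nrow(tf_correlation_network(tf2, genes, k = 5)), 10L)
})

test_that("planted TF targets dominate the selection at low noise", {
  des <- planted_omics_design(
    n_features = c(transcript = 40, protein = 5, metabolite = 5),
    planted_log2fc = list(),
    tf_target_map = list(transcript_001 = list(
      targets = sprintf("transcript_%03d", 2:7),
      loadings = c(1, 1, -1, 1, -1, 1))),
    coupled_genes = character(0), coupled_metabolites = character(0),
    sigma = 0.02, seed = 8)
  logm <- log2(gen_omics_dataset(des)$transcript$abundance)
  edges <- tf_correlation_network(logm["transcript_001", , drop = FALSE],
                                  logm[-1, , drop = FALSE], k = 6)
  expect_setequal(edges$target, sprintf("transcript_%03d", 2:7))
})

test_that("Mantel statistic is exact and its enumeration p matches an oracle", {
  set.seed(22)
  x <- matrix(rnorm(6 * 4), 6, 4)
  y <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(mantel_test(x, x, permutations = 99, seed = 1)$statistic, 1)
  res <- mantel_test(x, y, exact = TRUE)
  oracle <- mantel_exact_oracle(x, y)
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(res$p.value, oracle$p, tolerance = 1e-12)
  expect_identical(res$permutations, 24L)
  expect_gte(res$p.value, 1 / 24)
})

test_that("Mantel statistic agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(23)
  x <- matrix(rnorm(6 * 7), 6, 7)
  y <- matrix(rnorm(6 * 7), 6, 7)
  ours <- mantel_test(x, y, permutations = 99, seed = 1)
  ref <- suppressWarnings(vegan::mantel(dist(t(x)), dist(t(y)),
                                        permutations = 99))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Mantel p is seeded and inputs are validated", {
  set.seed(24)
  x <- matrix(rnorm(6 * 6), 6, 6)
  y <- matrix(rnorm(6 * 6), 6, 6)
  a <- mantel_test(x, y, permutations = 199, seed = 5)
  b <- mantel_test(x, y, permutations = 199, seed = 5)
  expect_identical(a$p.value, b$p.value)
  expect_gte(a$p.value, 1 / 200)
  expect_error(mantel_test(x[, 1:3], y[, 1:3], permutations = 199),
               "at least 4 samples")
  expect_error(mantel_test(x, y, permutations = 10), "99")
  expect_error(mantel_test(x, y[, 1:5], permutations = 199), "same sample")
})

test_that("mantel_pairs detects the planted gene-metabolite coupling", {
  des <- planted_omics_design(sigma = 0.1, seed = 5)
  tabs <- gen_omics_dataset(des)
  logg <- log2(tabs$transcript$abundance)
  logmet <- log2(tabs$metabolite$abundance)
  groups <- setNames(rep("EC:4.1.1.39", length(des$coupled_genes)),
                     des$coupled_genes)
  mp <- mantel_pairs(logg, groups, logmet[des$coupled_metabolites[1:2], ,
                                          drop = FALSE],
                     permutations = 199, seed = 2)
  expect_identical(nrow(mp), 2L)
  expect_true(all(mp$p <= 0.01))
  expect_true(all(mp$r_m > 0.5))
  # reproducible under the same base seed
  mp2 <- mantel_pairs(logg, groups, logmet[des$coupled_metabolites[1:2], ,
                                           drop = FALSE],
                      permutations = 199, seed = 2)
  expect_identical(mp$p, mp2$p)
})
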