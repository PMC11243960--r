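test_that("fold change uses the experimental/control group-mean convention", {
  m <- rbind(c(10, 10, 10, 10, 10, 10),
             c(5, 5, 5, 20, 20, 20),
             c(8, 10, 12, 40, 38, 42))
  tab <- two_group_table(m)
  fc <- fold_change(tab, "AvsB")
  expect_equal(fc$fc[1], 1)
  expect_equal(fc$log2fc[1], 0)
  expect_equal(fc$fc[2], 4)
  expect_equal(fc$log2fc[2], 2)
  expect_equal(fc$fc[3], 40 / 10)
  # zeros need an explicit offset
  m0 <- rbind(c(0, 0, 0, 5, 5, 5))
  expect_error(fold_change(two_group_table(m0), "AvsB"), "offset")
  fc0 <- fold_change(two_group_table(m0), "AvsB", offset = 1)
  expect_equal(fc0$fc, 6)
  expect_identical(attr(fc0, "offset"), 1)
})

test_that("Welch test matches the textbook statistic on a toy example", {
  a <- c(5.1, 5.3, 4.9)   # log2 abundances, treatment (B)
  b <- c(6.0, 6.4, 6.2)   # control (A)
  tab <- two_group_table(rbind(2^c(b, a)))
  w <- welch_test(tab, "AvsB")
  # hand-computed Welch statistic and Welch-Satterthwaite df
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p, p_hand, tolerance = 1e-12)
  # identical constant groups: p = 1 by convention, flagged
  tab2 <- two_group_table(rbind(rep(8, 6)))
  w2 <- welch_test(tab2, "AvsB")
  expect_identical(w2$p, 1)
  expect_true(w2$zero_variance)
})

test_that("Welch test is calibrated under the global null", {
  des <- planted_omics_design(
    n_features = c(transcript = 1, protein = 1000, metabolite = 1),
    planted_log2fc = list(), tf_target_map = list(),
    coupled_genes = character(0), coupled_metabolites = character(0),
    sigma = 0.25, seed = 3)
  w <- welch_test(gen_omics_dataset(des)$protein, "AvsB")
  expect_gte(mean(w$p < 0.05), 0.03)
  expect_lte(mean(w$p < 0.05), 0.07)
})

test_that("VIP scores are normalised and single out a separating feature", {
  set.seed(11)
  m <- 2^matrix(rnorm(10 * 6, 8, 0.3), 10, 6)
  m[4, 4:6] <- m[4, 4:6] * 2^4          # strong planted separation
  tab <- two_group_table(m, layer = "metabolite")
  v <- pls_vip(tab, "AvsB")
  expect_equal(sum(v$vip^2), nrow(m), tolerance = 1e-9)
  expect_identical(which.max(v$vip), 4L)
  expect_gt(max(v$vip), 1)
  # constant features are dropped with a warning, normalisation adapts
  m2 <- m
  m2[1, ] <- 5
  expect_warning(v2 <- pls_vip(two_group_table(m2, "metabolite"), "AvsB"),
                 "constant")
  expect_equal(sum(v2$vip^2), nrow(m) - 1, tolerance = 1e-9)
})

test_that("VIP agrees with the reference PLS-DA implementation", {
  set.seed(12)
  m <- 2^matrix(rnorm(8 * 6, 8, 0.5), 8, 6)
  m[2, 4:6] <- m[2, 4:6] * 4
  tab <- two_group_table(m, layer = "metabolite")
  v <- pls_vip(tab, "AvsB")
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  fit <- mixOmics::plsda(t(log2(tab$abundance)),
                         factor(rep(c("A", "B"), each = 3)),
                         ncomp = 1, scale = TRUE)
  ref <- mixOmics::vip(fit)[v$feature, 1]
  expect_equal(v$vip, unname(ref), tolerance = 1e-8)
})

test_that("permuting class labels destroys the VIP ranking", {
  set.seed(13)
  m <- 2^matrix(rnorm(5 * 6, 8, 0.3), 5, 6)
  m[1, 4:6] <- m[1, 4:6] * 2^4
  samples <- paste(rep(c("A", "B"), each = 3), 1:3, sep = "_")
  first <- vapply(1:100, function(i) {
    mp <- m[, sample(6), drop = FALSE]
    dimnames(mp) <- list(sprintf("m_%02d", 1:5), samples)
    tab <- omics_table(mp, data.frame(sample = samples,
                                      group = rep(c("A", "B"), each = 3)),
                       "metabolite")
    which.max(pls_vip(tab, "AvsB")$vip) == 1L
  }, logical(1))
  expect_lt(mean(first), 0.5)
})

test_that("screening rules implement each layer's thresholds exactly", {
  prot <- data.frame(feature = c("p1", "p2", "p3", "p4"),
                     fc = c(1.19, 1.2, 0.83, 2),
                     p = c(0.001, 0.04, 0.04, 0.2))
  out <- screen_differential(prot, "protein")
  expect_identical(out$call, c("ns", "up", "down", "ns"))
  met <- data.frame(feature = c("m1", "m2", "m3"),
                    fc = c(1.6, 0.5, 1.6),
                    vip = c(1.2, 1.2, 0.9))
  expect_identical(screen_differential(met, "metabolite")$call,
                   c("up", "down", "ns"))
  expect_error(screen_differential(met[, c("feature", "fc")], "metabolite"),
               "'vip' column")
  tra <- data.frame(feature = c("t1", "t2", "t3"),
                    fc = c(1.01, 0.99, 1.5),
                    q = c(0.01, 0.01, 0.2))
  expect_identical(screen_differential(tra, "transcript")$call,
                   c("up", "down", "ns"))
})

test_that("raising thresholds never adds screening calls", {
  set.seed(14)
  rec <- data.frame(feature = sprintf("p%03d", 1:200),
                    fc = 2^rnorm(200, 0, 0.6),
                    p = runif(200))
  loose <- screen_differential(rec, "protein",
                               list(p = 0.05, fc_up = 1.2, fc_down = 0.83))
  tight <- screen_differential(rec, "protein",
                               list(p = 0.01, fc_up = 1.5, fc_down = 0.67))
  called <- function(x) x$feature[x$call != "ns"]
  expect_true(all(called(tight) %in% called(loose)))
})

test_that("z-score rows are standardised exactly", {
  set.seed(15)
  m <- matrix(rnorm(5 * 6, 10, 2), 5, 6,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  z <- zscore_matrix(m)
  brute <- t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(unclass(z)[, ], brute, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
  m[2, ] <- 7
  z2 <- zscore_matrix(m)
  expect_identical(attr(z2, "constant_features"), "f2")
  expect_true(all(z2[2, ] == 0))
  expect_error(zscore_matrix(m[, 1, drop = FALSE]), "2 samples")
})

test_that("published worked-example tables load with expected structure", {
  raw <- calvin_cycle_degs()
  expect_identical(nrow(raw), 7L)
  tidy <- calvin_cycle_degs(tidy = TRUE)
  expect_true(all(c("feature", "fc", "q", "ec") %in% names(tidy)))
  g2 <- g2like_members()
  expect_identical(nrow(g2), 10L)             # duplicated row preserved
  g2t <- g2like_members(tidy = TRUE)
  expect_false(any(duplicated(g2t[, c("feature", "comparison")])))
  pcc <- tf_calvin_correlations()
  expect_identical(dim(pcc), c(10L, 4L))
  expect_identical(length(unique(pcc$tf_id)), 2L)
})
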