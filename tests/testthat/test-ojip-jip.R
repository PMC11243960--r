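test_that("cardinal points follow their definitions", {
  p <- ojip_model_params()
  tr <- gen_ojip_transient(p)
  cp <- extract_cardinal_points(tr)
  # the default grid samples the cardinal times, so the noiseless values
  # equal the closed-form model there
  expect_equal(cp$FK, ojip_model_value(p, 3e-4), tolerance = 1e-9)
  expect_equal(cp$FJ, ojip_model_value(p, 2e-3), tolerance = 1e-9)
  expect_equal(cp$FI, ojip_model_value(p, 3e-2), tolerance = 1e-9)
  expect_identical(cp$Fo, min(tr$fluorescence))
  expect_identical(cp$Fm, max(tr$fluorescence))

  # O is the global minimum even when it sits at an interior sample
  f2 <- tr$fluorescence
  f2[5] <- f2[1] * 0.9
  cp2 <- extract_cardinal_points(fluorescence_transient(tr$time, f2))
  expect_identical(cp2$Fo, f2[5])
  expect_identical(cp2$t_O, tr$time[5])
  expect_identical(cp2$F_first, f2[1])

  flat <- fluorescence_transient(tr$time, rep(100, length(tr$time)))
  expect_error(extract_cardinal_points(flat), "degenerate")
})

test_that("normalisation identities hold on any valid transient", {
  tr <- gen_ojip_transient(ojip_model_params(noise_sd = 0.01, seed = 2))
  cp <- extract_cardinal_points(tr)
  nc <- normalize_transient(tr, cp)
  i_p <- which.max(tr$fluorescence)
  expect_identical(nc$vt[i_p], 1)
  wt_at_j <- approx(log(nc$time), nc$wt, xout = log(2e-3))$y
  expect_equal(wt_at_j, 1, tolerance = 1e-12)
  expect_equal(nc$rel, tr$fluorescence / cp$Fo)

  # noiseless Vt at 2 ms equals the closed-form ratio
  p <- ojip_model_params()
  trn <- gen_ojip_transient(p)
  ncn <- normalize_transient(trn)
  vj <- approx(log(ncn$time), ncn$vt, xout = log(2e-3))$y
  cpn <- ncn$points
  expect_equal(vj, (ojip_model_value(p, 2e-3) - cpn$Fo) / (cpn$Fm - cpn$Fo),
               tolerance = 1e-9)

  # a trace still flat at 2 ms has no O-J normalisation
  t <- ojip_time_grid()
  f <- ifelse(t <= 5e-3, 100, 100 + 900 * (1 - exp(-(t - 5e-3) / 0.05)))
  expect_error(normalize_transient(fluorescence_transient(t, f)),
               "O-J standardisation")
})

test_that("difference curves: self-zero, antisymmetry and K-band sign", {
  healthy <- normalize_transient(gen_ojip_transient(ojip_model_params()))
  self <- difference_curves(healthy, healthy)
  expect_true(all(abs(self$dvt) < 1e-12))
  expect_identical(self$dwk, 0)

  damaged <- normalize_transient(gen_ojip_transient(
    ojip_model_params(Fm = 2250, k_band_weight = 0.15), label = "B"))
  fwd <- difference_curves(damaged, healthy)
  rev <- difference_curves(healthy, damaged)
  expect_gt(fwd$dwk, 0)
  expect_equal(fwd$dvt, -rev$dvt, tolerance = 1e-12)
  expect_equal(fwd$dwt, -rev$dwt, tolerance = 1e-12)
  expect_equal(fwd$dwk, -rev$dwk, tolerance = 1e-12)

  # disjoint time ranges cannot be differenced
  a <- structure(list(time = 1:10 * 1e-4, vt = runif(10), wt = runif(10),
                      label = "x"), class = "normalized_curves")
  b <- structure(list(time = 1:10 * 1e-1, vt = runif(10), wt = runif(10),
                      label = "y"), class = "normalized_curves")
  expect_error(difference_curves(a, b), "do not overlap")
})

test_that("JIP parameters follow their defining formulas", {
  t <- ojip_time_grid(n = 60)
  f <- 500 + 2000 * (seq_along(t) - 1) / (length(t) - 1)
  tr <- fluorescence_transient(t, f)
  jp <- jip_parameters(tr)
  expect_identical(jp$fv_fm, (2500 - 500) / 2500)
  cp <- extract_cardinal_points(tr)
  expect_equal(jp$mo, 4 * (cp$FK - 500) / 2000, tolerance = 1e-12)
  expect_equal(jp$vj, (cp$FJ - 500) / 2000, tolerance = 1e-12)
  expect_equal(jp$psi0, 1 - jp$vj, tolerance = 1e-12)
  expect_equal(jp$psie0, jp$fv_fm * (1 - jp$vj), tolerance = 1e-12)
  expect_equal(jp$pi_abs,
               jp$rc_abs * jp$fv_fm / (1 - jp$fv_fm) * jp$psi0 / (1 - jp$psi0),
               tolerance = 1e-12)
  expect_equal(jp$tr0_rc * jp$vj, jp$mo, tolerance = 1e-12)
  expect_equal(jp$et0_rc, jp$tr0_rc * jp$psi0, tolerance = 1e-12)
  expect_equal(jp$tr0_cs0, jp$fv_fm * 500, tolerance = 1e-12)
  df <- as.data.frame(jp)
  expect_named(df, c("parameter", "value"))
  expect_true("pi_abs" %in% df$parameter)
})

test_that("dimensionless parameters are invariant under rescaling", {
  tr <- gen_ojip_transient(ojip_model_params(noise_sd = 0.005, seed = 6))
  scaled <- fluorescence_transient(tr$time, tr$fluorescence * 3.7)
  a <- unlist(unclass(jip_parameters(tr)))
  b <- unlist(unclass(jip_parameters(scaled)))
  dimensionless <- c("fv_fm", "vj", "vi", "wk", "mo", "sm", "psi0", "psie0",
                     "rc_abs", "pi_abs", "tr0_rc", "et0_rc")
  expect_equal(b[dimensionless], a[dimensionless], tolerance = 1e-12)
  per_cs <- c("rc_cs0", "tr0_cs0", "et0_cs0")
  expect_equal(b[per_cs], a[per_cs] * 3.7, tolerance = 1e-12)
})

test_that("doubling the grid density moves every parameter by < 0.5%", {
  p <- ojip_model_params()
  a <- unlist(unclass(jip_parameters(gen_ojip_transient(p))))
  b <- unlist(unclass(jip_parameters(
    gen_ojip_transient(p, grid = ojip_time_grid(n = 240)))))
  expect_true(all(abs(b - a) / abs(a) < 0.005))
})

test_that("group summaries report means, SEs and LSD letters", {
  values <- c(10, 11, 9, 20, 21, 19, 10.5, 9.5, 10.4)
  groups <- rep(c("A", "B", "C"), each = 3)
  gs <- group_summary(values, groups)
  expect_equal(gs$mean, c(10, 20, 10.1333), tolerance = 1e-4)
  fit <- aov(values ~ factor(groups))
  expect_equal(gs$se,
               rep(sqrt(sum(residuals(fit)^2) / df.residual(fit) / 3), 3),
               tolerance = 1e-10)
  expect_identical(gs$letter[gs$group == "B"], "a")   # top mean alone
  expect_identical(gs$letter[gs$group == "A"], gs$letter[gs$group == "C"])
  expect_false(gs$letter[gs$group == "A"] == "a")
  expect_error(group_summary(c(1, 2), c("A", "B")), "2 replicates")
})
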