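test_that("noiseless OJIP model starts at Fo and saturates at Fm", {
  p <- ojip_model_params()
  expect_lt(abs(ojip_model_value(p, 1e-9) - p$Fo), 1e-3 * p$Fo)
  tr <- gen_ojip_transient(p)
  n <- length(tr$time)
  # at 2 s every phase has run for >= 16 time constants
  expect_lt(abs(tr$fluorescence[n] - p$Fm) / p$Fm, 0.001)
  expect_equal(tr$fluorescence, ojip_model_value(p, tr$time))
})

test_that("OJIP generator is seed-reproducible and validates its inputs", {
  p <- ojip_model_params(noise_sd = 0.01, seed = 7)
  expect_identical(gen_ojip_transient(p)$fluorescence,
                   gen_ojip_transient(p)$fluorescence)
  p2 <- ojip_model_params(noise_sd = 0.01, seed = 8)
  expect_false(identical(gen_ojip_transient(p)$fluorescence,
                         gen_ojip_transient(p2)$fluorescence))
  expect_error(ojip_model_params(Fo = 600, Fm = 500), "Fm must exceed Fo")
  expect_error(ojip_model_params(phase_weights = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(ojip_model_params(phase_taus = c(0.01, 0.01, 0.1)),
               "strictly increasing")
  expect_error(ojip_model_params(noise_sd = -0.1), "noise_sd")
  expect_error(gen_ojip_transient(p, grid = rev(ojip_time_grid())),
               "strictly increasing")
  expect_error(gen_ojip_transient(p, grid = seq(0.1, 3, length.out = 60)),
               "within \\(0, 2\\]")
})

test_that("K-band injection raises the downstream Wk statistic", {
  wk_at <- function(k) {
    tr <- gen_ojip_transient(ojip_model_params(k_band_weight = k))
    jip_parameters(tr)$wk
  }
  wks <- vapply(c(0, 0.1, 0.2), wk_at, numeric(1))
  expect_true(all(diff(wks) > 0))
})

test_that("light-curve generator: dark point, exact round trip, validation", {
  ds <- gen_light_curve_dataset()
  q <- quenching_parameters(ds)
  expect_identical(q$retr[q$par == 0], 0)
  expect_identical(q$npq[q$par == 0], 0)
  fit <- fit_light_curve(q$par, q$retr)
  expect_lt(abs(fit$alpha - 0.3) / 0.3, 1e-6)
  expect_lt(abs(fit$etrmax - 60) / 60, 1e-6)
  expect_error(gen_light_curve_dataset(noise_sd = -0.01), "noise_sd")
  expect_error(gen_light_curve_dataset(par_levels = c(0, 100, 200, 400)),
               ">= 700")
  expect_error(gen_light_curve_dataset(alpha_true = 0.5), "PhiPSII")
})

test_that("alpha is recovered within 10% in at least 9 of 10 noisy runs", {
  hits <- vapply(1:10, function(s) {
    ds <- gen_light_curve_dataset(noise_sd = 0.05, seed = s)
    q <- quenching_parameters(ds)
    fit <- fit_light_curve(q$par, q$retr)
    abs(fit$alpha - 0.3) / 0.3 < 0.1
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("omics generator recovers planted log2 fold changes as noise vanishes", {
  des <- planted_omics_design(
    n_features = c(transcript = 20, protein = 5, metabolite = 5),
    planted_log2fc = list(transcript = c(transcript_001 = 1.5,
                                         transcript_002 = -2)),
    tf_target_map = list(), coupled_genes = character(0),
    coupled_metabolites = character(0), sigma = 0.01, seed = 4)
  tabs <- gen_omics_dataset(des)
  fc <- fold_change(tabs$transcript, "AvsB")
  expect_equal(fc$log2fc[fc$feature == "transcript_001"], 1.5,
               tolerance = 0.05)
  expect_equal(fc$log2fc[fc$feature == "transcript_002"], -2,
               tolerance = 0.05)
  # seed determinism: bit-identical regeneration
  tabs2 <- gen_omics_dataset(des)
  expect_identical(tabs$transcript$abundance, tabs2$transcript$abundance)
  expect_identical(tabs$metabolite$abundance, tabs2$metabolite$abundance)
})

test_that("TF-target latent factors give correlations of the planted sign", {
  des <- planted_omics_design(
    n_features = c(transcript = 20, protein = 5, metabolite = 5),
    planted_log2fc = list(),
    tf_target_map = list(transcript_010 = list(
      targets = c("transcript_011", "transcript_012"),
      loadings = c(1, -1))),
    coupled_genes = character(0), coupled_metabolites = character(0),
    sigma = 1e-3, seed = 9)
  logm <- log2(gen_omics_dataset(des)$transcript$abundance)
  expect_gt(cor(logm["transcript_010", ], logm["transcript_011", ]), 0.999)
  expect_lt(cor(logm["transcript_010", ], logm["transcript_012", ]), -0.999)
})

test_that("null tables yield no differential calls at small noise", {
  zero_call_runs <- vapply(1:10, function(s) {
    des <- planted_omics_design(
      n_features = c(transcript = 1, protein = 50, metabolite = 1),
      planted_log2fc = list(), tf_target_map = list(),
      coupled_genes = character(0), coupled_metabolites = character(0),
      sigma = 0.05, seed = s)
    calls <- screen_layer(gen_omics_dataset(des)$protein, "AvsB")
    all(calls$call == "ns")
  }, logical(1))
  expect_gte(sum(zero_call_runs), 9L)
})

test_that("invalid planted designs are rejected", {
  expect_error(planted_omics_design(
    planted_log2fc = list(transcript = c(nope_001 = 2))), "not in the")
  expect_error(planted_omics_design(reps_per_group = 1), "reps_per_group")
  expect_error(planted_omics_design(
    tf_target_map = list(transcript_101 = list(targets = "transcript_999",
                                               loadings = 1))),
    "unknown transcript")
})
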