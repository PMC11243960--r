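---
title: "Methods: fluorescence phenotyping and multi-omics screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence phenotyping and multi-omics screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoromics)
```

`fluoromics` covers the analysis chain of a UV-B stress photosynthesis
experiment: fast chlorophyll fluorescence (OJIP) transients, PAM
saturation-pulse quenching with rapid light curves, rule-based
differential screening of transcript/protein/metabolite tables, and
correlation/Mantel integration across layers. This vignette records the
models behind each stage, the defaults and why they were chosen, and the
numerical conventions a user should know before trusting the output.

## OJIP transients and the JIP test

A dark-adapted leaf exposed to saturating light emits a polyphasic
fluorescence rise with characteristic points O (origin, minimal
fluorescence), K (300 µs), J (2 ms), I (30 ms) and P (peak, F~m~). The
package follows the classical JIP-test reading of this curve.

**Cardinal points.** `extract_cardinal_points()` takes F~o~ as the global
minimum of the record and F~m~ as the global maximum, with their times.
Instruments sometimes treat the first sample (10–20 µs) as O; on noisy
records the two can differ, so the first-sample value is also reported
(`F_first`) while the global minimum remains the primary definition. K, J
and I are evaluated at exactly 300 µs, 2 ms and 30 ms; because
acquisition grids are log-spaced, interpolation is linear in log-time.
The default synthetic grid (`ojip_time_grid()`) inserts these three times
as exact sample points, as instrument exports do, so noiseless synthetic
cardinal values are sampled rather than interpolated.

**Normalisations.** `normalize_transient()` computes F~t~/F~o~,
V~t~ = (F~t~ − F~o~)/(F~m~ − F~o~) and W~t~ = (F~t~ − F~o~)/(F~J~ − F~o~).
By construction V~t~ is 0 at O and 1 at P, and W~t~ is 1 at 2 ms; the
test suite asserts both identities.

**Difference curves.** `difference_curves()` re-interpolates the control
onto the treatment grid (log-time linear) over the overlapping range and
subtracts. The caller chooses the control: in a four-group design
(A control, B UV-B, C UV-B + ABA, D ABA) it is meaningful to difference
B against A but also C against D, and the package imposes no pairing.
ΔW~k~, the difference at 300 µs, is the donor-side damage statistic: a
positive value means the treatment's O-J rise is relatively faster at the
K band, the fingerprint of an impaired oxygen-evolving complex.

**Derived parameters.** The paper-level parameter set is named only by
its symbols in most publications; the formulas here follow the standard
Strasser-type JIP test:

* φ~P0~ = F~v~/F~m~ = (F~m~ − F~o~)/F~m~; V~J~ = V~t~(2 ms);
  V~I~ = V~t~(30 ms); W~k~ = W~t~(300 µs).
* M~o~ = 4 (F~K~ − F~o~)/(F~m~ − F~o~) per ms. The factor 4 (= 1/0.25 ms)
  is the usual initial-slope approximation anchored at the K point; it is
  a convention, not a fit.
* S~m~ = [∫(F~m~ − F~t~) dt]/(F~m~ − F~o~), integrated by the trapezoid
  rule on the native grid from the time of O to the time of F~m~, in
  milliseconds (the customary JIP unit). When F~m~ occurs before the end
  of the record the integral stops at t(F~m~).
* ψ~0~ = 1 − V~J~ (probability a trapped exciton's electron passes
  Q~A~), Ψ~E0~ = φ~P0~(1 − V~J~) (the same per absorbed photon) — the
  captured- vs absorbed-energy wording distinguishes the two.
* RC/ABS = φ~P0~ V~J~/M~o~, and PI~abs~ = (RC/ABS) · φ~P0~/(1 − φ~P0~) ·
  ψ~0~/(1 − ψ~0~).
* TR~0~/RC = M~o~/V~J~; ET~0~/RC = (M~o~/V~J~)(1 − V~J~). Cross-section
  fluxes use the standard proxy ABS/CS~0~ ≈ F~o~ (recorded in the result
  attributes): RC/CS~0~, TR~0~/CS~0~ = φ~P0~F~o~, ET~0~/CS~0~ = Ψ~E0~F~o~.

Degenerate inputs are handled explicitly rather than silently: a flat
trace (F~m~ = F~o~) is an error, and V~J~ ∈ {0, 1} flags the parameters
that divide by V~J~, 1 − V~J~ or M~o~ as `NA` (listed in the
`degenerate` attribute) while the rest of the set is still returned.

**Group statistics.** `group_summary()` reports means ± SE with compact
letters from one-way ANOVA followed by pairwise LSD at α = 0.05, the
usual presentation for n = 3 phenotyping panels.

## PAM quenching and rapid light curves

Per light step with steady-state F and pulse maximum F~m~′, against the
dark-adapted F~0~ and F~m~:

* Φ~PSII~ = (F~m~′ − F)/F~m~′, NPQ = (F~m~ − F~m~′)/F~m~′,
  qP = (F~m~′ − F)/(F~m~′ − F~o~′).
* F~o~′ is estimated by the Oxborough–Baker relation
  F~o~′ = F~0~/(F~v~/F~m~ + F~0~/F~m~′), since no far-red F~o~′
  measurement is part of the protocol.
* Y(NO) defaults to the simplified lake-model form F/F~m~; the Kramer
  form 1/(1 + NPQ + qL(F~m~/F~0~ − 1)) is available via
  `yno_form = "kramer"`. The two agree in the dark-adapted state.
* rETR = Φ~PSII~ · PAR · 0.5 · 0.84. The PSII fraction (0.5) and leaf
  absorptance (0.84) are community defaults, not measurements, and are
  exposed as arguments/config so species-specific values can be used.

Steps where F~m~′ exceeds F~m~ produce negative NPQ; they are kept but
flagged with a warning, because hiding them would mask instrument drift.
Steps where F~m~′ collapses onto F~o~′ leave qP undefined (`NA`, flagged).

**Light-curve model.** `fit_light_curve()` uses the exponential-free
saturating form rETR = ETR~max~ tanh(α·PAR/ETR~max~), fitted by
Levenberg–Marquardt with multi-start initialisation (α from the steepest
low-light secant, ETR~max~ from the largest observed rETR, both perturbed
over a small grid); the best converged start by RSS wins and
non-convergence is an error, never a silent fallback. E~k~ = ETR~max~/α
is computed as an identity from the fitted pair. The tanh form was chosen
because it has exactly the two parameters the downstream summaries use
and fits the generator's saturation shape without a photoinhibition term;
records showing strong high-light decline would need a different model
and are out of scope.

## Differential screening

Fold change is the ratio of group means on the linear abundance scale
(experimental/control, with the comparison label `"AvsB"` reading
"A is control, B is treatment"). Zeros are handled by an explicit,
recorded pseudo-abundance offset — never silently.

The per-layer rules are:

| layer | rule |
|---|---|
| metabolite | VIP > 1 and FC ≥ 1.5 (up) or FC ≤ 0.67 (down) |
| protein | p < 0.05 and FC ≥ 1.2 (up) or FC ≤ 0.83 (down) |
| transcript | Q < 0.05 and FC > 1 (up) or FC < 1 (down) |

The protein test is a two-sided Welch t on log2 abundances: at n = 3 per
group, unequal variances are the rule rather than the exception and the
Welch form is the robust default. Transcript Q-values supplied with a
table (as in published DEG summaries) are used as-is; when the package
computes transcript tests itself it applies Benjamini–Hochberg to its own
Welch p-values. The transcript fold rule (any FC > 1) is implemented
literally, with the bounds exposed in the config for users who want a
stricter fold threshold.

VIP scores come from a two-class PLS model written with NIPALS: features
autoscaled to unit variance, class-coded centred response, one component
by default. The VIP definition normalises the mean squared score to 1,
so `sum(VIP^2)` equals the number of retained features — an identity the
tests assert — and VIP > 1 marks above-average discriminating weight.
Vendor metabolomics workflows typically report OPLS-DA VIP; with one
predictive component the PLS-DA VIP used here plays the same role but is
not numerically identical to an OPLS-DA implementation, which is why the
component count is configurable and the choice is documented here. The
test suite cross-checks the scores against an independent PLS-DA
implementation.

Heat-map preparation (`zscore_matrix()`) standardises each feature to
mean 0, SD 1; constant features cannot be scaled and are returned as
zero rows with their ids flagged.

## Correlation and Mantel integration

`tf_correlation_network()` ranks candidate genes per transcription factor
by |r| (the display plots signed edges, but selection strength is
absolute correlation), keeps the top k (default 50), and breaks ties by
lexicographic gene id so results are reproducible. Edges carry r, the
t-based p-value and the rank; a |r| > 0.9 filter flags "strongly
correlated" pairs. Pearson invariance makes the selection immune to
uniform affine rescaling of expression.

`mantel_test()` correlates the vectorised distance matrices of two
feature-by-sample blocks over the same samples. Defaults: Euclidean
distance, one-sided test, significance by permuting the sample labels of
the second matrix with p = (1 + #{r\* ≥ r})/(1 + B). Both the metric and
the sidedness are arguments because neither is canonical. For n ≤ 7 an
exact mode enumerates all n! permutations. The gene–metabolite summary
(`mantel_pairs()`) groups genes by enzyme (EC number) and tests each
enzyme block against each metabolite, mirroring integration figures that
pair enzyme-number gene groups with named Calvin-cycle metabolites;
single genes per group are accepted (a one-feature distance matrix is
just the pairwise abundance difference).

## Synthetic data: what it does and does not emulate

The generators exist so that every stage has a parameter-recovery test
surface with known truth; their defaults are stand-ins chosen to look
like a realistic small phenotyping study, since no quantitative noise or
effect-size characterisation of real instrument data ships with the
package.

**OJIP** (`gen_ojip_transient()`): a three-exponential rise
F(t) = F~o~ + (F~m~ − F~o~) Σ w~i~(1 − e^−t/τ~i~^) with defaults
τ = (0.4 ms, 10 ms, 120 ms) and weights (0.5, 0.3, 0.2), placing the J
and I inflections near 2 and 30 ms. This is a phenomenological shape
generator, not a mechanistic electron-transport simulation: it produces
no K-band dip kinetics, no I-P heterogeneity, and its phases are exactly
exponential. Donor-side damage is emulated jointly by an injected
ultra-fast phase (`k_band_weight`, τ = 0.2 ms, remaining weights
renormalised) and a caller-supplied F~m~ reduction, matching the joint
K-band rise and F~m~ drop seen in damaged leaves. Noise is multiplicative
Gaussian (default 1% when enabled), seeded.

**Rapid light curves** (`gen_light_curve_dataset()`): rETR is drawn from
the tanh model plus multiplicative noise, and the fluorescence record is
back-computed so quenching analysis inverts the generator exactly: NPQ
follows a sigmoidal Hill response npq~max~·PAR²/(PAR² + E~k~²)
(half-saturation at E~k~), F~m~′ = F~m~/(1 + NPQ), and
F = F~m~′(1 − Φ~PSII~) with Φ~PSII~ implied by the drawn rETR. The Hill
exponent 2 matches the sigmoidal shape of measured NPQ induction curves
and keeps qP monotonically non-increasing in PAR on noiseless data, which
the first-order hyperbolic form does not. The default PAR ladder spans
0–1400 µmol m⁻² s⁻¹ and includes the 700 µmol m⁻² s⁻¹ level at which
treatment effects are conventionally read.

**Omics** (`gen_omics_dataset()`): log2-scale simulation with uniform
baselines in [3, 10], planted B-vs-A effects, one latent factor per
transcription factor shared with its targets (signed loadings give the
expected correlation sign), one shared gene–metabolite factor for the
Mantel stage, and Gaussian log2 noise (default σ = 0.25, a mid-range
replicate CV for expression data; recovery tests use σ = 0.1 and 0.01
where the spec of the test demands near-noiseless truth). Values are
returned on the positive linear scale. The generator does not emulate
count-specific mean–variance relationships, missingness, batch effects
or compositionality — so passing screens on synthetic data demonstrate
rule correctness and calibration, not robustness to those real-data
pathologies.

All generators are bit-reproducible under a fixed seed, and the pipeline
writes each artifact's seed into a sidecar metadata file.

## Problem sizes and test design

The test suite runs the statistical checks at sizes chosen to make their
Monte-Carlo error small relative to the asserted bounds while staying
desk-scale: 1000 features for null calibration of the protein rule, 200
planted features for sensitivity, 20 seeds for noisy light-curve
recovery, 200 seeds × 199 permutations for Mantel calibration, and a
20000-point quadrature grid as the S~m~ oracle. The single-number
acceptance script (`scripts/acceptance.R`) regenerates the paired
healthy/impaired transients and reports ΔW~k~.

## Known limitations

* No Q~A~ reoxidation kinetics, OJIP heterogeneity decomposition, or
  photoinhibition terms in the light-curve model.
* The JIP cross-section fluxes inherit the ABS/CS~0~ ≈ F~o~ proxy; they
  are scale-dependent by design and should only be compared within an
  instrument/gain setting.
* VIP is PLS-DA based (see above), and with n = 3 per class its ranking
  is unstable under label permutation — which the tests exploit as a
  sanity check rather than hide.
* The Mantel stage treats samples as exchangeable; designs with nested
  structure would need restricted permutations that are not implemented.
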