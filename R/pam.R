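#' Rapid-light-curve dataset from a PAM fluorometer
#'
#' Holds the dark-adapted reference (`F0`, `Fm`) and one record per actinic
#' light step: incident PAR (µmol photons m^-2 s^-1), steady-state
#' fluorescence `F` and the pulse maximum `Fm'`.
#'
#' @param F0 dark-adapted minimal fluorescence, > 0.
#' @param Fm dark-adapted maximal fluorescence, > `F0`.
#' @param steps data.frame with columns `par`, `f`, `fm_prime`; PAR must be
#'   strictly increasing (the first step may be 0) and each step must have
#'   `fm_prime >= f > 0`.
#' @param label treatment group label.
#' @param meta free-form metadata (the generator stores the true
#'   parameters and seed here).
#' @return an object of class `light_curve_dataset`.
#' @export
light_curve_dataset <- function(F0, Fm, steps, label = NA_character_,
                                meta = list()) {
  stopifnot(is.numeric(F0), length(F0) == 1L,
            is.numeric(Fm), length(Fm) == 1L,
            is.data.frame(steps))
  if (!(Fm > F0 && F0 > 0)) stop("need Fm > F0 > 0", call. = FALSE)
  if (!all(c("par", "f", "fm_prime") %in% names(steps))) {
    stop("steps must have columns par, f, fm_prime", call. = FALSE)
  }
  if (nrow(steps) < 1L) stop("at least one light step required", call. = FALSE)
  if (any(steps$par < 0) || any(diff(steps$par) <= 0)) {
    stop("PAR levels must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  if (any(!(steps$fm_prime >= steps$f & steps$f > 0))) {
    stop("each step needs fm_prime >= f > 0", call. = FALSE)
  }
  structure(list(F0 = F0, Fm = Fm,
                 steps = steps[, c("par", "f", "fm_prime")],
                 label = label, meta = meta),
            class = "light_curve_dataset")
}

#' @export
print.light_curve_dataset <- function(x, ...) {
  cat(sprintf("<light_curve_dataset> %d steps, PAR %g-%g, Fv/Fm %.3f, group %s\n",
              nrow(x$steps), min(x$steps$par), max(x$steps$par),
              (x$Fm - x$F0) / x$Fm, x$label))
  invisible(x)
}

#' Generate a synthetic rapid-light-curve dataset
#'
#' Draws relative electron transport rates from the saturating tanh model
#' `rETR = ETRmax tanh(alpha PAR / ETRmax)` with multiplicative Gaussian
#' noise, then back-computes the fluorescence record so that quenching
#' analysis of the dataset is exactly consistent with the drawn rETR:
#' non-photochemical quenching rises sigmoidally and monotonically with
#' PAR as `NPQ = npq_max PAR^2 / (PAR^2 + Ek^2)` (a Hill response with
#' half-saturation at `Ek`, the usual shape of NPQ induction curves),
#' `Fm' = Fm / (1 + NPQ)`, and `F = Fm' (1 - PhiPSII)` with the operating
#' efficiency implied by the drawn rETR
#' (`PhiPSII = rETR / (PAR * psii_fraction * absorptance)`).
#'
#' @param alpha_true true initial slope (> 0, must satisfy
#'   `alpha_true < absorptance * psii_fraction * fv_fm` so the implied
#'   PhiPSII stays below the dark-adapted yield).
#' @param etrmax_true true maximal rETR (> 0).
#' @param npq_max asymptotic NPQ at saturating light (>= 0).
#' @param par_levels strictly increasing PAR levels; must reach at least
#'   700 µmol photons m^-2 s^-1 so the curve spans the saturating range.
#' @param noise_sd relative noise on rETR (>= 0).
#' @param seed integer seed or `NULL`.
#' @param fv_fm dark-adapted Fv/Fm used for the back-computation.
#' @param Fm dark-adapted maximal fluorescence (arbitrary units).
#' @param absorptance,psii_fraction leaf absorptance and PSII fraction of
#'   absorbed light used in the rETR convention.
#' @param label treatment group label.
#' @return a [light_curve_dataset()] whose `meta$truth` holds the
#'   generating parameters.
#' @export
gen_light_curve_dataset <- function(alpha_true = 0.3, etrmax_true = 60,
                                    npq_max = 1.5,
                                    par_levels = c(0, 25, 50, 100, 200, 400,
                                                   700, 1000, 1400),
                                    noise_sd = 0, seed = NULL,
                                    fv_fm = 0.8, Fm = 4000,
                                    absorptance = 0.84, psii_fraction = 0.5,
                                    label = NA_character_) {
  stopifnot(alpha_true > 0, etrmax_true > 0, npq_max >= 0,
            fv_fm > 0, fv_fm < 1, Fm > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(diff(par_levels) <= 0) || any(par_levels < 0)) {
    stop("PAR levels must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  if (max(par_levels) < 700) {
    stop("PAR levels must include a level >= 700 umol m-2 s-1", call. = FALSE)
  }
  q <- absorptance * psii_fraction
  if (alpha_true / q >= fv_fm) {
    stop("alpha_true too large: implied PhiPSII at low light would exceed Fv/Fm",
         call. = FALSE)
  }
  ek <- etrmax_true / alpha_true
  retr_true <- etrmax_true * tanh(alpha_true * par_levels / etrmax_true)
  retr <- if (noise_sd > 0) {
    with_seed(seed, retr_true *
                (1 + stats::rnorm(length(retr_true), 0, noise_sd)))
  } else {
    retr_true
  }
  retr <- pmax(retr, 0)
  phi <- ifelse(par_levels > 0, retr / (q * par_levels), fv_fm)
  phi <- pmin(phi, 0.999)  # keep F > 0 under extreme noise draws
  npq <- npq_max * par_levels^2 / (par_levels^2 + ek^2)
  F0 <- Fm * (1 - fv_fm)
  fmp <- Fm / (1 + npq)
  f <- fmp * (1 - phi)
  light_curve_dataset(F0 = F0, Fm = Fm,
                      steps = data.frame(par = par_levels, f = f,
                                         fm_prime = fmp),
                      label = label,
                      meta = list(truth = list(alpha = alpha_true,
                                               etrmax = etrmax_true,
                                               ek = ek, npq_max = npq_max,
                                               noise_sd = noise_sd),
                                  seed = seed,
                                  absorptance = absorptance,
                                  psii_fraction = psii_fraction))
}

#' Saturation-pulse quenching parameters per light step
#'
#' Computes, for every light step, the PSII operating efficiency
#' `PhiPSII = (Fm' - F)/Fm'`, non-photochemical quenching
#' `NPQ = (Fm - Fm')/Fm'`, the photochemical quenching coefficient
#' `qP = (Fm' - F)/(Fm' - Fo')` with `Fo'` estimated by the
#' Oxborough-Baker relation `Fo' = F0 / (Fv/Fm + F0/Fm')`, the yield of
#' non-regulated dissipation `Y(NO)` (simplified lake-model form `F/Fm` by
#' default, with the Kramer form `1/(1 + NPQ + qL (Fm/F0 - 1))` as an
#' option) and the relative electron transport rate
#' `rETR = PhiPSII * PAR * psii_fraction * absorptance`.
#'
#' Steps with `Fm' > Fm` yield negative NPQ; they are kept but flagged
#' with a warning.  Steps where `Fm'` collapses onto `Fo'` have undefined
#' `qP` and are reported as `NA` with a flag.
#'
#' @param ds a [light_curve_dataset()].
#' @param absorptance,psii_fraction rETR convention factors (defaults
#'   0.84 and 0.5; overridden by values recorded in `ds$meta`).
#' @param yno_form `"simple"` (`F/Fm`) or `"kramer"`.
#' @return a data.frame with one row per step (`par`, `f`, `fm_prime`,
#'   `fo_prime`, `phi_psii`, `npq`, `qp`, `y_no`, `retr`, `qp_defined`);
#'   the dataset-level `fv_fm` is attached as an attribute.
#' @export
quenching_parameters <- function(ds,
                                 absorptance = NULL, psii_fraction = NULL,
                                 yno_form = c("simple", "kramer")) {
  stopifnot(inherits(ds, "light_curve_dataset"))
  yno_form <- match.arg(yno_form)
  absorptance <- absorptance %||% ds$meta$absorptance %||% 0.84
  psii_fraction <- psii_fraction %||% ds$meta$psii_fraction %||% 0.5
  s <- ds$steps
  fv_fm <- (ds$Fm - ds$F0) / ds$Fm
  if (any(s$fm_prime > ds$Fm)) {
    warning("Fm' exceeds dark-adapted Fm at some steps; NPQ is negative there",
            call. = FALSE)
  }
  phi <- (s$fm_prime - s$f) / s$fm_prime
  npq <- (ds$Fm - s$fm_prime) / s$fm_prime
  fo_p <- ds$F0 / (fv_fm + ds$F0 / s$fm_prime)
  denom <- s$fm_prime - fo_p
  qp_defined <- abs(denom) > .Machine$double.eps^0.5 * ds$Fm
  qp <- ifelse(qp_defined, (s$fm_prime - s$f) / denom, NA_real_)
  y_no <- if (yno_form == "simple") {
    s$f / ds$Fm
  } else {
    ql <- qp * fo_p / s$f
    1 / (1 + npq + ql * (ds$Fm / ds$F0 - 1))
  }
  retr <- phi * s$par * psii_fraction * absorptance
  out <- data.frame(par = s$par, f = s$f, fm_prime = s$fm_prime,
                    fo_prime = fo_p, phi_psii = phi, npq = npq, qp = qp,
                    y_no = y_no, retr = retr, qp_defined = qp_defined,
                    row.names = NULL)
  attr(out, "fv_fm") <- fv_fm
  attr(out, "yno_form") <- yno_form
  out
}

#' Fit the saturating tanh model to a rapid light curve
#'
#' Least-squares fit of `rETR = ETRmax tanh(alpha PAR / ETRmax)` by
#' Levenberg-Marquardt with multi-start initialisation (alpha from the
#' initial slope of the lowest light steps, ETRmax from the largest
#' observed rETR, each perturbed over a small grid); the best converged
#' start by residual sum of squares wins.  The light-saturation parameter
#' is defined as `Ek = ETRmax / alpha` (an identity, not a fit output).
#'
#' @param par PAR levels (>= 4 distinct values required).
#' @param retr relative electron transport rates at those levels.
#' @return an object of class `light_curve_fit`: list with `alpha`,
#'   `etrmax`, `ek`, `rss`, `converged`, `n`.
#' @export
fit_light_curve <- function(par, retr) {
  stopifnot(is.numeric(par), is.numeric(retr), length(par) == length(retr))
  ok <- is.finite(par) & is.finite(retr)
  par <- par[ok]; retr <- retr[ok]
  if (length(unique(par)) < 4L) {
    stop("at least 4 steps with distinct PAR are required", call. = FALSE)
  }
  if (all(retr <= 0)) stop("all rETR values are zero; nothing to fit",
                           call. = FALSE)
  pos <- par > 0 & retr > 0
  alpha0 <- if (any(pos)) max(retr[pos] / par[pos]) else 0.3
  etrmax0 <- max(retr)
  dat <- data.frame(par = par, retr = retr)
  best <- NULL
  for (a0 in alpha0 * c(1, 0.5, 2)) {
    for (e0 in etrmax0 * c(1, 1.5)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(retr ~ etrmax * tanh(alpha * par / etrmax),
                          data = dat,
                          start = list(alpha = a0, etrmax = e0),
                          lower = c(alpha = 1e-9, etrmax = 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) {
        co <- stats::coef(fit)
        best <- list(alpha = unname(co["alpha"]),
                     etrmax = unname(co["etrmax"]), rss = rss)
      }
    }
  }
  if (is.null(best)) {
    stop("light-curve fit failed to converge from all starts", call. = FALSE)
  }
  structure(list(alpha = best$alpha, etrmax = best$etrmax,
                 ek = best$etrmax / best$alpha, rss = best$rss,
                 converged = TRUE, n = length(par)),
            class = "light_curve_fit")
}

#' @export
print.light_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<light_curve_fit> alpha = %.4g, ETRmax = %.4g, Ek = %.4g (rss %.3g, n = %d)\n",
    x$alpha, x$etrmax, x$ek, x$rss, x$n))
  invisible(x)
}
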