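#' Extract the O, K, J, I, P cardinal points of an OJIP transient
#'
#' O is the global minimum of the trace (wherever it occurs), K/J/I are the
#' fluorescence values at exactly 300 µs, 2 ms and 30 ms (interpolated
#' linearly in log-time when not sampled), and P is the global maximum with
#' its time recorded.  The fluorescence of the first recorded sample is
#' also reported (`F_first`) since instruments sometimes define O as the
#' first sample; the global minimum is the primary definition here.
#'
#' @param transient a [fluorescence_transient()].
#' @return an object of class `cardinal_points` with fields `Fo`, `FK`,
#'   `FJ`, `FI`, `Fm`, `t_O`, `t_Fm`, `F_first`.
#' @export
extract_cardinal_points <- function(transient) {
  stopifnot(inherits(transient, "fluorescence_transient"))
  f <- transient$fluorescence
  t <- transient$time
  i_min <- which.min(f)
  i_max <- which.max(f)
  Fo <- f[i_min]
  Fm <- f[i_max]
  if (Fm - Fo <= .Machine$double.eps * max(Fm, 1)) {
    stop("degenerate transient: Fm equals Fo, normalisations are undefined",
         call. = FALSE)
  }
  kji <- interp_logtime(t, f, c(3e-4, 2e-3, 3e-2))
  structure(list(Fo = Fo, FK = kji[1L], FJ = kji[2L], FI = kji[3L],
                 Fm = Fm, t_O = t[i_min], t_Fm = t[i_max],
                 F_first = f[1L]),
            class = "cardinal_points")
}

#' O-point, O-P and O-J standardisations of a transient
#'
#' Computes the three standard normalised curves on the input grid:
#' the relative curve `Ft/Fo`, the O-P relative variable fluorescence
#' `Vt = (Ft - Fo) / (Fm - Fo)` and the O-J relative variable fluorescence
#' `Wt = (Ft - Fo) / (FJ - Fo)`.  By construction `Vt` is 0 at the O point
#' and 1 at the P point, and `Wt` is 1 at the J point (2 ms).
#'
#' @param transient a [fluorescence_transient()].
#' @param points its [extract_cardinal_points()] (recomputed by default).
#' @return an object of class `normalized_curves` with fields `time`,
#'   `rel` (Ft/Fo), `vt`, `wt`, `points`, `label`.
#' @export
normalize_transient <- function(transient,
                                points = extract_cardinal_points(transient)) {
  stopifnot(inherits(transient, "fluorescence_transient"),
            inherits(points, "cardinal_points"))
  if (points$Fm <= points$Fo) {
    stop("Fm must exceed Fo for the O-P standardisation", call. = FALSE)
  }
  if (points$FJ <= points$Fo) {
    stop("FJ must exceed Fo for the O-J standardisation", call. = FALSE)
  }
  f <- transient$fluorescence
  structure(list(time = transient$time,
                 rel = f / points$Fo,
                 vt = (f - points$Fo) / (points$Fm - points$Fo),
                 wt = (f - points$Fo) / (points$FJ - points$Fo),
                 points = points, label = transient$label),
            class = "normalized_curves")
}

#' Treatment-minus-control difference curves and the K-band statistic
#'
#' Re-interpolates the control curves (linearly in log-time) onto the
#' treatment grid restricted to the overlapping time range, then forms
#' `dVt = Vt(treatment) - Vt(control)` and
#' `dWt = Wt(treatment) - Wt(control)`.  The scalar `dWk` is `dWt`
#' evaluated at the K point (300 µs); `dWk > 0` marks a relative K-band
#' rise in the treatment, the fingerprint of donor-side (oxygen-evolving
#' complex) impairment.  The caller chooses which group serves as control.
#'
#' @param treatment,control [normalize_transient()] outputs.
#' @return an object of class `difference_curves` with fields `time`,
#'   `dvt`, `dwt`, `dwk`, `treatment_label`, `control_label`.
#' @export
difference_curves <- function(treatment, control) {
  stopifnot(inherits(treatment, "normalized_curves"),
            inherits(control, "normalized_curves"))
  lo <- max(treatment$time[1L], control$time[1L])
  hi <- min(treatment$time[length(treatment$time)],
            control$time[length(control$time)])
  if (lo >= hi) {
    stop("treatment and control time ranges do not overlap", call. = FALSE)
  }
  keep <- treatment$time >= lo & treatment$time <= hi
  tt <- treatment$time[keep]
  dvt <- treatment$vt[keep] - interp_logtime(control$time, control$vt, tt)
  dwt <- treatment$wt[keep] - interp_logtime(control$time, control$wt, tt)
  dwk <- if (3e-4 >= lo && 3e-4 <= hi) {
    interp_logtime(tt, dwt, 3e-4)
  } else {
    NA_real_
  }
  structure(list(time = tt, dvt = dvt, dwt = dwt, dwk = dwk,
                 treatment_label = treatment$label,
                 control_label = control$label),
            class = "difference_curves")
}

#' Derive the JIP-test parameter set of a transient
#'
#' Computes the standard fast-fluorescence parameters from the cardinal
#' points and normalised curves, following the classical JIP-test
#' formulation:
#' \itemize{
#'   \item `fv_fm` = (Fm - Fo)/Fm, the maximum quantum yield of PSII
#'     photochemistry (phi_P0);
#'   \item `vj`, `vi`: relative variable fluorescence at 2 ms and 30 ms;
#'   \item `wk`: O-J-normalised relative fluorescence at 300 µs;
#'   \item `mo` = 4 (FK - Fo)/(Fm - Fo) per ms, the initial-slope
#'     approximation of the maximal rate of QA reduction (the factor 4 is
#'     1/0.25 ms, the K-point convention);
#'   \item `area`, `sm`: area between Fm and the trace from the O point to
#'     the time of Fm (trapezoid rule on the native grid, in ms), and
#'     `sm = area / (Fm - Fo)`, proportional to the plastoquinone pool;
#'   \item `psi0` = 1 - Vj (probability that a trapped electron moves past
#'     QA), `psie0` = phi_P0 (1 - Vj) (same per absorbed photon);
#'   \item `rc_abs` = phi_P0 Vj / Mo (QA-reducing reaction centers per
#'     absorbed photon), and the composite performance index
#'     `pi_abs = rc_abs * phi_P0/(1 - phi_P0) * psi0/(1 - psi0)`;
#'   \item specific fluxes `tr0_rc = Mo/Vj`, `et0_rc = (Mo/Vj)(1 - Vj)`;
#'   \item cross-section fluxes using the standard proxy ABS/CS0 ~ Fo:
#'     `rc_cs0 = rc_abs * Fo`, `tr0_cs0 = phi_P0 * Fo`,
#'     `et0_cs0 = psie0 * Fo`.
#' }
#' When `Vj` degenerates to 0 or 1 the parameters that divide by `Vj`,
#' `1 - Vj` or `Mo` are reported as `NA` and listed in the `degenerate`
#' attribute instead of aborting the whole set.
#'
#' @param transient a [fluorescence_transient()].
#' @param points its cardinal points (recomputed by default).
#' @param curves its normalised curves (recomputed by default).
#' @return an object of class `jip_parameter_set`; `as.data.frame()` turns
#'   it into a tidy (parameter, value) table.
#' @export
jip_parameters <- function(transient,
                           points = extract_cardinal_points(transient),
                           curves = normalize_transient(transient, points)) {
  stopifnot(inherits(points, "cardinal_points"),
            inherits(curves, "normalized_curves"))
  Fo <- points$Fo; Fm <- points$Fm
  fv_fm <- (Fm - Fo) / Fm
  vj <- interp_logtime(curves$time, curves$vt, 2e-3)
  vi <- interp_logtime(curves$time, curves$vt, 3e-2)
  wk <- interp_logtime(curves$time, curves$wt, 3e-4)
  mo <- 4 * (points$FK - Fo) / (Fm - Fo)           # per ms
  i_o <- which.min(transient$fluorescence)
  i_p <- which.max(transient$fluorescence)
  seg <- i_o:i_p
  area <- if (length(seg) > 1L) {
    tms <- transient$time[seg] * 1e3               # ms
    gap <- Fm - transient$fluorescence[seg]
    sum(diff(tms) * (gap[-length(gap)] + gap[-1L]) / 2)
  } else {
    0
  }
  sm <- area / (Fm - Fo)
  psi0 <- 1 - vj
  psie0 <- fv_fm * psi0
  degenerate <- character(0)
  if (vj <= 0 || vj >= 1 || mo <= 0) {
    rc_abs <- pi_abs <- tr0_rc <- et0_rc <- rc_cs0 <- NA_real_
    degenerate <- c("rc_abs", "pi_abs", "tr0_rc", "et0_rc", "rc_cs0")
  } else {
    rc_abs <- fv_fm * vj / mo
    pi_abs <- rc_abs * fv_fm / (1 - fv_fm) * psi0 / (1 - psi0)
    tr0_rc <- mo / vj
    et0_rc <- mo / vj * psi0
    rc_cs0 <- rc_abs * Fo
  }
  structure(list(fv_fm = fv_fm, vj = vj, vi = vi, wk = wk, mo = mo,
                 area = area, sm = sm, psi0 = psi0, psie0 = psie0,
                 rc_abs = rc_abs, pi_abs = pi_abs,
                 tr0_rc = tr0_rc, et0_rc = et0_rc,
                 rc_cs0 = rc_cs0, tr0_cs0 = fv_fm * Fo,
                 et0_cs0 = psie0 * Fo),
            class = "jip_parameter_set",
            degenerate = degenerate,
            abs_cs0_proxy = "Fo")
}

#' @export
as.data.frame.jip_parameter_set <- function(x, ...) {
  data.frame(parameter = names(unclass(x)),
             value = as.numeric(unlist(unclass(x))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.jip_parameter_set <- function(x, ...) {
  cat("<jip_parameter_set>\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
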