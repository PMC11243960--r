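#' Parameters for the synthetic OJIP transient model
#'
#' Defines a three-exponential fluorescence rise
#' \deqn{F(t) = F_o + (F_m - F_o) \sum_i w_i (1 - e^{-t/\tau_i})}
#' whose three phases emulate the O-J, J-I and I-P steps of a fast
#' chlorophyll fluorescence induction curve.  Donor-side (oxygen-evolving
#' complex) impairment is emulated by injecting an extra ultra-fast phase
#' with weight `k_band_weight` and time constant `k_band_tau`, which raises
#' the relative fluorescence around the K point (300 µs); the remaining
#' phase weights are renormalised by `1 - k_band_weight`.  A reduction of
#' `Fm` can be combined with the injection to emulate the joint K-band
#' rise / Fm drop seen in donor-side damaged leaves.
#'
#' The default time constants (0.4 ms, 10 ms, 120 ms) place the J and I
#' inflections near their defining times (2 ms and 30 ms).
#'
#' @param Fo minimal fluorescence (arbitrary units, > 0).
#' @param Fm maximal fluorescence (> `Fo`).
#' @param phase_weights nonnegative 3-vector (O-J, J-I, I-P), must sum to 1.
#' @param phase_taus strictly increasing 3-vector of time constants in
#'   seconds.
#' @param k_band_weight extra fast-phase weight in `[0, 1)`; 0 = healthy.
#' @param k_band_tau time constant of the injected K phase in seconds.
#' @param noise_sd relative (multiplicative Gaussian) noise level, >= 0.
#' @param seed integer seed used when noise is drawn, or `NULL`.
#' @return an object of class `ojip_model_params`.
#' @seealso [gen_ojip_transient()], [ojip_model_value()]
#' @export
ojip_model_params <- function(Fo = 500, Fm = 2500,
                              phase_weights = c(0.5, 0.3, 0.2),
                              phase_taus = c(4e-4, 1e-2, 0.12),
                              k_band_weight = 0, k_band_tau = 2e-4,
                              noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(Fo), length(Fo) == 1L, Fo > 0,
            is.numeric(Fm), length(Fm) == 1L,
            is.numeric(phase_weights), length(phase_weights) == 3L,
            is.numeric(phase_taus), length(phase_taus) == 3L,
            is.numeric(k_band_weight), length(k_band_weight) == 1L,
            is.numeric(k_band_tau), length(k_band_tau) == 1L, k_band_tau > 0,
            is.numeric(noise_sd), length(noise_sd) == 1L)
  if (Fm <= Fo) stop("Fm must exceed Fo", call. = FALSE)
  if (any(phase_weights < 0)) stop("phase weights must be nonnegative", call. = FALSE)
  if (abs(sum(phase_weights) - 1) > 1e-8) {
    stop("phase weights must sum to 1 (before K-band injection)", call. = FALSE)
  }
  if (any(diff(phase_taus) <= 0) || any(phase_taus <= 0)) {
    stop("phase time constants must be positive and strictly increasing",
         call. = FALSE)
  }
  if (k_band_weight < 0 || k_band_weight >= 1) {
    stop("k_band_weight must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(Fo = Fo, Fm = Fm,
                 phase_weights = phase_weights, phase_taus = phase_taus,
                 k_band_weight = k_band_weight, k_band_tau = k_band_tau,
                 noise_sd = noise_sd, seed = seed),
            class = "ojip_model_params")
}

#' Closed-form value of the noiseless OJIP model
#'
#' Evaluates the deterministic generator model at arbitrary times.  This is
#' the analytic reference used by the parameter-recovery tests: a noiseless
#' generated transient sampled at time `t` equals `ojip_model_value(p, t)`
#' exactly.
#'
#' @param params an [ojip_model_params()] object.
#' @param time vector of times in seconds (>= 0).
#' @return fluorescence values on the model curve.
#' @export
ojip_model_value <- function(params, time) {
  stopifnot(inherits(params, "ojip_model_params"), is.numeric(time),
            all(time >= 0))
  w <- c((1 - params$k_band_weight) * params$phase_weights,
         params$k_band_weight)
  tau <- c(params$phase_taus, params$k_band_tau)
  rise <- (1 - exp(-outer(time, tau, "/"))) %*% w
  as.numeric(params$Fo + (params$Fm - params$Fo) * rise)
}

#' Log-spaced OJIP acquisition grid
#'
#' Log-spaced time grid from `from` to `to` seconds.  By default the K, J
#' and I cardinal times (300 µs, 2 ms, 30 ms) are inserted as exact sample
#' points, mirroring instrument exports that always record those times;
#' with them present, cardinal values of noiseless synthetic transients are
#' sampled rather than interpolated.
#'
#' @param n number of base log-spaced points (>= 50).
#' @param from,to grid limits in seconds, `0 < from < to <= 2`.
#' @param include extra times inserted exactly (set to `NULL` to disable).
#' @return strictly increasing vector of times in seconds.
#' @export
ojip_time_grid <- function(n = 120, from = 1e-5, to = 2,
                           include = c(3e-4, 2e-3, 3e-2)) {
  stopifnot(n >= 50, from > 0, to > from, to <= 2)
  grid <- exp(seq(log(from), log(to), length.out = n))
  if (!is.null(include)) grid <- sort(unique(c(grid, include)))
  grid
}

#' Generate a synthetic OJIP fluorescence transient
#'
#' Samples the closed-form OJIP model on a time grid and applies
#' multiplicative Gaussian noise, `F * (1 + eps)` with
#' `eps ~ N(0, noise_sd)`, drawn under the params' seed so that a fixed
#' seed reproduces the trace bit for bit.
#'
#' @param params an [ojip_model_params()] object.
#' @param grid strictly increasing time grid in seconds, at least 50
#'   points, within `(0, 2]`.
#' @param label treatment group label attached to the transient.
#' @return a [fluorescence_transient()] carrying the generating model in
#'   its `meta` field.
#' @export
gen_ojip_transient <- function(params, grid = ojip_time_grid(), label = "A") {
  stopifnot(inherits(params, "ojip_model_params"))
  if (!is.numeric(grid) || length(grid) < 50L) {
    stop("time grid must be numeric with at least 50 points", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  if (grid[1L] <= 0 || grid[length(grid)] > 2) {
    stop("time grid must lie within (0, 2] seconds", call. = FALSE)
  }
  f <- ojip_model_value(params, grid)
  if (params$noise_sd > 0) {
    f <- with_seed(params$seed,
                   f * (1 + stats::rnorm(length(f), 0, params$noise_sd)))
    f <- pmax(f, 0)
  }
  fluorescence_transient(grid, f, label = label,
                         meta = list(model = params, seed = params$seed))
}
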