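#' Dopaminergic modulation factors of the striatum
#'
#' The input of every striatal unit is the ordinary weighted sum of its
#' afferents multiplied by a dopamine-dependent factor.  For the direct
#' pathway (D1-receptor units) the factor is multiplicative excitatory,
#' `b_strd1 + d_strd1 * a_DA`; for the indirect pathway (D2-receptor units)
#' it is multiplicative inhibitory,
#' `(b_strd1 + d_strd1 * a_DA) / (b_strd2 + d_strd2 * a_DA)` — the D1
#' factor in the numerator carries the combined effect of D1 and D2
#' receptors, the growing denominator the net suppression of the indirect
#' pathway by dopamine.
#'
#' @param a_da Dopamine unit activity (clamped to \[`DA_MIN`, `DA_MAX`\]).
#' @param b_strd1,d_strd1 Baseline and dopamine amplitude of the D1 factor.
#' @param b_strd2,d_strd2 Baseline and dopamine amplitude of the D2
#'   denominator (must keep `b_strd2 + d_strd2 * a_da > 0`).
#' @return The multiplicative factor (vectorised over `a_da`).
#' @name striatal-modulation
#' @examples
#' d1_factor(0.5, b_strd1 = 1, d_strd1 = 2)            # 2
#' d2_factor(1, b_strd1 = 1, d_strd1 = 0, b_strd2 = 1, d_strd2 = 1)  # 0.5
NULL

#' @rdname striatal-modulation
#' @export
d1_factor <- function(a_da, b_strd1, d_strd1) {
  stopifnot(all(a_da >= 0))
  b_strd1 + d_strd1 * a_da
}

#' @rdname striatal-modulation
#' @export
d2_factor <- function(a_da, b_strd1, d_strd1, b_strd2, d_strd2) {
  den <- b_strd2 + d_strd2 * a_da
  if (any(den <= 0))
    stop("non-positive StrD2 dopamine denominator: b_strd2 + d_strd2 * a_DA")
  d1_factor(a_da, b_strd1, d_strd1) / den
}

#' Gaussian input pulse specification
#'
#' A Gaussian-shaped external drive `height * exp(-(t - center)^2 / (2 sd^2))`
#' used both for dopamine bursts and for the cortical inputs that mimic
#' signals from other cortical areas.
#'
#' @param height Pulse height (drive units, `>= 0`).
#' @param sd Pulse standard deviation (s; `> 0` when `height > 0`).
#' @param center Pulse center (s, relative to trial start).
#' @param per_channel_scaling Whether the pulse is independently rescaled by
#'   a Uniform(0, 1) draw for each of the three channels it targets (used
#'   for cortical inputs).
#' @return A `pulse_spec` list.
#' @export
#' @examples
#' pulse_spec(50, 0.020)   # tic-condition dopamine burst
#' pulse_spec(17, 0.250)   # tic-condition cortical input
pulse_spec <- function(height, sd, center = 1, per_channel_scaling = FALSE) {
  if (height < 0) stop("pulse height must be non-negative")
  if (height > 0 && sd <= 0) stop("pulse sd must be positive when height > 0")
  structure(list(height = height, sd = max(sd, .Machine$double.eps),
                 center = center,
                 per_channel_scaling = isTRUE(per_channel_scaling)),
            class = "pulse_spec")
}

#' Evaluate a pulse on a time grid
#'
#' @param spec A [pulse_spec()].
#' @param time Numeric vector of times (s).
#' @return Drive values at `time`.
#' @export
pulse_trace <- function(spec, time) {
  spec$height * exp(-0.5 * ((time - spec$center) / spec$sd)^2)
}

#' Per-channel cortical drive traces
#'
#' Evaluates a cortical pulse for the three motor channels, independently
#' rescaling each channel by a Uniform(0, 1) draw so that the channels
#' receive asymmetric drive (the asymmetry seeds the selection competition).
#'
#' @param spec A [pulse_spec()].
#' @param time Time grid (s).
#' @param scalings Optional fixed scaling triple; by default three fresh
#'   Uniform(0, 1) draws from the current RNG stream.
#' @return A tibble with columns `time_s`, `channel`, `drive` plus a
#'   `"scalings"` attribute.
#' @export
cortical_pulse <- function(spec, time, scalings = NULL) {
  if (is.null(scalings)) scalings <- stats::runif(3)
  base <- pulse_trace(spec, time)
  out <- tidyr::expand_grid(channel = 1:3, time_s = time)
  out$drive <- base[match(out$time_s, time)] * scalings[out$channel]
  attr(out, "scalings") <- scalings
  out
}

#' Dopamine efflux trajectory
#'
#' Simulates the dopamine unit alone: a leaky integrator resting at
#' `DA_MIN`, driven by a Gaussian burst through the input gain `w_da_in`,
#' with its potential hard-clamped to \[`DA_MIN`, `DA_MAX`\].  Under the
#' tic-condition burst (height 50, SD 0.020 s, centered 1 s into the trial)
#' the clamped potential rises from `DA_MIN`, saturates at `DA_MAX = 0.5`
#' near the burst center and decays back toward `DA_MIN`.
#'
#' @param burst A [pulse_spec()] describing the dopamine burst.
#' @param params Parameter vector (uses `tau_da` and `w_da_in`).
#' @param dt Integration step (s).
#' @param horizon Total simulated time (s).
#' @return Tibble with columns `time_s`, `u_da` (clamped potential).
#' @export
#' @examples
#' tr <- da_trajectory(pulse_spec(50, 0.020, center = 1))
#' max(tr$u_da)   # 0.5, reached near t = 1
da_trajectory <- function(burst, params = default_parameters(), dt = 0.001,
                          horizon = 2) {
  if (burst$center > horizon)
    stop("burst center must lie within the simulated horizon")
  n_steps <- round(horizon / dt)
  time <- (seq_len(n_steps) - 1) * dt
  drive <- params[["w_da_in"]] * pulse_trace(burst, time)
  u <- numeric(n_steps)
  u_prev <- DA_MIN
  tau <- params[["tau_da"]]
  for (s in seq_len(n_steps)) {
    u_prev <- u_prev + (dt / tau) * (-u_prev + DA_MIN + drive[s])
    u_prev <- min(max(u_prev, DA_MIN), DA_MAX)
    u[s] <- u_prev
  }
  tibble::tibble(time_s = time + dt, u_da = u)
}
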