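#' Leaky-integrator unit primitives
#'
#' The elementary operations of the rate network.  Each unit carries an
#' activation potential `u` that relaxes toward its input `I` with time
#' constant `tau` (`tau * du/dt = -u + I`), and an activation
#' `a = f(u) = max(0, 400 * tanh(u / 400) - thr)`: a hyperbolic tangent
#' remapped to the range \[-400, 400\] (unity gain near rest, so potentials
#' and firing rates share a scale), shifted by the threshold `thr` and
#' rectified.  Activations are therefore bounded to \[0, 400\].
#'
#' @param u Activation potential(s).
#' @param thr Activation threshold (activity units, `>= 0`).
#' @param r Resting potential of the post-synaptic unit.
#' @param presyn Activities of the pre-synaptic units.
#' @param weights Connection weights, same length as `presyn` (inhibitory
#'   connections carry negative weights).
#' @param noise Noise sample added to the input.
#' @param I Total input drive.
#' @param tau Unit decay constant (s, `> 0`).
#' @param dt Integration step (s, `0 < dt < tau`).
#' @return `activate()`: activation in \[0, 400\].  `unit_input()`: the
#'   drive `r + sum(weights * presyn) + noise`.  `euler_step()`: the
#'   potential advanced by one Euler step.
#' @name dynamics
#' @examples
#' activate(0, 0)          # 0 at rest
#' activate(-5, 10)        # rectification keeps activity at 0
#' unit_input(2, c(1, 3), c(0.5, -1), 0)
#' euler_step(0, 1, tau = 0.01, dt = 0.001)
NULL

#' @rdname dynamics
#' @export
activate <- function(u, thr = 0) {
  if (any(thr < 0)) stop("activation threshold must be non-negative")
  pmax(0, 400 * tanh(u / 400) - thr)
}

#' @rdname dynamics
#' @export
unit_input <- function(r, presyn, weights, noise = 0) {
  if (length(presyn) != length(weights))
    stop("presyn activities and weights must have the same length")
  r + sum(weights * presyn) + noise
}

#' @rdname dynamics
#' @export
euler_step <- function(u, I, tau, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (any(dt >= tau))
    stop("Euler integration unstable: dt must be smaller than tau")
  u + (dt / tau) * (-u + I)
}

#' Advance the whole network by one synchronous Euler step
#'
#' Pure-R reference implementation of the network update: every unit's input
#' is assembled from the activations of the previous step (plus one fresh
#' Gaussian noise draw per unit, taken from R's RNG stream in unit order),
#' the striatal inputs are multiplied by the dopaminergic factors, all
#' potentials are advanced together and activations recomputed.  The
#' compiled simulator ([simulate_circuit()]) performs the identical update;
#' this function exists as its readable, testable reference.
#'
#' @param state List with elements `u` (potentials), `a` (activations) and
#'   `t` (current time, s), as produced by [init_state()].
#' @param network A `tic_network` from [build_network()].
#' @param external External drive vector (one entry per unit; zero where no
#'   external input).
#' @param dt Integration step (s).
#' @return The advanced state (same shape as `state`).
#' @export
step_network <- function(state, network, external = numeric(network$n),
                         dt = network$dt) {
  n <- network$n
  if (length(external) != n)
    stop("external drive must have one entry per unit")
  z <- stats::rnorm(n)
  noise <- network$noise_mean + network$noise_sd * z
  I <- network$r + as.vector(network$W %*% state$a) + noise + external

  has_da <- length(network$da_idx) == 1 && !is.na(network$da_idx)
  if (has_da) {
    a_da <- state$a[network$da_idx]
    f1 <- network$b_d1 + network$d_d1 * a_da
    den <- network$b_d2 + network$d_d2 * a_da
    if (den <= 0) stop("non-positive StrD2 dopamine denominator")
    I[network$d1_idx] <- I[network$d1_idx] * f1
    I[network$d2_idx] <- I[network$d2_idx] * (f1 / den)
  }

  u <- state$u + (dt / network$tau) * (-state$u + I)
  if (has_da)
    u[network$da_idx] <- min(max(u[network$da_idx], network$da_min),
                             network$da_max)
  if (any(!is.finite(u)))
    stop("non-finite activation potential at t = ", state$t)
  a <- activate(u, network$thr)
  if (has_da) a[network$da_idx] <- u[network$da_idx]
  list(u = u, a = a, t = state$t + dt)
}

#' Initial network state
#'
#' All potentials at zero except the dopamine unit, which rests at its
#' floor `DA_MIN`; activations consistent with the potentials.
#'
#' @inheritParams step_network
#' @return State list (`u`, `a`, `t`).
#' @export
init_state <- function(network) {
  u <- numeric(network$n)
  a <- activate(u, network$thr)
  if (length(network$da_idx) == 1 && !is.na(network$da_idx)) {
    u[network$da_idx] <- network$da_min
    a[network$da_idx] <- network$da_min
  }
  list(u = u, a = a, t = 0)
}

#' Simulate the circuit with the compiled core
#'
#' Runs the synchronous Euler integration for `n_steps` steps with a set of
#' Gaussian input pulses, recording unit activations over the requested
#' windows.  Noise is drawn from R's RNG stream, so `set.seed()` before the
#' call makes the run reproducible.
#'
#' @inheritParams step_network
#' @param n_steps Number of integration steps.
#' @param pulses Tibble/data frame with columns `unit` (1-based unit index),
#'   `height`, `sd` (s) and `center` (s): Gaussian drive
#'   `height * exp(-(t - center)^2 / (2 sd^2))` added to that unit's input.
#'   May have zero rows.
#' @param windows Data frame with columns `start` (1-based step) and `length`:
#'   recording windows.
#' @param state Optional starting state (default [init_state()]).
#' @return List with `windows` (list of activation matrices, steps x units,
#'   with unit-name columns), `u_da` (the dopamine unit's potential trace
#'   over the whole run), `u_final` and `a_final`.
#' @export
simulate_circuit <- function(network, n_steps, pulses = NULL, windows = NULL,
                             dt = network$dt, state = init_state(network)) {
  network <- as_tic_network(network)
  if (is.null(pulses) || nrow(pulses) == 0) {
    pm <- matrix(numeric(0), 0, 4)
  } else {
    pm <- cbind(pulses$unit - 1L, pulses$height, pulses$sd, pulses$center)
  }
  if (is.null(windows) || nrow(windows) == 0) {
    wm <- matrix(integer(0), 0, 2)
  } else {
    wm <- cbind(as.integer(windows$start - 1L), as.integer(windows$length))
    if (any(wm[, 1] < 0) || any(wm[, 1] + wm[, 2] > n_steps))
      stop("recording window outside the simulated range")
  }
  out <- .sim_core(network$W, state$u, network$tau, network$r, network$thr,
                   network$noise_mean, network$noise_sd,
                   network$d1_idx - 1L, network$d2_idx - 1L,
                   network$da_idx - 1L,
                   network$b_d1, network$d_d1, network$b_d2, network$d_d2,
                   network$da_min, network$da_max,
                   dt, as.integer(n_steps), pm, wm, TRUE)
  out$windows <- lapply(out$windows, function(m) {
    colnames(m) <- network$unit_names
    m
  })
  out$u_final <- as.vector(out$u_final)
  out$a_final <- as.vector(out$a_final)
  out
}
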