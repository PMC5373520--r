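# Shared fixtures, built in code.

# A bare leaky-integrator network without the dopamine machinery, for
# oracle tests against hand-unrolled scalar updates.
toy_network <- function(W, tau, r, thr = rep(0, nrow(W)),
                        noise_sd = rep(0, nrow(W)),
                        noise_mean = rep(0, nrow(W)), dt = 0.001) {
  n <- nrow(W)
  structure(list(n = n, W = W, tau = tau, r = r, thr = thr,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 d1_idx = integer(0), d2_idx = integer(0),
                 da_idx = integer(0),
                 b_d1 = 0, d_d1 = 0, b_d2 = 1, d_d2 = 0,
                 da_min = DA_MIN, da_max = DA_MAX, dt = dt),
            class = "tic_network")
}

run_steps <- function(network, n_steps, external = numeric(network$n),
                      state = init_state(network), dt = network$dt) {
  for (s in seq_len(n_steps))
    state <- step_network(state, network, external, dt)
  state
}

# The default circuit, built once per test run.
default_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network(default_parameters())
    net
  }
})

# A small labelled cohort shared by analysis tests (6 subjects).
small_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- run_cohort(default_net(), n_subjects = 6,
                                       master_seed = 301)
    co
  }
})

# One tic-condition standalone trial with fixed channel scalings.
tic_trial_fixture <- function(seed = 11, scalings = NULL) {
  set.seed(seed)
  if (is.null(scalings)) scalings <- stats::runif(3)
  cond <- tic_condition()
  ticcircuit:::simulate_trial(default_net(), cond$da_burst,
                              cond$cortical_input, scalings = scalings,
                              lead_in = 1)
}
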