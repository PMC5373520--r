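test_that("activation function is a rectified, thresholded remapped tanh", {
  expect_equal(activate(0, 0), 0)
  expect_equal(activate(-5, 10), 0)          # rectification below threshold
  expect_lt(400 - activate(1e6, 0), 1e-6)    # saturation at 400
  # monotone and bounded over a wide grid
  u <- seq(-2000, 2000, by = 7)
  a <- activate(u, 12)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a <= 400))
  expect_error(activate(0, -1), "non-negative")
})

test_that("unit input is the resting potential plus the weighted sum", {
  expect_equal(unit_input(0, numeric(0), numeric(0)), 0)
  expect_equal(unit_input(2, c(1, 3), c(0.5, -1)), -0.5)
  x <- rnorm(1)
  expect_equal(unit_input(0, x, 1), x)
  expect_error(unit_input(0, 1:3, 1:2), "same length")
  # linearity in activities and in weights (superposition)
  set.seed(1)
  a1 <- runif(5); a2 <- runif(5); w <- rnorm(5)
  expect_equal(unit_input(0, a1 + a2, w),
               unit_input(0, a1, w) + unit_input(0, a2, w))
  w2 <- rnorm(5)
  expect_equal(unit_input(0, a1, w + w2),
               unit_input(0, a1, w) + unit_input(0, a1, w2))
})

test_that("Euler step relaxes the potential toward the drive", {
  expect_equal(euler_step(0, 0, tau = 0.01, dt = 0.001), 0)
  expect_equal(euler_step(0, 1, tau = 0.01, dt = 0.001), 0.1)
  expect_equal(euler_step(3.7, 3.7, tau = 0.05, dt = 0.001), 3.7) # fixed point
  expect_error(euler_step(0, 1, tau = 0.001, dt = 0.001), "unstable")
})

test_that("an isolated noiseless unit converges to its drive", {
  net <- toy_network(W = matrix(0, 1, 1), tau = 0.01, r = 0)
  I <- 2.5
  st <- run_steps(net, round(20 * 0.01 / 0.001), external = I)
  expect_lt(abs(st$u - I), 1e-6)
})

test_that("activations stay within [0, 400] even under strong self-excitation", {
  net <- toy_network(W = matrix(3, 1, 1), tau = 0.01, r = 10)
  st <- init_state(net)
  for (s in 1:10000) {
    st <- step_network(st, net, external = 0)
    expect_true(st$a >= 0 && st$a <= 400)
  }
  expect_gt(st$a, 390)  # saturated, not divergent
})

test_that("network step matches a hand-unrolled scalar update for 100 steps", {
  # 3 units: 1 excites 2, 2 inhibits 3, 3 excites 1; mixed taus/thresholds
  W <- rbind(c(0, 0, 0.8),
             c(1.2, 0, 0),
             c(0, -0.9, 0))
  tau <- c(0.01, 0.02, 0.015)
  r <- c(5, -2, 3)
  thr <- c(0, 1, 2)
  nm <- c(0.5, 0, -0.3)
  ns <- c(2, 1, 0)
  dt <- 0.001
  net <- toy_network(W, tau, r, thr, noise_sd = ns, noise_mean = nm, dt = dt)

  set.seed(99)
  st <- init_state(net)
  for (k in 1:100) st <- step_network(st, net, external = c(1, 0, 0))

  # independent scalar implementation of the same equations
  f <- function(u, th) max(0, 400 * tanh(u / 400) - th)
  set.seed(99)
  u <- c(0, 0, 0); a <- vapply(1:3, function(i) f(u[i], thr[i]), 0)
  for (k in 1:100) {
    z <- rnorm(3)
    I1 <- r[1] + 0.8 * a[3] + nm[1] + ns[1] * z[1] + 1
    I2 <- r[2] + 1.2 * a[1] + nm[2] + ns[2] * z[2]
    I3 <- r[3] - 0.9 * a[2] + nm[3] + ns[3] * z[3]
    u <- c(u[1] + dt / tau[1] * (-u[1] + I1),
           u[2] + dt / tau[2] * (-u[2] + I2),
           u[3] + dt / tau[3] * (-u[3] + I3))
    a <- vapply(1:3, function(i) f(u[i], thr[i]), 0)
  }
  expect_lt(max(abs(st$u - u)), 1e-12)
  expect_lt(max(abs(st$a - a)), 1e-12)
})

test_that("compiled simulator agrees with the R reference on the full circuit", {
  net <- default_net()
  n_steps <- 60
  set.seed(7)
  out <- simulate_circuit(net, n_steps = n_steps,
                          windows = data.frame(start = n_steps, length = 1))
  set.seed(7)
  st <- run_steps(net, n_steps)
  expect_lt(max(abs(out$windows[[1]][1, ] - st$a)), 1e-10)
  expect_lt(max(abs(out$u_final - st$u)), 1e-10)
})

test_that("identical seeds give bitwise-identical simulations", {
  net <- default_net()
  run <- function() {
    set.seed(123)
    simulate_circuit(net, 200, windows = data.frame(start = 1, length = 200))
  }
  expect_identical(run()$windows[[1]], run()$windows[[1]])
})

test_that("a quiescent, noiseless network relaxes to zero activity", {
  p <- default_parameters()
  p[startsWith(names(p), "sd_")] <- 0
  p[startsWith(names(p), "r_")] <- 0
  p["r_pc"] <- 0
  net <- build_network(p)
  out <- simulate_circuit(net, 500,
                          windows = data.frame(start = 500, length = 1))
  a <- out$windows[[1]][1, ]
  a <- a[-net$da_idx]  # DA rests at its floor by construction
  expect_lt(max(abs(a)), 1e-6)
})
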