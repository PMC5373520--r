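test_that("the assembled circuit has the expected composition", {
  net <- default_net()
  counts <- setNames(net$layout$n_units, net$layout$component)
  expect_equal(unname(counts[c("StrD1", "StrD2", "STN", "GPe", "GPi")]),
               rep(3L, 5))
  expect_equal(unname(counts[c("ThBC", "ThC", "M1", "MF", "PC", "DN")]),
               rep(3L, 6))
  expect_equal(unname(counts["GC"]), 100L)
  expect_equal(unname(counts[c("GO", "DA")]), c(1L, 1L))
  expect_equal(net$n, 135L)
  # noiseless cerebellar layers
  quiet <- unlist(net$idx[c("GC", "GO", "PC", "DN")])
  expect_true(all(net$noise_sd[quiet] == 0))
})

test_that("connection signs follow transmitter type", {
  net <- default_net()
  gabaergic <- list(c("StrD1", "GPi"), c("StrD2", "GPe"), c("GPe", "GPi"),
                    c("GPe", "STN"), c("GPi", "ThBC"), c("GO", "GC"),
                    c("PC", "DN"))
  for (con in gabaergic) {
    block <- net$W[net$idx[[con[2]]], net$idx[[con[1]]], drop = FALSE]
    expect_true(all(block <= 0), info = paste(con, collapse = "->"))
    expect_true(any(block < 0), info = paste(con, collapse = "->"))
  }
  glut <- list(c("M1", "StrD1"), c("STN", "GPi"), c("STN", "GPe"),
               c("ThBC", "M1"), c("DN", "ThBC"), c("MF", "GC"))
  for (con in glut) {
    block <- net$W[net$idx[[con[2]]], net$idx[[con[1]]], drop = FALSE]
    expect_true(all(block >= 0), info = paste(con, collapse = "->"))
    expect_true(any(block > 0), info = paste(con, collapse = "->"))
  }
  # one-to-one channel links are diagonal; STN projects diffusely
  blk <- net$W[net$idx$GPi, net$idx$StrD1]
  expect_true(all(blk[row(blk) != col(blk)] == 0))
  blk_stn <- net$W[net$idx$GPi, net$idx$STN]
  expect_true(all(blk_stn > 0))
})

test_that("incomplete parameter vectors are rejected", {
  p <- default_parameters()
  expect_error(build_network(p[setdiff(names(p), "w_stn_mf")]),
               "w_stn_mf")
  p2 <- p; p2["tau_m1"] <- 0.0005
  expect_error(build_network(p2), "unstable")
  p3 <- c(p, bogus = 1)
  expect_error(build_network(p3), "unknown")
})

test_that("parameters round-trip through JSON", {
  p <- default_parameters()
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  expect_equal(read_params(path), p)
})

test_that("striatal dopamine factors behave as multiplicative excitatory / inhibitory", {
  expect_equal(d1_factor(0, b_strd1 = 0.7, d_strd1 = 3), 0.7)
  expect_equal(d1_factor(123, b_strd1 = 0.7, d_strd1 = 0), 0.7)
  expect_equal(d1_factor(0.5, b_strd1 = 1, d_strd1 = 2), 2)
  expect_equal(d2_factor(1, 1, 0, 1, 1), 0.5)
  expect_equal(d2_factor(0, 1.3, 2, 0.5, 10), 1.3 / 0.5)
  # inhibitory direction: decreasing in dopamine when the D2 term dominates
  a <- seq(0, 0.5, by = 0.01)
  f <- d2_factor(a, b_strd1 = 1, d_strd1 = 0, b_strd2 = 0.5, d_strd2 = 20)
  expect_true(all(diff(f) < 0))
  expect_error(d2_factor(1, 1, 1, b_strd2 = -2, d_strd2 = 1), "denominator")
})

test_that("dopamine trajectory is clamped, peaks at the burst and decays", {
  flat <- da_trajectory(pulse_spec(0, 0.02, center = 1))
  expect_true(all(flat$u_da == DA_MIN))

  tr <- da_trajectory(pulse_spec(50, 0.020, center = 1))
  expect_equal(max(tr$u_da), DA_MAX)
  expect_lt(abs(tr$time_s[which.max(tr$u_da)] - 1), 0.1)
  expect_true(all(tr$u_da >= DA_MIN & tr$u_da <= DA_MAX))
  # non-increasing after the peak window of a single burst
  post <- tr$u_da[tr$time_s > 1.1]
  expect_true(all(diff(post) <= 1e-12))
  expect_lt(tail(tr$u_da, 1), 0.05)  # decays back toward the floor
})

test_that("cortical pulses are independently rescaled per channel", {
  time <- seq(0, 2, by = 0.001)
  zero <- cortical_pulse(pulse_spec(0, 0.04), time, scalings = runif(3))
  expect_true(all(zero$drive == 0))

  set.seed(5)
  cp1 <- cortical_pulse(pulse_spec(30, 0.040, center = 1), time)
  set.seed(5)
  cp2 <- cortical_pulse(pulse_spec(30, 0.040, center = 1), time)
  expect_identical(cp1$drive, cp2$drive)

  sums <- tapply(cp1$drive, cp1$channel, sum)
  expect_equal(length(unique(round(sums, 6))), 3)  # distinct integrals
  expect_true(all(cp1$drive <= 30))
})

test_that("hand-set granule-to-Purkinje weights encode selectability", {
  w <- set_gc_pc_weights(selectable = 1, w_gc_pc = 0.5)
  expect_true(all(w[, 1] == 0))
  expect_true(all(w[, 2:3] == 0.5))
  expect_error(set_gc_pc_weights(selectable = c(1, 4)), "subset")

  # MF silent: PC spontaneously active on all channels, DN silent
  net <- build_network(default_parameters(), selectable = 1:3)
  out <- simulate_circuit(net, 800,
                          windows = data.frame(start = 701, length = 100))
  a <- colMeans(out$windows[[1]])
  expect_true(all(a[net$idx$PC] > 20))
  expect_true(all(a[net$idx$DN] < 5))
})

test_that("no channel selectable keeps the dentate silent under mossy input", {
  net <- build_network(default_parameters(), selectable = integer(0))
  set.seed(3)
  cond <- tic_condition()
  tr <- ticcircuit:::simulate_trial(net, cond$da_burst, cond$cortical_input,
                                    scalings = c(0.9, 0.8, 0.7), lead_in = 1)
  dn <- tr$traces[, grep("^DN_", colnames(tr$traces))]
  pc <- tr$traces[, grep("^PC_", colnames(tr$traces))]
  # Purkinje inhibition (granule-driven) dominates: DN stays near zero
  expect_lt(max(colMeans(dn)), 5)
  expect_gt(max(pc), 50)
})

test_that("disinhibition chain: striatal drive releases the thalamus", {
  # frozen inputs, no noise: raising StrD1 on channel 1 lowers GPi_1 and
  # raises ThBC_1 monotonically
  p <- default_parameters()
  p[startsWith(names(p), "sd_")] <- 0
  net <- build_network(p)
  probe <- function(drive) {
    ext <- numeric(net$n)
    ext[net$idx$StrD1[1]] <- drive
    st <- run_steps(net, 600, external = ext)
    c(gpi = st$a[net$idx$GPi[1]], thbc = st$a[net$idx$ThBC[1]])
  }
  res <- vapply(c(0, 40, 120, 400), probe, numeric(2))
  expect_true(all(diff(res["gpi", ]) <= 1e-8))
  expect_lt(res["gpi", 4], res["gpi", 1] - 50)
  expect_true(all(diff(res["thbc", ]) >= -1e-8))
  # STN perturbation reaches every pallidal unit (diffuse projection)
  ext <- numeric(net$n); ext[net$idx$STN[2]] <- 100
  st0 <- run_steps(net, 600)
  st1 <- run_steps(net, 600, external = ext)
  expect_true(all(st1$u[net$idx$GPi] > st0$u[net$idx$GPi]))
  expect_true(all(st1$u[net$idx$GPe] > st0$u[net$idx$GPe]))
})

test_that("connection table matches declared weights and exports cleanly", {
  net <- default_net()
  tbl <- connection_table(net)
  expect_true(all(c("pre", "post", "topology", "sign", "weight", "value")
                  %in% names(tbl)))
  expect_equal(tbl$value[tbl$pre == "GPi" & tbl$post == "ThBC"],
               unname(default_parameters()["w_gpi_thbc"]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_connections(net, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tbl))
})
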