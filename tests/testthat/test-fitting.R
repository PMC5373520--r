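test_that("fitting error is normalised, self-consistent and bounded", {
  target <- make_reference_traces(default_parameters(), seed = 5)
  expect_true(all(c("area", "state", "time_s", "activity") %in% names(target)))
  expect_setequal(unique(target$state), c("TIC", "NO-TIC"))

  err_self <- fit_error(default_parameters(), target, seed = 5)
  expect_lt(err_self, 1e-6)   # self-match under common random numbers

  # all-zero prediction scores (near) the worst possible error
  p0 <- default_parameters()
  p0[startsWith(names(p0), "r_")] <- 0
  p0[startsWith(names(p0), "sd_")] <- 0
  p0[startsWith(names(p0), "w_")] <- 0
  p0["w_da_in"] <- 0.05
  err0 <- fit_error(p0, target, seed = 5)
  expect_gt(err0, 0.5)
  expect_lt(err0, 1)

  # identifiability: a visibly perturbed circuit scores worse than the truth
  pert <- default_parameters()
  pert["w_thbc_m1"] <- 2.0
  pert["r_gpi"] <- 180
  expect_gt(fit_error(pert, target, seed = 5), err_self)
})

test_that("reference traces round-trip through CSV", {
  target <- make_reference_traces(default_parameters(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(target, path)
  back <- read_traces(path)
  expect_equal(back$activity, target$activity)
  expect_equal(back$time_s, round(target$time_s, 6))
  expect_equal(back$area, target$area)
})

test_that("genetic fit is elitist, reproducible and archive-complete", {
  target <- make_reference_traces(default_parameters(), seed = 5)
  ga <- ga_config(population_size = 6, n_generations = 3, seed = 2,
                  stop_error = 0)  # never stop early
  fit <- genetic_fit(target, ga = ga, fit_names = c("w_thbc_m1", "r_gpi"),
                     eval_seed = 5)
  expect_equal(nrow(fit$archive), 18)         # every evaluation archived
  expect_true(all(fit$archive$error > 0 & fit$archive$error < 1))
  expect_true(all(diff(fit$generations$best_error) <= 0))  # elitism

  fit2 <- genetic_fit(target, ga = ga, fit_names = c("w_thbc_m1", "r_gpi"),
                      eval_seed = 5)
  expect_identical(fit$best_error, fit2$best_error)
  expect_identical(fit$archive, fit2$archive)

  b <- parameter_bounds()
  for (nm in fit$fit_names) {
    bi <- b[b$parameter == nm, ]
    expect_true(all(fit$archive[[nm]] >= bi$lower &
                    fit$archive[[nm]] <= bi$upper))
  }
})

test_that("with no mutation or crossover the GA only reselects its founders", {
  target <- make_reference_traces(default_parameters(), seed = 5)
  ga <- ga_config(population_size = 5, n_generations = 3, seed = 9,
                  mutation_prob = 0, crossover_rate = 0, stop_error = 0)
  fit <- genetic_fit(target, ga = ga, fit_names = c("w_thbc_m1", "r_gpi"),
                     eval_seed = 5)
  founders <- unique(round(fit$archive$w_thbc_m1[1:5], 12))
  later <- unique(round(fit$archive$w_thbc_m1[-(1:5)], 12))
  expect_true(all(later %in% founders))
})

test_that("sensitivity ranks low-variance parameters as most influential", {
  set.seed(6)
  n <- 200
  archive <- tibble::tibble(
    generation = rep(1, n),
    error = runif(n, 0.01, 0.99),
    w_thbc_m1 = 2.0,                            # pinned everywhere
    r_gpi = runif(n, -100, 250),                # error-irrelevant, diffuse
    w_m1_thbc = 4 * pmin(1, pmax(0, error + rnorm(n, 0, 0.05)))
  )
  out <- sensitivity(archive)
  expect_equal(out$parameter[1], "w_thbc_m1")
  expect_equal(out$sd_norm[1], 0)
  expect_equal(out$parameter[3], "r_gpi")       # largest normalised spread
  # a parameter uniform over its bounds has sd near that of Uniform(0,1)
  expect_equal(out$sd_norm[out$parameter == "r_gpi"], sqrt(1 / 12),
               tolerance = 0.15)
  # permutation invariance
  out2 <- sensitivity(archive[sample(n), ])
  expect_equal(out, out2)
  expect_error(sensitivity(archive[1:4, ]), "too small")
})
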