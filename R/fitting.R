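#' Reference firing-rate curves from known parameters
#'
#' Simulates one tic-condition and one no-tic-condition trial with the
#' given parameters and returns the pooled-area mean activity traces as a
#' fitting target.  This surrogate generator stands in for empirical
#' reference curves and makes closed-loop parameter-recovery experiments
#' possible without external data (the `state` column names the input
#' condition, not a classification outcome).
#'
#' @param params Named parameter vector.
#' @param seed Integer seed (noise and channel scalings).
#' @param lead_in Settling time before the monitored window (s).
#' @return A `FitTarget` tibble with columns `area`, `state` (`"TIC"` /
#'   `"NO-TIC"` condition), `time_s`, `activity`.
#' @export
make_reference_traces <- function(params, seed = 1L, lead_in = 1) {
  network <- as_tic_network(params)
  conds <- list(`TIC` = tic_condition(), `NO-TIC` = no_tic_condition())
  purrr::imap_dfr(conds, function(cond, nm) {
    set.seed(seed)
    sc <- stats::runif(3)
    tr <- simulate_trial(network, cond$da_burst, cond$cortical_input,
                         scalings = sc, lead_in = lead_in)
    am <- area_trace_matrix(tr$traces)
    tibble::tibble(
      area = rep(colnames(am), each = nrow(am)),
      state = nm,
      time_s = rep(seq_len(nrow(am)) * tr$dt, times = ncol(am)),
      activity = as.vector(am)
    )
  })
}

#' Normalised fitting error
#'
#' Simulates the tic- and no-tic-condition trials under `params` with a
#' fixed seed (common random numbers, so the objective is deterministic)
#' and returns the mean squared error between the simulated and target
#' pooled-area traces, normalised to (0, 1) by the MSE of an all-zero
#' prediction and clipped away from the boundaries.  Numerical failures in
#' the simulation score the worst possible error.
#'
#' @param params Named parameter vector (a full vector; see
#'   [genetic_fit()] for fitting a subset).
#' @param target A `FitTarget` tibble from [make_reference_traces()] or
#'   [read_traces()].
#' @param seed Evaluation seed (common random numbers).
#' @return Error in (0, 1).
#' @export
fit_error <- function(params, target, seed = 1L) {
  if (nrow(target) == 0) stop("empty fitting target")
  sim <- try(make_reference_traces(params, seed = seed), silent = TRUE)
  if (inherits(sim, "try-error")) return(1 - 1e-8)
  key <- paste(target$area, target$state, round(target$time_s, 6))
  sim_key <- paste(sim$area, sim$state, round(sim$time_s, 6))
  m <- match(key, sim_key)
  if (any(is.na(m)))
    stop("target grid does not align with the simulation grid")
  mse <- mean((sim$activity[m] - target$activity)^2)
  baseline <- mean(target$activity^2)
  if (baseline == 0) stop("degenerate all-zero fitting target")
  min(max(mse / baseline, 1e-8), 1 - 1e-8)
}

#' Genetic-algorithm configuration
#'
#' Operator presets for [genetic_fit()]: tournament selection (size 3),
#' blend crossover, bounded Gaussian mutation with SD equal to a fraction
#' of each parameter's bound range, and elitism.  The full-scale preset
#' explores roughly 2500 candidates over 300 generations; the test-scale
#' preset (population 20, 50 generations) is used for parameter-recovery
#' experiments.
#'
#' @param population_size Candidates per generation (`>= 2`).
#' @param n_generations Number of generations.
#' @param mutation_sd Mutation SD as a fraction of each bound range.
#' @param mutation_prob Per-gene mutation probability.
#' @param crossover_rate Probability that a pair is blended.
#' @param blend_alpha Blend-crossover expansion factor.
#' @param tournament_size Tournament size for selection.
#' @param elitism_count Elites copied unchanged (`>= 1`).
#' @param stop_error Stop early when the best error falls below this.
#' @param seed GA seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 20, n_generations = 50,
                      mutation_sd = 0.05, mutation_prob = 0.25,
                      crossover_rate = 0.9, blend_alpha = 0.5,
                      tournament_size = 3, elitism_count = 1,
                      stop_error = 0.08, seed = 1L) {
  stopifnot(population_size >= 2, n_generations >= 1, elitism_count >= 1,
            elitism_count < population_size)
  structure(list(population_size = population_size,
                 n_generations = n_generations,
                 mutation_sd = mutation_sd, mutation_prob = mutation_prob,
                 crossover_rate = crossover_rate, blend_alpha = blend_alpha,
                 tournament_size = tournament_size,
                 elitism_count = elitism_count,
                 stop_error = stop_error, seed = seed),
            class = "ga_config")
}

#' Fit the starred parameters with a genetic algorithm
#'
#' Minimises [fit_error()] over the fitted parameter subset within the
#' declared bounds.  Every evaluation (parameter vector and error) is
#' appended to an archive for the later [sensitivity()] analysis; elitism
#' makes the per-generation best error non-increasing.
#'
#' @param target Fitting target ([make_reference_traces()] /
#'   [read_traces()]).
#' @param ga A [ga_config()].
#' @param base_params Full parameter vector supplying the non-fitted
#'   values.
#' @param fit_names Names of the parameters to fit (default:
#'   [starred_parameters()]).
#' @param eval_seed Seed passed to every [fit_error()] evaluation (common
#'   random numbers).
#' @return A `tic_fit`: `best_params` (full vector), `best_error`,
#'   `archive` tibble (one row per evaluation: generation, the fitted
#'   parameter values, `error`), `generations` tibble (per-generation best
#'   error), `bounds`, `fit_names`.
#' @export
genetic_fit <- function(target, ga = ga_config(),
                        base_params = default_parameters(),
                        fit_names = starred_parameters(),
                        eval_seed = 1L) {
  bounds <- parameter_bounds(base_params)
  b <- bounds[match(fit_names, bounds$parameter), ]
  if (any(is.na(b$parameter))) stop("unknown fitted parameter name")
  if (any(!is.finite(b$lower)) || any(!is.finite(b$upper)))
    stop("fitted parameters need finite bounds")
  lo <- b$lower; hi <- b$upper; rng <- hi - lo
  d <- length(fit_names)

  evaluate <- function(x) {
    p <- base_params
    p[fit_names] <- x
    err <- try(fit_error(p, target, seed = eval_seed), silent = TRUE)
    if (inherits(err, "try-error")) 1 - 1e-8 else err
  }

  set.seed(ga$seed)
  pop <- matrix(stats::runif(ga$population_size * d, lo, hi),
                ga$population_size, d, byrow = TRUE)
  archive <- list()
  gen_best <- numeric(0)
  best_x <- NULL
  best_err <- Inf

  for (g in seq_len(ga$n_generations)) {
    errs <- apply(pop, 1, evaluate)
    archive[[g]] <- tibble::as_tibble(as.data.frame(pop)) |>
      stats::setNames(fit_names) |>
      dplyr::mutate(generation = g, error = errs, .before = 1)
    if (min(errs) < best_err) {
      best_err <- min(errs)
      best_x <- pop[which.min(errs), ]
    }
    gen_best[g] <- best_err
    if (best_err < ga$stop_error) break
    if (g == ga$n_generations) break

    ord <- order(errs)
    elites <- pop[ord[seq_len(ga$elitism_count)], , drop = FALSE]
    tournament <- function() {
      cand <- sample.int(ga$population_size, ga$tournament_size)
      pop[cand[which.min(errs[cand])], ]
    }
    n_children <- ga$population_size - ga$elitism_count
    children <- matrix(0, n_children, d)
    for (i in seq_len(n_children)) {
      p1 <- tournament(); p2 <- tournament()
      child <- if (stats::runif(1) < ga$crossover_rate) {
        # blend (BLX-alpha) crossover, gene-wise
        cmin <- pmin(p1, p2); cmax <- pmax(p1, p2)
        span <- cmax - cmin
        stats::runif(d, cmin - ga$blend_alpha * span,
                     cmax + ga$blend_alpha * span)
      } else p1
      mutate_mask <- stats::runif(d) < ga$mutation_prob
      child[mutate_mask] <- child[mutate_mask] +
        stats::rnorm(sum(mutate_mask), 0,
                     ga$mutation_sd * rng[mutate_mask])
      children[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- rbind(elites, children)
  }

  best_params <- base_params
  best_params[fit_names] <- best_x
  structure(list(best_params = best_params, best_error = best_err,
                 archive = dplyr::bind_rows(archive),
                 generations = tibble::tibble(generation = seq_along(gen_best),
                                              best_error = gen_best),
                 bounds = b, fit_names = fit_names, ga = ga),
            class = "tic_fit")
}

#' @export
print.tic_fit <- function(x, ...) {
  cat("<tic_fit> ", length(x$fit_names), " fitted parameters, ",
      nrow(x$archive), " evaluations, best error ",
      signif(x$best_error, 4), "\n", sep = "")
  invisible(x)
}

#' First-quartile sensitivity analysis over a fitting archive
#'
#' Restricts the archive to the evaluations whose error lies within the
#' first quartile of all archived errors, min-max normalises every fitted
#' parameter to \[0, 1\] over its declared bounds, and ranks parameters by
#' the standard deviation of their normalised values, ascending: a small
#' standard deviation among well-fitting parameter sets indicates a
#' parameter with great influence on the model behaviour (poorly fitting
#' values of it were discarded by selection).
#'
#' @param archive Evaluation archive (tibble with an `error` column and
#'   one column per fitted parameter), e.g. `fit$archive`.
#' @param bounds Bounds tibble (`parameter`, `lower`, `upper`); defaults
#'   to the declared [parameter_bounds()].
#' @return Tibble with columns `parameter`, `sd_norm`, `n_selected`,
#'   ranked ascending by `sd_norm` (most influential first).
#' @export
sensitivity <- function(archive, bounds = parameter_bounds()) {
  if (nrow(archive) < 8) stop("archive too small for a quartile analysis")
  pars <- setdiff(names(archive), c("generation", "error"))
  q1 <- stats::quantile(archive$error, 0.25, names = FALSE)
  sel <- archive[archive$error <= q1, , drop = FALSE]
  if (nrow(sel) == nrow(archive))
    warning("all archived errors are equal; quartile filter selects everything")
  out <- purrr::map_dfr(pars, function(p) {
    bi <- bounds[bounds$parameter == p, ]
    if (nrow(bi) != 1) stop("no bounds declared for parameter ", p)
    z <- (sel[[p]] - bi$lower) / (bi$upper - bi$lower)
    tibble::tibble(parameter = p, sd_norm = stats::sd(z),
                   n_selected = nrow(sel))
  })
  dplyr::arrange(out, .data$sd_norm)
}
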