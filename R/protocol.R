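#' Session configuration
#'
#' The simulated-subject protocol: a continuous 90-s run integrated at
#' `dt = 0.001` s, with 10 monitored trial windows of 2 s (2000 steps)
#' separated by 7-s gaps (so that the activity of one trial cannot
#' influence the next).  Within each trial a dopamine burst is applied 1 s
#' after trial start together with a cortical input pulse; a trial is
#' labelled TIC when the time-averaged activity of some M1 unit exceeds the
#' classification threshold of 40.
#'
#' @param dt Integration step (s).
#' @param session_length Total simulated time per subject (s).
#' @param n_trials Number of monitored trial windows.
#' @param trial_length Trial window length (s).
#' @param inter_trial_gap Gap between consecutive trial windows (s).
#' @param first_trial_at Start of the first trial window (s); the initial
#'   seconds let the circuit settle to its noisy baseline.
#' @param da_burst [pulse_spec()] of the dopamine burst (tic condition:
#'   height 50, SD 0.020 s, centered 1 s into the trial).
#' @param cortical_input [pulse_spec()] of the cortical drive to M1 (tic
#'   condition: height 17, SD 0.250 s), independently rescaled by
#'   Uniform(0, 1) per channel.
#' @param tic_threshold Classification threshold on the time-averaged M1
#'   unit activity (strictly above = TIC).
#' @return A validated `session_config` list.
#' @export
session_config <- function(dt = 0.001,
                           session_length = 90,
                           n_trials = 10,
                           trial_length = 2,
                           inter_trial_gap = 7,
                           first_trial_at = 4,
                           da_burst = pulse_spec(50, 0.020, center = 1),
                           cortical_input = pulse_spec(17, 0.250, center = 1,
                                                       per_channel_scaling = TRUE),
                           tic_threshold = 40) {
  cfg <- structure(list(dt = dt, session_length = session_length,
                        n_trials = n_trials, trial_length = trial_length,
                        inter_trial_gap = inter_trial_gap,
                        first_trial_at = first_trial_at,
                        da_burst = da_burst, cortical_input = cortical_input,
                        tic_threshold = tic_threshold),
                   class = "session_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  need <- c("dt", "session_length", "n_trials", "trial_length",
            "inter_trial_gap", "first_trial_at", "da_burst",
            "cortical_input", "tic_threshold")
  for (f in need) {
    if (is.null(cfg[[f]])) stop("session config is missing field `", f, "`")
  }
  span <- cfg$first_trial_at + cfg$n_trials * cfg$trial_length +
    (cfg$n_trials - 1) * cfg$inter_trial_gap
  if (span > cfg$session_length)
    stop("trial windows (", span, " s) do not fit in the session (",
         cfg$session_length, " s)")
  steps <- cfg$trial_length / cfg$dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("trial_length must be an integer number of steps")
  cfg
}

#' Tic- and no-tic-condition input magnitudes
#'
#' The two input regimes used to reproduce the reference firing-rate
#' curves: in the tic condition the dopamine burst is tall and brief
#' (height 50, SD 0.020 s) and the cortical input low and sustained
#' (height 17, SD 0.250 s); in the no-tic condition the dopamine burst is
#' negligible (height 1, SD 0.600 s) and the cortical input brief
#' (height 30, SD 0.040 s).
#'
#' @return A list with elements `da_burst` and `cortical_input`.
#' @name conditions
#' @export
tic_condition <- function() {
  list(da_burst = pulse_spec(50, 0.020, center = 1),
       cortical_input = pulse_spec(17, 0.250, center = 1,
                                   per_channel_scaling = TRUE))
}

#' @rdname conditions
#' @export
no_tic_condition <- function() {
  list(da_burst = pulse_spec(1, 0.600, center = 1),
       cortical_input = pulse_spec(30, 0.040, center = 1,
                                   per_channel_scaling = TRUE))
}

# Map unit-name columns of a trace matrix to pooled recording areas.
area_indices <- function(unit_names) {
  comp <- sub("_[0-9]+$", "", unit_names)
  list(
    DorsalPutamen = which(comp %in% c("StrD1", "StrD2")),
    GPe = which(comp == "GPe"),
    GPi = which(comp == "GPi"),
    STN = which(comp == "STN"),
    Th = which(comp %in% c("ThBC", "ThC")),
    M1 = which(comp == "M1"),
    CbllCx = which(comp %in% c("GC", "PC")),
    DA = which(comp == "DA")
  )
}

#' Monitored recording areas
#'
#' The pooled areas reported by the analyses: Dorsal putamen (StrD1 +
#' StrD2), GPe, GPi (GPi/SNr), STN, Th (ThBC + ThC), M1 and CbllCx
#' (granule + Purkinje layers, the model's cerebellar cortex).
#'
#' @param include_da Include the dopamine unit as an area.
#' @return Character vector of area names.
#' @export
areas <- function(include_da = FALSE) {
  a <- c("DorsalPutamen", "GPe", "GPi", "STN", "Th", "M1", "CbllCx")
  if (include_da) c(a, "DA") else a
}

# Across-unit mean activity trace per pooled area: steps x areas matrix.
area_trace_matrix <- function(traces, include_da = FALSE) {
  idx <- area_indices(colnames(traces))
  keep <- areas(include_da)
  out <- vapply(keep, function(a) rowMeans(traces[, idx[[a]], drop = FALSE]),
                numeric(nrow(traces)))
  colnames(out) <- keep
  out
}

new_tic_trial <- function(traces, dt, t0, events, subject = NA_integer_,
                          trial = NA_integer_) {
  structure(list(traces = traces, dt = dt, t0 = t0, events = events,
                 subject = subject, trial = trial,
                 label = NA_character_),
            class = "tic_trial")
}

#' @export
print.tic_trial <- function(x, ...) {
  cat("<tic_trial> ", nrow(x$traces), " steps x ", ncol(x$traces),
      " units, label: ", ifelse(is.na(x$label), "unlabelled", x$label),
      "\n", sep = "")
  invisible(x)
}

#' Run one simulated-subject session
#'
#' Simulates the circuit continuously for the whole session and extracts
#' the monitored trial windows.  Within each trial the dopamine burst is
#' applied 1 s after trial start and the cortical pulse is rescaled per
#' channel by fresh Uniform(0, 1) draws.  Trials come back unlabelled; see
#' [classify_trials()].
#'
#' @param network A `tic_network` or a named parameter vector.
#' @param config A [session_config()].
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return A `tic_session`: list of `tic_trial` recordings plus the config,
#'   seed and per-trial channel scalings.
#' @export
run_session <- function(network = default_parameters(),
                        config = session_config(), seed = 1L) {
  network <- as_tic_network(network)
  config <- validate_config(config)
  dt <- config$dt
  set.seed(seed)
  scalings <- matrix(stats::runif(config$n_trials * 3), config$n_trials, 3)

  starts_s <- config$first_trial_at +
    (seq_len(config$n_trials) - 1) * (config$trial_length + config$inter_trial_gap)
  m1_units <- network$idx$M1
  pulses <- purrr::map_dfr(seq_len(config$n_trials), function(k) {
    da <- config$da_burst
    ci <- config$cortical_input
    sc <- if (isTRUE(ci$per_channel_scaling)) scalings[k, ] else rep(1, 3)
    dplyr::bind_rows(
      tibble::tibble(unit = network$da_idx,
                     height = network$w_da_in * da$height,
                     sd = da$sd, center = starts_s[k] + da$center),
      tibble::tibble(unit = m1_units, height = ci$height * sc,
                     sd = ci$sd, center = starts_s[k] + ci$center)
    )
  })
  windows <- tibble::tibble(start = round(starts_s / dt) + 1L,
                            length = as.integer(round(config$trial_length / dt)))
  out <- simulate_circuit(network, n_steps = round(config$session_length / dt),
                          pulses = pulses, windows = windows, dt = dt)
  trials <- purrr::imap(out$windows, function(m, k) {
    new_tic_trial(m, dt, starts_s[k],
                  events = list(da_burst = config$da_burst,
                                cortical_input = config$cortical_input,
                                scalings = scalings[k, ]),
                  trial = k)
  })
  structure(list(trials = trials, config = config, seed = seed,
                 scalings = scalings, network_params = network$params),
            class = "tic_session")
}

#' @export
print.tic_session <- function(x, ...) {
  labs <- vapply(x$trials, function(tr) tr$label, character(1))
  cat("<tic_session> ", length(x$trials), " trials (seed ", x$seed, "); ",
      sum(labs == "TIC", na.rm = TRUE), " TIC / ",
      sum(labs == "NO-TIC", na.rm = TRUE), " NO-TIC / ",
      sum(is.na(labs)), " unlabelled\n", sep = "")
  invisible(x)
}

#' Tic classification
#'
#' A trial is labelled TIC when the time-averaged activity of at least one
#' M1 unit over the 2-s window is strictly above the threshold (default
#' 40); otherwise NO-TIC.  `classify_trial()` labels one recording,
#' `classify_trials()` labels every trial of a session and returns a tidy
#' label manifest alongside.
#'
#' @param trial,session A `tic_trial` / `tic_session`.
#' @param threshold Classification threshold (activity units).
#' @return `classify_trial()`: the labelled trial.  `classify_trials()`:
#'   the session with labelled trials and a `labels` tibble attached
#'   (columns `trial`, `label`, `m1_avg_max`, `m1_peak`).
#' @name classification
#' @export
classify_trial <- function(trial, threshold = 40) {
  m1 <- trial$traces[, area_indices(colnames(trial$traces))$M1, drop = FALSE]
  trial$label <- if (max(colMeans(m1)) > threshold) "TIC" else "NO-TIC"
  trial
}

#' @rdname classification
#' @export
classify_trials <- function(session, threshold = session$config$tic_threshold) {
  session$trials <- purrr::map(session$trials, classify_trial,
                               threshold = threshold)
  session$labels <- purrr::imap_dfr(session$trials, function(tr, k) {
    m1 <- tr$traces[, area_indices(colnames(tr$traces))$M1, drop = FALSE]
    tibble::tibble(trial = k, label = tr$label,
                   m1_avg_max = max(colMeans(m1)),
                   m1_peak = max(rowMeans(m1)))
  })
  session
}

# counter-based per-subject seed derivation (stays below 2^31; `subject`
# must be smaller than `stride`)
subject_seed <- function(master_seed, subject, stride = 1000L) {
  base_mod <- (2147483647L %/% stride) - 1L
  (abs(as.integer(master_seed)) %% base_mod) * stride + as.integer(subject)
}

#' Run a cohort of simulated subjects
#'
#' One session per subject, each with a seed derived from the master seed by
#' a counter scheme, all trials classified.  To keep the result small the
#' cohort stores per-trial summaries (labels, per-area peak amplitudes, M1
#' unit peaks and time averages) and the per-subject average area traces
#' over TIC trials (used by the latency analysis), not the raw unit traces.
#'
#' @inheritParams run_session
#' @param n_subjects Number of simulated subjects.
#' @param master_seed Master seed for the cohort.
#' @return A `tic_cohort` with tibbles `labels` (subject, trial, label,
#'   m1_avg_max, m1_peak, m1 unit peaks) and `peaks` (subject, trial,
#'   label, area, peak), plus per-subject TIC-averaged area traces.
#' @export
run_cohort <- function(network = default_parameters(),
                       config = session_config(),
                       n_subjects = 40, master_seed = 1L) {
  network <- as_tic_network(network)
  labels <- list()
  peaks <- list()
  tic_traces <- vector("list", n_subjects)
  seeds <- integer(n_subjects)
  for (s in seq_len(n_subjects)) {
    seeds[s] <- subject_seed(master_seed, s)
    ses <- classify_trials(run_session(network, config, seed = seeds[s]))
    per_trial <- purrr::imap(ses$trials, function(tr, k) {
      am <- area_trace_matrix(tr$traces)
      m1 <- tr$traces[, area_indices(colnames(tr$traces))$M1, drop = FALSE]
      list(area_means = am,
           peaks = apply(am, 2, max),
           m1_unit_peaks = apply(m1, 2, max),
           m1_unit_avgs = colMeans(m1))
    })
    labels[[s]] <- dplyr::mutate(ses$labels, subject = s, .before = 1) |>
      dplyr::mutate(
        m1_unit_peak_1 = vapply(per_trial, function(x) x$m1_unit_peaks[1], 0),
        m1_unit_peak_2 = vapply(per_trial, function(x) x$m1_unit_peaks[2], 0),
        m1_unit_peak_3 = vapply(per_trial, function(x) x$m1_unit_peaks[3], 0),
        m1_unit_avg_1 = vapply(per_trial, function(x) x$m1_unit_avgs[1], 0),
        m1_unit_avg_2 = vapply(per_trial, function(x) x$m1_unit_avgs[2], 0),
        m1_unit_avg_3 = vapply(per_trial, function(x) x$m1_unit_avgs[3], 0)
      )
    peaks[[s]] <- purrr::imap_dfr(per_trial, function(x, k) {
      tibble::tibble(subject = s, trial = k, label = ses$labels$label[k],
                     area = names(x$peaks), peak = unname(x$peaks))
    })
    is_tic <- ses$labels$label == "TIC"
    if (any(is_tic)) {
      mats <- purrr::map(per_trial[is_tic], "area_means")
      tic_traces[[s]] <- Reduce(`+`, mats) / length(mats)
    }
  }
  structure(list(labels = dplyr::bind_rows(labels),
                 peaks = dplyr::bind_rows(peaks),
                 tic_traces = tic_traces,
                 seeds = tibble::tibble(subject = seq_len(n_subjects),
                                        seed = seeds),
                 config = config, master_seed = master_seed,
                 network_params = network$params),
            class = "tic_cohort")
}

#' @export
print.tic_cohort <- function(x, ...) {
  n_sub <- length(x$tic_traces)
  cat("<tic_cohort> ", n_sub, " subjects, ", nrow(x$labels), " trials (",
      sum(x$labels$label == "TIC"), " TIC)\n", sep = "")
  invisible(x)
}

# One standalone trial: lead-in to settle, then a 2-s monitored window with
# the dopamine burst and cortical pulse centred 1 s into the window.
simulate_trial <- function(network, da_burst, cortical_input,
                           scalings = stats::runif(3), lead_in = 1,
                           dt = network$dt) {
  n_lead <- round(lead_in / dt)
  n_trial <- round(2 / dt)
  sc <- if (isTRUE(cortical_input$per_channel_scaling)) scalings else rep(1, 3)
  pulses <- dplyr::bind_rows(
    tibble::tibble(unit = network$da_idx,
                   height = network$w_da_in * da_burst$height,
                   sd = da_burst$sd, center = lead_in + da_burst$center),
    tibble::tibble(unit = network$idx$M1,
                   height = cortical_input$height * sc,
                   sd = cortical_input$sd,
                   center = lead_in + cortical_input$center)
  )
  out <- simulate_circuit(network, n_steps = n_lead + n_trial, pulses = pulses,
                          windows = tibble::tibble(start = n_lead + 1L,
                                                   length = n_trial),
                          dt = dt)
  new_tic_trial(out$windows[[1]], dt, lead_in,
                events = list(da_burst = da_burst,
                              cortical_input = cortical_input,
                              scalings = scalings))
}

#' Dopamine dose-response sweep
#'
#' For each dopamine burst height, each simulated subject runs a block of
#' independent trials in which the burst is applied at that height while M1
#' receives a brief cortical pulse whose height is drawn uniformly from
#' `cortical_height_range` (and rescaled per channel by Uniform(0, 1));
#' tics are counted per subject and level.
#'
#' @inheritParams run_cohort
#' @param da_heights Dopamine burst heights to sweep (default: 0 to 100 in
#'   17 steps).
#' @param cortical_height_range Range the cortical pulse height is drawn
#'   from.
#' @param cortical_sd,da_sd Pulse standard deviations (s).
#' @param n_trials Trials per subject per level.
#' @param lead_in Settling time before each trial window (s).
#' @param threshold Tic classification threshold.
#' @return Tibble with columns `subject`, `da_height`, `n_tics`, `n_trials`.
#' @export
dose_response <- function(network = default_parameters(),
                          da_heights = seq(0, 100, length.out = 17),
                          cortical_height_range = c(0, 900),
                          cortical_sd = 0.040, da_sd = 0.020,
                          n_subjects = 40, n_trials = 30, master_seed = 1L,
                          lead_in = 1, threshold = 40) {
  if (is.unsorted(da_heights) || any(da_heights < 0))
    stop("da_heights must be non-negative and sorted")
  network <- as_tic_network(network)
  grid <- tidyr::expand_grid(level = seq_along(da_heights),
                             subject = seq_len(n_subjects))
  counts <- purrr::pmap_dfr(grid, function(level, subject) {
    set.seed(subject_seed(master_seed, (level - 1L) * 500L + subject,
                          stride = 20000L))
    n_tics <- 0L
    for (k in seq_len(n_trials)) {
      h <- stats::runif(1, cortical_height_range[1], cortical_height_range[2])
      sc <- stats::runif(3)
      tr <- simulate_trial(
        network,
        da_burst = pulse_spec(da_heights[level], da_sd, center = 1),
        cortical_input = pulse_spec(h, cortical_sd, center = 1,
                                    per_channel_scaling = TRUE),
        scalings = sc, lead_in = lead_in
      )
      if (classify_trial(tr, threshold)$label == "TIC") n_tics <- n_tics + 1L
    }
    tibble::tibble(subject = subject, da_height = da_heights[level],
                   n_tics = n_tics, n_trials = n_trials)
  })
  dplyr::arrange(counts, .data$da_height, .data$subject)
}
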