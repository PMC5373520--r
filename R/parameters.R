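#' Default model parameters
#'
#' Returns the full parameter vector of the circuit as a flat named numeric
#' vector: unit decay constants (`tau_*`, seconds), resting potentials
#' (`r_*`, activation-potential units on the same scale as firing rates),
#' activation thresholds (`thr_*`, activity units), Gaussian noise means and
#' standard deviations per component group (`mean_*`, `sd_*`), connection
#' weight magnitudes (`w_<pre>_<post>`; signs are fixed by transmitter type
#' and applied by [build_network()]), the dopaminergic modulation
#' coefficients of the striatal direct and indirect pathways (`b_strd1`,
#' `d_strd1`, `b_strd2`, `d_strd2`), and the input gain of the dopamine unit
#' (`w_da_in`).
#'
#' The shipped values are package-calibrated: core basal-ganglia and
#' cerebellar values are hand-set from the action-selection and Marr-Albus
#' modelling literature, and the remaining ("starred", see
#' [starred_parameters()]) values were calibrated so that the circuit
#' reproduces the reported system-level phenomena (tic generation under the
#' conjunction of a dopamine burst and cortical input, winner-take-all
#' selection, the two-cluster onset-latency pattern, the TIC/NO-TIC
#' peak-amplitude significance pattern and the dopamine dose-response).
#' They are not the original authors' values.
#'
#' @return Named numeric vector.
#' @seealso [parameter_bounds()], [build_network()]
#' @export
#' @examples
#' p <- default_parameters()
#' p[c("tau_m1", "r_gpi", "w_thbc_m1")]
default_parameters <- function() {
  c(
    # decay constants (s)
    tau_strd1 = 0.010, tau_strd2 = 0.040, tau_stn = 0.005,
    tau_gpe = 0.010, tau_gpi = 0.005,
    tau_thbc = 0.008, tau_thc = 0.020, tau_m1 = 0.030,
    tau_mf = 0.010, tau_gc = 0.010, tau_go = 0.005,
    tau_pc = 0.010, tau_dn = 0.010, tau_da = 0.180,
    # resting potentials (activation-potential units)
    r_strd1 = 25, r_strd2 = 100, r_stn = 5, r_gpe = 250, r_gpi = 242,
    r_thbc = 0, r_thc = 0, r_m1 = 0, r_mf = 0,
    r_gc = -30, r_go = -20, r_pc = 55, r_dn = 0,
    # activation thresholds (activity units)
    thr_strd1 = 15, thr_strd2 = 5, thr_stn = 0, thr_gpe = 0, thr_gpi = 0,
    thr_thbc = 0, thr_thc = 0, thr_m1 = 8, thr_mf = 0,
    thr_gc = 35, thr_go = 0, thr_pc = 0, thr_dn = 10,
    # noise (activation-potential units, one fresh draw per unit per step)
    mean_bg = 0, sd_bg1 = 15, sd_bg2 = 10,
    mean_th = 0, sd_th = 3,
    mean_mf = 0, sd_mf = 10,
    mean_m1 = 0, sd_m1 = 15,
    # cortico-striatal / cortico-subcortical efferents (one-to-one)
    w_m1_strd1 = 0.05, w_m1_strd2 = 0.02, w_m1_stn = 2.0,
    w_m1_mf = 0.6, w_m1_pc = 0.8, w_m1_thbc = 0.6, w_m1_thc = 0.5,
    # thalamo-cortical and thalamo-striatal efferents
    w_thbc_m1 = 4.0, w_thbc_strd1 = 0.25, w_thbc_strd2 = 0.1,
    w_thbc_stn = 1.5,
    w_thc_m1 = 1.0, w_thc_strd1 = 0.1, w_thc_strd2 = 0.1,
    # basal ganglia
    w_strd1_gpi = 2.0, w_strd2_gpe = 2.5,
    w_stn_gpe = 0.3, w_stn_gpi = 0.45, w_stn_mf = 0.5,
    w_gpe_gpi = 0.6, w_gpe_stn = 0.2,
    w_gpi_thbc = 4.0,
    # cerebellum
    w_mf_gc = 4.0, w_mf_go = 0.2, w_mf_dn = 0.45,
    w_gc_go = 0.05, w_gc_pc = 0.5, w_go_gc = 1.8,
    w_pc_dn = 0.4,
    w_dn_thbc = 0.25, w_dn_thc = 0.5,
    # dopaminergic modulation (Str direct / indirect pathway)
    b_strd1 = 0.5, d_strd1 = 8, b_strd2 = 0.02, d_strd2 = 60,
    # input gain of the dopamine unit
    w_da_in = 0.05
  )
}

#' Parameter bounds
#'
#' Declared lower/upper bounds for every model parameter, used by the
#' genetic-algorithm fitter ([genetic_fit()]) and by the sensitivity
#' analysis ([sensitivity()]) for min-max normalisation.
#'
#' @param params Named parameter vector (defaults to [default_parameters()]);
#'   only used to establish the parameter set and ordering.
#' @return A tibble with columns `parameter`, `lower`, `upper`, `starred`
#'   (whether the parameter belongs to the fitted subset).
#' @export
parameter_bounds <- function(params = default_parameters()) {
  nm <- names(params)
  lower <- numeric(length(nm))
  upper <- numeric(length(nm))
  for (i in seq_along(nm)) {
    n <- nm[i]
    if (n == "tau_da") {
      lower[i] <- 0.02; upper[i] <- 0.5
    } else if (startsWith(n, "tau_")) {
      lower[i] <- 0.005; upper[i] <- 0.2
    } else if (startsWith(n, "r_")) {
      lower[i] <- -100; upper[i] <- 250
    } else if (startsWith(n, "thr_")) {
      lower[i] <- 0; upper[i] <- 50
    } else if (startsWith(n, "sd_")) {
      lower[i] <- 0; upper[i] <- 60
    } else if (startsWith(n, "mean_")) {
      lower[i] <- -20; upper[i] <- 20
    } else if (n == "b_strd1") {
      lower[i] <- 0.01; upper[i] <- 1
    } else if (n == "d_strd1") {
      lower[i] <- 0; upper[i] <- 10
    } else if (n == "b_strd2") {
      lower[i] <- 0.01; upper[i] <- 2
    } else if (n == "d_strd2") {
      lower[i] <- 0; upper[i] <- 100
    } else if (n == "w_da_in") {
      lower[i] <- 0.001; upper[i] <- 0.5
    } else if (startsWith(n, "w_")) {
      lower[i] <- 0; upper[i] <- 4
    } else {
      stop("unknown parameter name: ", n)
    }
  }
  tibble::tibble(
    parameter = nm, lower = lower, upper = upper,
    starred = nm %in% starred_parameters()
  )
}

#' Names of the fitted ("starred") parameters
#'
#' The subset of parameters tuned by the automatic optimisation procedure
#' (the remainder are hand-set core circuit values).  The subset mirrors the
#' parameters examined in the sensitivity analysis: thalamo-cortical gains,
#' cortical efferent weights, pallidal/subthalamic weights and resting
#' potentials, the cerebello-thalamic weights, the subthalamo-cerebellar
#' weight and the dopamine amplitude coefficients.
#'
#' @return Character vector of parameter names.
#' @export
starred_parameters <- function() {
  c(
    "w_thbc_m1", "w_thc_m1", "w_m1_thbc", "w_m1_thc",
    "w_m1_strd1", "w_m1_strd2", "w_m1_stn", "w_m1_mf",
    "w_stn_gpi", "w_gpe_gpi", "r_gpi", "r_gpe",
    "w_dn_thbc", "w_dn_thc", "w_stn_mf",
    "d_strd1", "d_strd2"
  )
}

#' Validate a parameter vector
#'
#' Checks completeness (every expected name present, no extras), bounds, and
#' structural invariants (positive decay constants, non-negative thresholds
#' and noise SDs, positive dopamine denominator over the whole DA range).
#'
#' @param params Named numeric parameter vector.
#' @param dt Integration step used to check Euler stability (`dt < tau`).
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(params, dt = 0.001) {
  expected <- names(default_parameters())
  missing <- setdiff(expected, names(params))
  extra <- setdiff(names(params), expected)
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  if (length(extra) > 0)
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  if (any(!is.finite(params)))
    stop("non-finite parameter values: ",
         paste(names(params)[!is.finite(params)], collapse = ", "))
  taus <- params[startsWith(names(params), "tau_")]
  if (any(taus <= 0)) stop("decay constants must be positive")
  if (any(taus <= dt))
    stop("Euler integration unstable: dt = ", dt,
         " must be smaller than every tau (smallest: ", min(taus), ")")
  thrs <- params[startsWith(names(params), "thr_")]
  if (any(thrs < 0)) stop("activation thresholds must be non-negative")
  sds <- params[startsWith(names(params), "sd_")]
  if (any(sds < 0)) stop("noise standard deviations must be non-negative")
  # DA denominator positive over the clamped DA range [DA_MIN, DA_MAX]
  den <- params[["b_strd2"]] + params[["d_strd2"]] * c(DA_MIN, DA_MAX)
  if (any(den <= 0))
    stop("b_strd2 + d_strd2 * a_DA must stay positive over the DA range")
  ws <- params[startsWith(names(params), "w_")]
  if (any(ws < 0)) stop("connection weight magnitudes must be non-negative")
  invisible(params)
}

#' Dopamine efflux bounds
#'
#' The activation potential of the dopamine unit is hard-clamped to
#' `[DA_MIN, DA_MAX]`: it rests at `DA_MIN = 0.01`, rapidly reaches
#' `DA_MAX = 0.5` under a tic-condition burst, and decays back toward
#' `DA_MIN`.
#'
#' @name da-bounds
#' @export
DA_MIN <- 0.01

#' @rdname da-bounds
#' @export
DA_MAX <- 0.5
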