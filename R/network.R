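#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @useDynLib ticcircuit, .registration = TRUE
NULL

# Component layout: name, number of units.  Every component except GC, GO and
# DA has one unit per action channel.
component_layout <- function() {
  tibble::tibble(
    component = c("StrD1", "StrD2", "STN", "GPe", "GPi", "ThBC", "ThC",
                  "M1", "MF", "GC", "GO", "PC", "DN", "DA"),
    n_units = c(3, 3, 3, 3, 3, 3, 3, 3, 3, 100, 1, 3, 3, 1)
  )
}

# Component-level connection table: pre, post, topology, sign, weight name.
# This transcribes the full arrow set of the architecture; any connection not
# listed here is absent from the model.
connection_layout <- function() {
  con <- function(pre, post, topology, sign) {
    tibble::tibble(pre = pre, post = post, topology = topology, sign = sign,
                   weight = paste0("w_", tolower(pre), "_", tolower(post)))
  }
  dplyr::bind_rows(
    con("M1", "StrD1", "one-to-one", "excitatory"),
    con("M1", "StrD2", "one-to-one", "excitatory"),
    con("M1", "STN", "one-to-one", "excitatory"),
    con("M1", "MF", "one-to-one", "excitatory"),
    con("M1", "PC", "one-to-one", "excitatory"),
    con("M1", "ThBC", "one-to-one", "excitatory"),
    con("M1", "ThC", "one-to-one", "excitatory"),
    con("ThBC", "M1", "one-to-one", "excitatory"),
    con("ThBC", "StrD1", "one-to-one", "excitatory"),
    con("ThBC", "StrD2", "one-to-one", "excitatory"),
    con("ThBC", "STN", "one-to-one", "excitatory"),
    con("ThC", "M1", "one-to-one", "excitatory"),
    con("ThC", "StrD1", "one-to-one", "excitatory"),
    con("ThC", "StrD2", "one-to-one", "excitatory"),
    con("StrD1", "GPi", "one-to-one", "inhibitory"),
    con("StrD2", "GPe", "one-to-one", "inhibitory"),
    con("STN", "GPe", "all-to-all", "excitatory"),
    con("STN", "GPi", "all-to-all", "excitatory"),
    con("STN", "MF", "one-to-one", "excitatory"),
    con("GPe", "GPi", "one-to-one", "inhibitory"),
    con("GPe", "STN", "one-to-one", "inhibitory"),
    con("GPi", "ThBC", "one-to-one", "inhibitory"),
    con("MF", "GC", "fixed-matrix", "excitatory"),
    con("MF", "GO", "all-to-all", "excitatory"),
    con("MF", "DN", "one-to-one", "excitatory"),
    con("GC", "GO", "all-to-all", "excitatory"),
    con("GC", "PC", "fixed-matrix", "excitatory"),
    con("GO", "GC", "all-to-all", "inhibitory"),
    con("PC", "DN", "one-to-one", "inhibitory"),
    con("DN", "ThBC", "one-to-one", "excitatory"),
    con("DN", "ThC", "one-to-one", "excitatory")
  )
}

# Deterministic mossy-fiber -> granule-cell expansion pattern.  The granule
# layer is a hand-designed sparse expansion: each input channel recruits a
# small set of strongly tuned granule units (9 per channel) while the
# remaining units carry only weak mixed drive, so that any given channel
# drive activates well under 10% of the layer with highly dissimilar
# patterns across channels.  Weight jitter comes from a fixed structural
# seed; the overall magnitude is the tunable parameter w_mf_gc.
mf_gc_pattern <- function(n_gc = 100, n_mf = 3, n_strong = 9) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(733100L)
  w <- matrix(stats::runif(n_gc * n_mf, 0.02, 0.18), n_gc, n_mf)
  pref <- rep_len(seq_len(n_mf), n_gc)
  for (k in seq_len(n_mf)) {
    strong <- which(pref == k)[seq_len(n_strong)]
    w[strong, k] <- stats::runif(n_strong, 0.85, 1.15)
  }
  w
}

#' Hand-set granule-to-Purkinje weights
#'
#' Builds the 100 x 3 granule-cell to Purkinje-cell weight matrix encoding
#' which action channels are selectable.  For a selectable channel the
#' parallel-fiber (granule to Purkinje) drive is zero, so that mossy fiber
#' input leaves the Purkinje unit at its spontaneous level and the dentate
#' unit can be disinhibited; for a non-selectable channel the excitatory
#' weights take the magnitude `w_gc_pc`, driving the Purkinje unit toward
#' saturation so that its inhibition keeps the dentate unit suppressed.
#'
#' @param selectable Integer channels (subset of `1:3`) whose motor pattern
#'   may be selected.  Default: all three.
#' @param w_gc_pc Weight magnitude for non-selectable channels.
#' @param n_gc Number of granule units.
#' @return Numeric matrix (`n_gc` x 3) of non-negative excitatory
#'   magnitudes.
#' @export
set_gc_pc_weights <- function(selectable = 1:3, w_gc_pc = 0.5, n_gc = 100) {
  if (!all(selectable %in% 1:3))
    stop("selectable channels must be a subset of 1:3")
  w <- matrix(w_gc_pc, n_gc, 3)
  w[, selectable] <- 0
  w
}

#' Assemble the executable circuit
#'
#' Builds the full 135-unit network: 15 basal-ganglia units (StrD1, StrD2,
#' STN, GPe, GPi/SNr; three action channels each), 6 thalamic units (ThBC,
#' ThC), 3 primary motor cortex units, a cerebellar microcircuit (3 mossy
#' fiber, 100 granule, 1 Golgi, 3 Purkinje, 3 dentate units) and 1 dopamine
#' unit, wired with the fixed connection set (one-to-one channel links,
#' diffuse subthalamic projections, the mossy-fiber expansion and the
#' hand-set granule-to-Purkinje matrix).  Inhibitory (GABAergic) links enter
#' the input equation with negative sign, excitatory (glutamatergic) links
#' with positive sign.
#'
#' @param params Named parameter vector (see [default_parameters()]).
#' @param selectable Channels whose motor pattern is selectable, passed to
#'   [set_gc_pc_weights()].
#' @param dt Integration step (s) used for the stability check.
#' @return An object of class `tic_network`: unit-level weight matrix `W`
#'   (row = post, column = pre), per-unit `tau`, `r`, `thr`, `noise_mean`,
#'   `noise_sd`, component index map `idx`, striatal/dopamine bookkeeping
#'   and the component-level connection table.
#' @export
#' @examples
#' net <- build_network(default_parameters())
#' net$n
#' connection_table(net)
build_network <- function(params = default_parameters(), selectable = 1:3,
                          dt = 0.001) {
  params <- validate_parameters(params, dt = dt)
  layout <- component_layout()
  n <- sum(layout$n_units)
  last <- cumsum(layout$n_units)
  first <- last - layout$n_units + 1
  idx <- purrr::map2(first, last, seq)
  names(idx) <- layout$component

  unit_names <- unlist(purrr::map2(layout$component, layout$n_units,
                                   function(cmp, k) {
                                     if (k == 1) cmp else paste0(cmp, "_", seq_len(k))
                                   }))

  p <- function(nm) unname(params[[nm]])
  per_unit <- function(prefix, da_value) {
    comp_key <- c(StrD1 = "strd1", StrD2 = "strd2", STN = "stn", GPe = "gpe",
                  GPi = "gpi", ThBC = "thbc", ThC = "thc", M1 = "m1",
                  MF = "mf", GC = "gc", GO = "go", PC = "pc", DN = "dn")
    v <- numeric(n)
    for (cmp in names(comp_key))
      v[idx[[cmp]]] <- p(paste0(prefix, "_", comp_key[[cmp]]))
    v[idx$DA] <- da_value
    v
  }

  tau <- per_unit("tau", p("tau_da"))
  r <- per_unit("r", DA_MIN)  # DA unit decays toward its floor
  thr <- per_unit("thr", 0)

  noise_mean <- numeric(n)
  noise_sd <- numeric(n)
  noise_mean[unlist(idx[c("StrD1", "StrD2", "STN", "GPe", "GPi")])] <- p("mean_bg")
  noise_sd[unlist(idx[c("StrD1", "StrD2", "STN")])] <- p("sd_bg1")
  noise_sd[unlist(idx[c("GPe", "GPi")])] <- p("sd_bg2")
  noise_mean[unlist(idx[c("ThBC", "ThC")])] <- p("mean_th")
  noise_sd[unlist(idx[c("ThBC", "ThC")])] <- p("sd_th")
  noise_mean[idx$MF] <- p("mean_mf")
  noise_sd[idx$MF] <- p("sd_mf")
  noise_mean[idx$M1] <- p("mean_m1")
  noise_sd[idx$M1] <- p("sd_m1")
  # GC, GO, PC, DN and DA carry no noise

  W <- matrix(0, n, n, dimnames = list(unit_names, unit_names))
  cons <- connection_layout()
  sgn <- function(s) if (s == "inhibitory") -1 else 1
  for (i in seq_len(nrow(cons))) {
    pre <- idx[[cons$pre[i]]]
    post <- idx[[cons$post[i]]]
    topo <- cons$topology[i]
    s <- sgn(cons$sign[i])
    if (topo == "one-to-one") {
      if (length(pre) != length(post))
        stop("one-to-one connection with unequal unit counts: ",
             cons$pre[i], " -> ", cons$post[i])
      w <- p(cons$weight[i])
      W[cbind(post, pre)] <- s * w
    } else if (topo == "all-to-all") {
      w <- p(cons$weight[i])
      W[post, pre] <- s * w
    } else { # fixed-matrix
      if (cons$pre[i] == "MF" && cons$post[i] == "GC") {
        W[post, pre] <- s * p("w_mf_gc") * mf_gc_pattern(length(post), length(pre))
      } else if (cons$pre[i] == "GC" && cons$post[i] == "PC") {
        gw <- set_gc_pc_weights(selectable, p("w_gc_pc"), n_gc = length(pre))
        W[post, pre] <- s * t(gw)
      } else {
        stop("no fixed matrix defined for ", cons$pre[i], " -> ", cons$post[i])
      }
    }
  }

  structure(list(
    n = n,
    layout = layout,
    idx = idx,
    unit_names = unit_names,
    W = W,
    tau = tau, r = r, thr = thr,
    noise_mean = noise_mean, noise_sd = noise_sd,
    d1_idx = idx$StrD1, d2_idx = idx$StrD2, da_idx = idx$DA,
    b_d1 = p("b_strd1"), d_d1 = p("d_strd1"),
    b_d2 = p("b_strd2"), d_d2 = p("d_strd2"),
    w_da_in = p("w_da_in"),
    da_min = DA_MIN, da_max = DA_MAX,
    connections = cons,
    params = params,
    selectable = selectable,
    dt = dt
  ), class = "tic_network")
}

#' @export
print.tic_network <- function(x, ...) {
  cat("<tic_network> ", x$n, " leaky-integrator units, ",
      nrow(x$connections), " component-level connections\n", sep = "")
  cat("components: ",
      paste0(x$layout$component, "(", x$layout$n_units, ")", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Component-level connection table
#'
#' The edge list of the circuit (pre, post, topology, sign, weight value),
#' suitable for inspection or export with [write_connections()].
#'
#' @param network A `tic_network` (or a parameter vector, which is built
#'   into one).
#' @return Tibble with one row per component-level connection.
#' @export
connection_table <- function(network = build_network()) {
  network <- as_tic_network(network)
  dplyr::mutate(
    network$connections,
    value = unname(network$params[.data$weight])
  )
}

# Accept either a parameter vector or a prebuilt network.
as_tic_network <- function(x, ...) {
  if (inherits(x, "tic_network")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(build_network(x, ...))
  stop("expected a tic_network or a named parameter vector")
}
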