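#' Read and write model parameters as JSON
#'
#' Parameters are stored as a flat name-to-value JSON map with sorted keys
#' (so files have a stable digest); round-trips are lossless.
#'
#' @param params Named parameter vector.
#' @param path File path.
#' @return `write_params()`: the path, invisibly.  `read_params()`: a
#'   validated named parameter vector.
#' @name params-io
#' @export
write_params <- function(params, path) {
  validate_parameters(params)
  x <- as.list(params[order(names(params))])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname params-io
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- unlist(x)
  validate_parameters(params)
  params[names(default_parameters())]
}

#' Read and write trace tables as tidy CSV
#'
#' Long-format traces (one observation per row), as produced by
#' [make_reference_traces()] or [tidy.tic_trial()]; numeric round-trips
#' are exact to the printed precision (time written with 6 decimals).
#'
#' @param traces Tibble with columns `area`, `state` (optional), `time_s`,
#'   `activity`.
#' @param path File path.
#' @return `write_traces()`: the path, invisibly.  `read_traces()`: the
#'   tibble.
#' @name traces-io
#' @export
write_traces <- function(traces, path) {
  stopifnot(all(c("area", "time_s", "activity") %in% names(traces)))
  out <- traces
  out$time_s <- sprintf("%.6f", out$time_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname traces-io
#' @export
read_traces <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("area", "time_s", "activity") %in% names(x)))
    stop("trace file ", path, " lacks the columns area/time_s/activity")
  tibble::as_tibble(x)
}

#' Export the connection edge list
#'
#' Writes the component-level connection table (pre, post, topology, sign,
#' weight name and value) for inspection.
#'
#' @param network A `tic_network` or parameter vector.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_connections <- function(network, path) {
  utils::write.csv(connection_table(network), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load and validate a session configuration file
#'
#' YAML with scalar fields (`dt`, `session_length`, `n_trials`,
#' `trial_length`, `inter_trial_gap`, `first_trial_at`, `tic_threshold`)
#' and nested pulse blocks `da_burst` / `cortical_input` (`height`, `sd`,
#' `center`, optional `per_channel_scaling`).  Missing fields are reported
#' by name.
#'
#' @param path YAML file path.
#' @return A validated `session_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  pulse_from <- function(block, name) {
    if (is.null(block)) stop("config is missing field `", name, "`")
    for (f in c("height", "sd")) {
      if (is.null(block[[f]]))
        stop("config field `", name, ".", f, "` is missing")
    }
    pulse_spec(block$height, block$sd,
               center = block$center %||% 1,
               per_channel_scaling = block$per_channel_scaling %||% FALSE)
  }
  scalars <- c("dt", "session_length", "n_trials", "trial_length",
               "inter_trial_gap", "first_trial_at", "tic_threshold")
  for (f in scalars) {
    if (is.null(y[[f]])) stop("config is missing field `", f, "`")
  }
  validate_config(structure(
    c(y[scalars],
      list(da_burst = pulse_from(y$da_burst, "da_burst"),
           cortical_input = pulse_from(y$cortical_input, "cortical_input"))),
    class = "session_config"))
}

#' Write a session configuration file
#'
#' @param config A `session_config`.
#' @param path YAML file path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  as_block <- function(ps) {
    list(height = ps$height, sd = ps$sd, center = ps$center,
         per_channel_scaling = ps$per_channel_scaling)
  }
  y <- list(dt = config$dt, session_length = config$session_length,
            n_trials = config$n_trials, trial_length = config$trial_length,
            inter_trial_gap = config$inter_trial_gap,
            first_trial_at = config$first_trial_at,
            tic_threshold = config$tic_threshold,
            da_burst = as_block(config$da_burst),
            cortical_input = as_block(config$cortical_input))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the config
#' snapshot, the master seed, a digest of the parameter values and the
#' package version, with a timestamp.
#'
#' @param dir Output directory (created if needed).
#' @param config A `session_config`.
#' @param seed Master seed of the run.
#' @param params Parameter vector used.
#' @return Path of the written manifest, invisibly.
#' @name manifest
#' @export
write_manifest <- function(dir, config, seed, params) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  digest <- sum(as.numeric(params) * seq_along(params)) # order-sensitive checksum
  m <- list(
    package_version = as.character(utils::packageVersion("ticcircuit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = seed,
    parameter_checksum = digest,
    parameters = as.list(params[order(names(params))]),
    config = list(dt = config$dt, session_length = config$session_length,
                  n_trials = config$n_trials,
                  trial_length = config$trial_length,
                  inter_trial_gap = config$inter_trial_gap,
                  first_trial_at = config$first_trial_at,
                  tic_threshold = config$tic_threshold,
                  da_burst = config$da_burst[1:3],
                  cortical_input = config$cortical_input[1:3])
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname manifest
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
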