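#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trial recording into a long trace table
#'
#' @param x A `tic_trial`.
#' @param pooled Return pooled area means (default) rather than every unit.
#' @param include_da Include the dopamine unit/area.
#' @param ... Unused.
#' @return Tibble with columns `area` (or `unit`), `step`, `time_s`,
#'   `activity`.
#' @export
tidy.tic_trial <- function(x, pooled = TRUE, include_da = FALSE, ...) {
  if (pooled) {
    m <- area_trace_matrix(x$traces, include_da = include_da)
    tibble::tibble(area = rep(colnames(m), each = nrow(m)),
                   step = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
                   time_s = rep(seq_len(nrow(m)) * x$dt, times = ncol(m)),
                   activity = as.vector(m))
  } else {
    m <- x$traces
    tibble::tibble(unit = rep(colnames(m), each = nrow(m)),
                   step = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
                   time_s = rep(seq_len(nrow(m)) * x$dt, times = ncol(m)),
                   activity = as.vector(m))
  }
}

#' Tidy a session into its label manifest
#'
#' @param x A classified `tic_session`.
#' @param ... Unused.
#' @return The label tibble (`trial`, `label`, `m1_avg_max`, `m1_peak`).
#' @export
tidy.tic_session <- function(x, ...) {
  if (is.null(x$labels))
    stop("session is unclassified; run classify_trials() first")
  x$labels
}

#' @export
glance.tic_session <- function(x, ...) {
  labs <- tidy(x)
  tibble::tibble(n_trials = nrow(labs),
                 n_tic = sum(labs$label == "TIC"),
                 tic_rate = mean(labs$label == "TIC"),
                 seed = x$seed)
}

#' @export
tidy.tic_cohort <- function(x, ...) x$labels

#' @export
glance.tic_cohort <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$seeds),
                 n_trials = nrow(x$labels),
                 n_tic = sum(x$labels$label == "TIC"),
                 tic_rate = mean(x$labels$label == "TIC"),
                 master_seed = x$master_seed)
}

#' Tidy an ANOVA result
#'
#' `tidy()` returns the ANOVA table (one row per term); `glance()` returns
#' a one-row summary with the headline F statistic and p value (the
#' interaction term for the two-way analysis, the single factor
#' otherwise), plus the post hoc table dimensions.
#'
#' @param x A `tic_anova`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tic_anova <- function(x, ...) {
  s <- summary(x$fit)[[1]]
  tibble::tibble(term = trimws(rownames(s)),
                 df = s$Df, sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
                 statistic = s$`F value`, p_value = s$`Pr(>F)`)
}

#' @rdname tidy.tic_anova
#' @export
glance.tic_anova <- function(x, ...) {
  tb <- tidy(x)
  terms <- tb$term[!tb$term %in% "Residuals"]
  head_term <- if ("area:state" %in% terms) "area:state" else terms[1]
  row <- tb[tb$term == head_term, ]
  tibble::tibble(kind = x$kind, term = head_term,
                 statistic = row$statistic, p_value = row$p_value,
                 n_posthoc = if (is.null(x$posthoc)) 0L else nrow(x$posthoc))
}

#' Tidy a genetic-algorithm fit
#'
#' `tidy()` returns the fitted parameter values with their bounds;
#' `glance()` the best error and evaluation counts.
#'
#' @param x A `tic_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tic_fit <- function(x, ...) {
  tibble::tibble(parameter = x$fit_names,
                 estimate = unname(x$best_params[x$fit_names]),
                 lower = x$bounds$lower, upper = x$bounds$upper)
}

#' @rdname tidy.tic_fit
#' @export
glance.tic_fit <- function(x, ...) {
  tibble::tibble(best_error = x$best_error,
                 n_evaluations = nrow(x$archive),
                 n_generations = nrow(x$generations),
                 converged = x$best_error < x$ga$stop_error)
}
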