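#' Peak amplitude of an area's mean activity
#'
#' The peak over time of the across-unit mean activity trace of a pooled
#' recording area (units within an area are averaged first, then the
#' maximum over the trial window is taken).
#'
#' @param trial A `tic_trial` recording.
#' @param area One of [areas()] (optionally `"DA"`).
#' @return Peak amplitude (activity units).
#' @export
peak_amplitude <- function(trial, area) {
  idx <- area_indices(colnames(trial$traces))
  if (!area %in% names(idx)) stop("unknown area: ", area)
  max(rowMeans(trial$traces[, idx[[area]], drop = FALSE]))
}

#' Per-subject peak-amplitude table
#'
#' For every subject, one trial is randomly selected per movement state
#' (TIC and NO-TIC) and the per-area peak amplitudes of those two trials
#' are collected.  Subjects lacking one of the two states are dropped with
#' a warning.
#'
#' @param cohort A `tic_cohort` from [run_cohort()].
#' @param seed Optional seed for the trial selection (restores the RNG
#'   state afterwards).
#' @return Tibble with columns `subject`, `area`, `state`, `peak`.
#' @export
peak_table <- function(cohort, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  picks <- cohort$labels |>
    dplyr::group_by(.data$subject, .data$label) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("subject", "trial", state = "label")
  complete <- picks |>
    dplyr::count(.data$subject) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::pull("subject")
  if (length(complete) < dplyr::n_distinct(picks$subject))
    warning(dplyr::n_distinct(picks$subject) - length(complete),
            " subject(s) lacked trials in one movement state and were dropped")
  picks |>
    dplyr::filter(.data$subject %in% complete) |>
    dplyr::inner_join(cohort$peaks, by = c("subject", "trial")) |>
    dplyr::select("subject", "area", "state", "peak")
}

#' Onset delay between two traces by cross-correlation of derivatives
#'
#' Both traces are first-differenced (no smoothing), the Pearson
#' correlation between the differenced reference and the differenced,
#' lag-shifted comparison trace is computed at every lag in
#' `-max_lag..max_lag`, and the lag of the dominant cross-correlation peak
#' (largest absolute correlation, so that areas responding with an
#' activity decrease are located by the same peak as areas responding
#' with an increase) is returned in seconds.  The sign convention is
#' positive when `other` precedes `ref`: `onset_delay(m1, putamen, dt)`
#' is positive when the putamen onset leads the M1 onset.  Ties in the
#' argmax are broken toward the smallest absolute lag.
#'
#' @param ref Reference trace (numeric vector).
#' @param other Comparison trace, same length.
#' @param dt Sampling step (s).
#' @param max_lag Maximum lag in steps (default: half the differenced
#'   length).
#' @return Delay in seconds.
#' @export
#' @examples
#' x <- dnorm(seq(0, 2, by = 0.001), mean = 1, sd = 0.1)
#' y <- c(rep(0, 126), x[1:(length(x) - 126)])  # y lags x by 126 steps
#' onset_delay(y, x, dt = 0.001)  # 0.126: x precedes the reference y
onset_delay <- function(ref, other, dt, max_lag = NULL) {
  if (length(ref) != length(other))
    stop("traces must have the same length")
  if (length(ref) < 3) stop("traces must have length >= 3")
  dr <- diff(ref)
  do <- diff(other)
  if (stats::sd(dr) == 0 || stats::sd(do) == 0)
    stop("undefined delay: a trace has a flat (zero-variance) derivative")
  n <- length(dr)
  if (is.null(max_lag)) max_lag <- n %/% 2
  max_lag <- min(max_lag, n - 3)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    # c(k) = cor(dref[t + k], dother[t]); maximal at k = lead of `other`
    if (k >= 0) {
      a <- dr[(1 + k):n]; b <- do[1:(n - k)]
    } else {
      a <- dr[1:(n + k)]; b <- do[(1 - k):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }, numeric(1))
  best <- max(abs(cc))
  cand <- lags[abs(cc) >= best - 1e-12]
  lag <- cand[order(abs(cand), cand)][1]
  lag * dt
}

#' Per-subject onset-latency table
#'
#' For each subject with at least one TIC trial, the area traces averaged
#' over that subject's TIC trials are compared with the M1 trace via
#' [onset_delay()]: positive delays mean the area's onset precedes M1.
#'
#' @param cohort A `tic_cohort`.
#' @param max_lag_s Maximum cross-correlation lag (s).
#' @return Tibble with columns `subject`, `area` (including `M1`, with
#'   delay 0 by construction), `delay_s`.
#' @export
latency_table <- function(cohort, max_lag_s = 1) {
  dt <- cohort$config$dt
  max_lag <- round(max_lag_s / dt)
  purrr::imap_dfr(cohort$tic_traces, function(m, s) {
    if (is.null(m)) return(NULL)
    ref <- m[, "M1"]
    purrr::map_dfr(areas(), function(a) {
      tibble::tibble(subject = s, area = a,
                     delay_s = if (a == "M1") 0
                               else onset_delay(ref, m[, a], dt, max_lag))
    })
  })
}

new_tic_anova <- function(fit, posthoc, kind) {
  structure(list(fit = fit, posthoc = posthoc, kind = kind),
            class = "tic_anova")
}

#' @export
print.tic_anova <- function(x, ...) {
  cat("<tic_anova> ", x$kind, "\n", sep = "")
  print(summary(x$fit))
  if (!is.null(x$posthoc)) {
    cat("\nPost hoc (Tukey HSD):\n")
    print(as.data.frame(x$posthoc), digits = 4)
  }
  invisible(x)
}

#' Two-way ANOVA of peak amplitudes (area x movement state)
#'
#' Fits `aov(peak ~ area * state)` on a [peak_table()] and applies a Tukey
#' HSD post hoc to the interaction, extracting the TIC-vs-NO-TIC
#' comparison within each area.  Significance is declared at `p < 0.001`.
#'
#' @param tbl Tibble with columns `subject`, `area`, `state`, `peak`.
#' @param alpha Significance level.
#' @return A `tic_anova` with the fitted model, the per-area post hoc
#'   table (`area`, `diff`, `p_adj`, `significant`) and tidiers
#'   ([tidy.tic_anova()], [glance.tic_anova()]).
#' @export
area_state_anova <- function(tbl, alpha = 0.001) {
  tbl <- dplyr::mutate(tbl, area = factor(.data$area),
                       state = factor(.data$state))
  counts <- dplyr::count(tbl, .data$area, .data$state)
  if (any(counts$n < 2) ||
      nrow(counts) < 2 * dplyr::n_distinct(tbl$area))
    stop("each area x state cell needs at least 2 observations")
  fit <- stats::aov(peak ~ area * state, data = tbl)
  tk <- stats::TukeyHSD(fit, "area:state")[["area:state"]]
  cmp <- tibble::tibble(contrast = rownames(tk),
                        diff = tk[, "diff"], p_adj = tk[, "p adj"])
  within_area <- purrr::map_dfr(levels(tbl$area), function(a) {
    lv <- paste0(a, ":", levels(tbl$state))
    hit <- cmp$contrast %in% c(paste(lv[1], lv[2], sep = "-"),
                               paste(lv[2], lv[1], sep = "-"))
    row <- cmp[hit, ][1, ]
    tibble::tibble(area = a, diff = abs(row$diff), p_adj = row$p_adj,
                   significant = row$p_adj < alpha)
  })
  new_tic_anova(fit, within_area, "two-way (area x state) peak amplitudes")
}

#' One-way ANOVA of onset delays across areas
#'
#' Fits `aov(delay_s ~ area)` on a [latency_table()] and extracts the
#' Tukey HSD comparisons of each area against M1.
#'
#' @param tbl Tibble with columns `subject`, `area`, `delay_s`.
#' @param alpha Significance level.
#' @return A `tic_anova` with post hoc columns `area`, `diff`, `p_adj`,
#'   `significant` for every area-vs-M1 comparison.
#' @export
latency_anova <- function(tbl, alpha = 0.001) {
  if (dplyr::n_distinct(tbl$subject) < 2)
    stop("at least 2 subjects required")
  tbl <- dplyr::mutate(tbl, area = factor(.data$area))
  fit <- stats::aov(delay_s ~ area, data = tbl)
  tk <- stats::TukeyHSD(fit, "area")[["area"]]
  cmp <- tibble::tibble(contrast = rownames(tk),
                        diff = tk[, "diff"], p_adj = tk[, "p adj"])
  vs_m1 <- cmp |>
    dplyr::filter(grepl("(^M1-)|(-M1$)", .data$contrast)) |>
    dplyr::mutate(area = sub("-?M1-?", "", .data$contrast),
                  diff = abs(.data$diff),
                  significant = .data$p_adj < alpha) |>
    dplyr::select("area", "diff", "p_adj", "significant")
  new_tic_anova(fit, vs_m1, "one-way onset delays across areas")
}

#' One-way ANOVA of tic counts across dopamine levels
#'
#' @param counts Tibble from [dose_response()] (columns `subject`,
#'   `da_height`, `n_tics`).
#' @return A `tic_anova` (no post hoc table).
#' @export
dose_response_anova <- function(counts) {
  if (dplyr::n_distinct(counts$da_height) < 2)
    stop("at least 2 dopamine levels required")
  counts <- dplyr::mutate(counts, level = factor(.data$da_height))
  fit <- stats::aov(n_tics ~ level, data = counts)
  new_tic_anova(fit, NULL, "one-way tic counts across dopamine levels")
}
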