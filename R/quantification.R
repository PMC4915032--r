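#' Normalize an EPSC amplitude time course to its baseline
#'
#' Divides every sweep amplitude by the mean amplitude of the baseline
#' window (8 min before induction by default) and summarizes the LTP
#' magnitude as the mean normalized amplitude in the post window (30-40 min
#' after induction by default) times 100.
#'
#' @param sweeps A `sweep_series` from [generate_ltp_series()], or a data
#'   frame with `time_s` and `amplitude_pa` columns (amplitudes may be
#'   negative for inward currents; magnitudes are used).
#' @param event_time Induction onset, s (default from attributes or 0).
#' @param baseline_window,post_window Length-2 windows, s.
#' @return An `ltp_result`: list with `normalized` (tibble `time_s`,
#'   `amplitude_pa`, `normalized`), `baseline_mean` (pA), `ltp_percent`.
#' @examples
#' s <- generate_ltp_series(100, 2.18, noise_sd = 0, seed = 1)
#' normalize_timecourse(s)$ltp_percent # 218
#' @export
normalize_timecourse <- function(sweeps, event_time = NULL,
                                 baseline_window = NULL, post_window = NULL) {
  if (is.null(event_time))
    event_time <- attr(sweeps, "event_time") %||% 0
  if (is.null(baseline_window))
    baseline_window <- attr(sweeps, "baseline_window") %||%
      c(event_time - 480, event_time)
  if (is.null(post_window))
    post_window <- attr(sweeps, "post_window") %||%
      c(event_time + 1800, event_time + 2400)
  if (baseline_window[2] > event_time + 1e-9)
    abort("baseline window must end at or before the induction event",
          class = "spinemorph_parameter_error")
  t <- sweeps$time_s
  a <- abs(sweeps$amplitude_pa)
  in_base <- t >= baseline_window[1] & t <= baseline_window[2]
  in_post <- t >= post_window[1] & t <= post_window[2]
  if (sum(in_base) < 3)
    abort("baseline window holds fewer than 3 sweeps",
          class = "spinemorph_parameter_error")
  if (sum(in_post) < 1)
    abort("post window holds no sweeps", class = "spinemorph_parameter_error")
  bmean <- mean(a[in_base])
  norm <- a / bmean
  structure(list(
    normalized = tibble::tibble(time_s = t, amplitude_pa = a,
                                normalized = norm),
    baseline_mean = bmean,
    baseline_window = baseline_window,
    post_window = post_window,
    ltp_percent = mean(norm[in_post]) * 100),
    class = "ltp_result")
}

#' @export
print.ltp_result <- function(x, ...) {
  cat(sprintf("<ltp_result> baseline %.1f pA, LTP %.1f%% of baseline (post window %g-%g s)\n",
              x$baseline_mean, x$ltp_percent, x$post_window[1], x$post_window[2]))
  invisible(x)
}

#' @export
glance.ltp_result <- function(x, ...) {
  tibble::tibble(baseline_mean = x$baseline_mean,
                 ltp_percent = x$ltp_percent,
                 n_sweeps = nrow(x$normalized))
}

#' Plot a normalized LTP time course
#'
#' @param object An `ltp_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ltp_result <- function(object, ...) {
  ggplot2::ggplot(object$normalized,
                  ggplot2::aes(.data$time_s / 60, .data$normalized * 100)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::annotate("rect", xmin = object$post_window[1] / 60,
                      xmax = object$post_window[2] / 60, ymin = -Inf,
                      ymax = Inf, alpha = 0.1) +
    ggplot2::labs(x = "time (min)", y = "EPSC amplitude (% of baseline)")
}

#' Paired-pulse ratio
#'
#' Second over first response amplitude for two stimuli 40 ms apart
#' (amplitudes of averaged traces).
#'
#' @param amp1,amp2 Response amplitudes, pA (vectorized; magnitudes used).
#' @return Dimensionless ratio.
#' @examples
#' paired_pulse_ratio(90, 171) # 1.9
#' @export
paired_pulse_ratio <- function(amp1, amp2) {
  if (any(!is.finite(amp1)) || any(abs(amp1) == 0))
    abort("first-pulse amplitude must be non-zero",
          class = "spinemorph_parameter_error")
  abs(amp2) / abs(amp1)
}

#' NMDAR/AMPAR amplitude ratio
#'
#' Ratio of isolated NMDAR current (recorded at +40 mV) to AMPAR current
#' (at -70 mV), in percent; magnitudes are used so the voltage-dependent
#' sign convention of the raw currents does not matter.
#'
#' @param nmdar_amp,ampar_amp Current amplitudes, pA.
#' @return Percent.
#' @examples
#' nmdar_ampar_ratio(36, -100) # 36
#' @export
nmdar_ampar_ratio <- function(nmdar_amp, ampar_amp) {
  if (any(!is.finite(ampar_amp)) || any(abs(ampar_amp) == 0))
    abort("AMPAR amplitude must be non-zero",
          class = "spinemorph_parameter_error")
  abs(nmdar_amp) / abs(ampar_amp) * 100
}

#' Tonic current shift under an antagonist
#'
#' Difference between the mean holding current over the last minute of
#' baseline and the last minute of a drug application window.
#'
#' @param holding A data frame with `time_s` and `holding_pa`.
#' @param drug_onset Drug application onset, s.
#' @param drug_duration Application length, s (6 min default).
#' @param window Averaging window, s (last minute by default).
#' @return Shift in pA (baseline minus post-drug).
#' @export
tonic_current_shift <- function(holding, drug_onset, drug_duration = 360,
                                window = 60) {
  t <- holding$time_s
  h <- holding$holding_pa
  b1 <- drug_onset - window
  p0 <- drug_onset + drug_duration - window
  p1 <- drug_onset + drug_duration
  if (b1 < min(t) || p1 > max(t))
    abort("averaging windows fall outside the recorded series",
          class = "spinemorph_parameter_error")
  in_b <- t >= b1 & t < drug_onset
  in_p <- t >= p0 & t <= p1
  if (!any(in_b) || !any(in_p))
    abort("averaging windows hold no samples",
          class = "spinemorph_parameter_error")
  mean(h[in_b]) - mean(h[in_p])
}

#' Displacement index for the object-displacement task
#'
#' `(T_novel * 100) / (T_novel + T_familiar)`: the percentage of object
#' exploration time spent on the displaced object.
#'
#' @param t_novel,t_familiar Exploration times, s (vectorized).
#' @return Percent.
#' @examples
#' displacement_index(68.2, 31.8) # 68.2
#' @export
displacement_index <- function(t_novel, t_familiar) {
  if (any(!is.finite(t_novel)) || any(!is.finite(t_familiar)) ||
      any(t_novel < 0) || any(t_familiar < 0))
    abort("exploration times must be finite and >= 0",
          class = "spinemorph_parameter_error")
  tot <- t_novel + t_familiar
  if (any(tot == 0))
    abort("displacement index undefined when both times are zero",
          class = "spinemorph_undefined_index_error")
  t_novel * 100 / tot
}

#' Fraction of time in the novel arm of a Y-maze
#'
#' @param arm_times Named numeric vector (or list) of per-arm occupancy
#'   times, s.
#' @param novel_arm Name (or index) of the novel arm.
#' @return Percent of total time spent in the novel arm.
#' @examples
#' novel_arm_fraction(c(novel = 40.5, start = 30, other = 29.5), "novel")
#' @export
novel_arm_fraction <- function(arm_times, novel_arm) {
  arm_times <- unlist(arm_times)
  if (any(!is.finite(arm_times)) || any(arm_times < 0))
    abort("arm times must be finite and >= 0",
          class = "spinemorph_parameter_error")
  tot <- sum(arm_times)
  if (tot == 0) abort("total arm time is zero",
                      class = "spinemorph_parameter_error")
  arm_times[[novel_arm]] / tot * 100
}

#' Specific radioligand binding per mg protein
#'
#' Specific binding is total minus non-specific binding, normalized to the
#' protein amount. Duplicate assay points (same `id`) are averaged before
#' subtraction. Noise in duplicates can push the difference below zero;
#' such values are clipped to 0 and flagged rather than treated as errors.
#'
#' @param total,nonspecific Bound ligand, fmol (vectorized).
#' @param protein Protein, mg.
#' @param id Optional assay-point identifier; duplicates are averaged.
#' @return Tibble with `specific_binding` (fmol/mg), `clipped` flag, and
#'   `id` when given.
#' @examples
#' specific_binding(0.85, 0.10, 0.010) # 75 fmol/mg
#' @export
specific_binding <- function(total, nonspecific, protein, id = NULL) {
  if (any(!is.finite(protein)) || any(protein <= 0))
    abort("`protein` must be positive", class = "spinemorph_parameter_error")
  if (any(total < 0) || any(nonspecific < 0))
    abort("bound amounts must be >= 0", class = "spinemorph_parameter_error")
  df <- tibble::tibble(total = total, nonspecific = nonspecific,
                       protein = protein,
                       id = if (is.null(id)) seq_along(total) else id)
  out <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(total = mean(.data$total),
                     nonspecific = mean(.data$nonspecific),
                     protein = mean(.data$protein), .groups = "drop") |>
    dplyr::mutate(raw = (.data$total - .data$nonspecific) / .data$protein,
                  clipped = .data$raw < 0,
                  specific_binding = pmax(.data$raw, 0)) |>
    dplyr::select("id", "specific_binding", "clipped")
  if (is.null(id)) out$id <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
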