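#' Plot cohort proportional startle scores
#'
#' Group x CS-type bar chart of mean proportional startle amplitudes with
#' standard-error bars, faceted by phase — the standard summary figure of
#' a differential conditioning experiment.
#'
#' @param scores Cohort score tibble (one row per participant with
#'   `group` and the four proportional score columns).
#' @return A ggplot object.
#' @export
plot_cohort_scores <- function(scores) {
  long <- scores |>
    dplyr::select("id", "group", "acq_prop_csp", "acq_prop_csm",
                  "ext_prop_csp", "ext_prop_csm") |>
    tidyr::pivot_longer(-c("id", "group"), names_to = "cell",
                        values_to = "proportional") |>
    dplyr::mutate(
      phase = ifelse(startsWith(.data$cell, "acq"), "acquisition", "extinction"),
      cs_type = ifelse(endsWith(.data$cell, "csp"), "CS+", "CS-")
    ) |>
    dplyr::filter(is.finite(.data$proportional)) |>
    dplyr::summarise(
      mean = mean(.data$proportional),
      sem = stats::sd(.data$proportional) / sqrt(dplyr::n()),
      .by = c("group", "phase", "cs_type")
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$cs_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(y = "startle (proportion of acquisition ITI)",
                  x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a processed trial window
#'
#' Shows the processed startle response curve around one probe, with the
#' baseline window, validity threshold and target window overlaid —
#' useful to eyeball what the detector saw.
#'
#' @param signal A `processed_signal`.
#' @param probe_onset_s Probe onset (session seconds).
#' @param config A [response_window_config()].
#' @param pre_s,post_s Plotted context around the probe.
#' @return A ggplot object.
#' @export
plot_trial <- function(signal, probe_onset_s,
                       config = response_window_config(),
                       pre_s = 0.6, post_s = 0.3) {
  fs <- signal$sampling_rate
  p <- as.integer(round(probe_onset_s * fs)) + 1L
  idx <- max(p - as.integer(pre_s * fs), 1L):min(p + as.integer(post_s * fs),
                                                 length(signal$samples))
  d <- tibble(
    t_ms = (idx - p) * 1000 / fs,
    uv = signal$samples[idx]
  )
  det <- detect_startle_response(signal, probe_onset_s, config)
  thr <- det$baseline_mean + config$threshold_k * det$baseline_sd
  ggplot2::ggplot(d, ggplot2::aes(.data$t_ms, .data$uv)) +
    ggplot2::annotate("rect", xmin = config$amplitude_window_ms[1],
                      xmax = config$amplitude_window_ms[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = thr, linetype = 3, colour = "firebrick") +
    ggplot2::labs(x = "time from probe onset (ms)", y = "processed EMG (uV)",
                  subtitle = sprintf("valid = %s (%s)", det$valid,
                                     det$invalid_reason)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of extinction differential against a covariate
#'
#' The correlation figure: remaining strength of conditioning in
#' extinction against a clinical covariate (default illness duration)
#' within the patient group, with the least-squares line.
#'
#' @param scores Cohort score tibble including the covariate column.
#' @param covariate Covariate column name.
#' @param group Group to plot (default `"MDD"`).
#' @return A ggplot object.
#' @export
plot_extinction_correlation <- function(scores,
                                        covariate = "illness_duration_years",
                                        group = "MDD") {
  d <- scores[scores$group == group &
                is.finite(scores$ext_differential) &
                is.finite(scores[[covariate]]), ]
  ggplot2::ggplot(d, ggplot2::aes(.data[[covariate]], .data$ext_differential)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(y = "extinction differential (CS+ - CS-)", x = covariate) +
    ggplot2::theme_minimal()
}

#' @method autoplot startle_results
#' @export
autoplot.startle_results <- function(object, ...) {
  plot_cohort_scores(object$scores)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
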