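#' Plot the four CTP time-intensity curves
#'
#' Facetted view of enhanced vessel volumes (both sides), collateral ratio,
#' arterial/venous enhancement, and the AV enhancement ratio, with contrast
#' arrival marked.
#'
#' @param object A `"tic_curves"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tic_curves <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(time_s = object$time_s, value = object$vol_occluded_ml,
           series = "occluded", panel = "Enhanced vessel volume (mL)"),
    tibble(time_s = object$time_s, value = object$vol_contralateral_ml,
           series = "contralateral", panel = "Enhanced vessel volume (mL)"),
    tibble(time_s = object$time_s, value = object$cr_percent,
           series = "CR", panel = "Collateral ratio (%)"),
    tibble(time_s = object$time_s, value = object$arterial_hu,
           series = "arterial", panel = "Enhancement (HU)"),
    tibble(time_s = object$time_s, value = object$venous_hu,
           series = "venous", panel = "Enhancement (HU)"),
    tibble(time_s = object$time_s, value = object$av_ratio,
           series = "AV ratio", panel = "AV enhancement ratio")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = attr(object, "arrival_s"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a normalized AV-ratio curve with its landmarks
#'
#' @param object An `"av_curve"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.av_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$normalized)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(0, 0.2, 0.5, 1),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(attr(object, "t_peak_s"),
                                       attr(object, "t_equi_s"),
                                       attr(object, "t_min_s")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Time (s)", y = "Normalized AV ratio") +
    ggplot2::theme_minimal()
}

#' Overlay normalized AV-ratio curves across subjects
#'
#' Display utility: curves can be aligned at the arterial-peak landmark
#' (each subject's peak shifted to time 0) to visualize the shared curve
#' shape across a cohort. Alignment here is purely for plotting; no analysis
#' stage depends on it.
#'
#' @param curves A list of `"av_curve"` objects.
#' @param align_at_peak Shift each curve so its AV-ratio peak sits at 0 s.
#' @return A ggplot.
#' @export
plot_normalized_curves <- function(curves, align_at_peak = TRUE) {
  long <- purrr::imap_dfr(curves, function(cv, i) {
    shift <- if (align_at_peak) attr(cv, "t_peak_s") else 0
    tibble(subject = as.character(i), time_s = cv$time_s - shift,
           normalized = cv$normalized)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$normalized,
                                     group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted",
                        colour = "grey60") +
    ggplot2::labs(x = if (align_at_peak) "Time from arterial peak (s)" else "Time (s)",
                  y = "Normalized AV ratio") +
    ggplot2::theme_minimal()
}

#' Bar chart of the mCTA phase distribution
#'
#' @param phases Output of [summarize_phase_distribution()].
#' @return A ggplot.
#' @export
plot_phase_distribution <- function(phases) {
  long <- tidyr::pivot_longer(phases, -"position", names_to = "phase",
                              values_to = "n")
  long$phase <- factor(long$phase, levels = phase_levels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~position) +
    ggplot2::labs(x = "Contrast acquisition phase", y = "Subjects") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
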