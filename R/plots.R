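#' Plot group-average CNV waveforms at Cz
#'
#' Response-locked group averages for correct trials with the four analysis
#' windows shaded. Negative is plotted downward-positive per the usual
#' mathematical orientation (no axis flipping).
#'
#' @param report An `erp_report`.
#' @param condition "correct" (default) or "error".
#' @return A ggplot object.
#' @export
plot_cnv <- function(report, condition = "correct") {
  w <- dplyr::filter(report$waveforms, .data$kind == "cnv",
                     .data$condition == !!condition)
  wins <- component_windows()$cnv$windows_ms
  shade <- purrr::map_dfr(names(wins), function(n) {
    tibble::tibble(w = n, xmin = wins[[n]][1], xmax = wins[[n]][2])
  })
  ggplot2::ggplot(w, ggplot2::aes(x = .data$time_ms, y = .data$value,
                                  colour = .data$group)) +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.12) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time relative to response (ms)",
                  y = "amplitude (µV/m²)",
                  title = paste("CNV at Cz,", condition, "trials")) +
    ggplot2::theme_minimal()
}

#' Plot FRN waveforms and difference waves at FCz
#'
#' Feedback-locked condition averages per group, plus the correct-minus-
#' error difference wave.
#'
#' @param report An `erp_report`.
#' @return A ggplot object.
#' @export
plot_frn <- function(report) {
  w <- dplyr::filter(report$waveforms, .data$kind == "frn")
  diff <- w |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    dplyr::mutate(value = .data$correct - .data$error,
                  condition = "difference") |>
    dplyr::select("kind", "group", "condition", "time_ms", "value")
  ggplot2::ggplot(dplyr::bind_rows(w, diff),
                  ggplot2::aes(x = .data$time_ms, y = .data$value,
                               colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "time relative to response (ms)",
                  y = "amplitude (µV/m²)",
                  title = "Feedback complex at FCz") +
    ggplot2::theme_minimal()
}

#' Plot the behavioral summary
#'
#' Group mean and SD of the response-category percentages.
#'
#' @param report An `erp_report`.
#' @return A ggplot object.
#' @export
plot_behavior <- function(report) {
  ggplot2::ggplot(report$behavior,
                  ggplot2::aes(x = .data$category, y = .data$mean_pct,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                   ymax = .data$mean_pct + .data$sd_pct),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "% of trials",
                  title = "Response categories by group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.erp_report <- function(object,
                                type = c("cnv", "frn", "behavior"), ...) {
  type <- match.arg(type)
  switch(type,
         cnv = plot_cnv(object, ...),
         frn = plot_frn(object),
         behavior = plot_behavior(object))
}
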