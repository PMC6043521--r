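#' Plot a positional-enrichment logo
#'
#' A ggplot2 rendering of the signed logo: significant residues are drawn
#' as letters at each window position, stacked above the axis when
#' enriched over the background and below when depleted, with height equal
#' to the frequency difference in percentage points.
#'
#' @param object A `phytasp_enrichment` from [positional_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phytasp_enrichment <- function(object, ...) {
  df <- object |>
    filter(.data$significant) |>
    mutate(sign = ifelse(.data$percent_difference >= 0, "enriched",
                         "depleted")) |>
    group_by(.data$position, .data$sign) |>
    arrange(dplyr::desc(abs(.data$percent_difference)), .by_group = TRUE) |>
    mutate(ytop = cumsum(.data$percent_difference),
           y = .data$ytop - .data$percent_difference / 2) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$y,
                                   label = .data$aa,
                                   size = abs(.data$percent_difference),
                                   colour = .data$sign)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(2, 8)) +
    ggplot2::scale_colour_manual(values = c(enriched = "#1b7837",
                                            depleted = "#762a83")) +
    ggplot2::labs(x = NULL, y = "frequency difference (percentage points)") +
    ggplot2::theme_minimal()
}

#' Plot a fluorescence trace with its fitted initial rate
#'
#' @param trace Tibble with `time`, `value`.
#' @param rate Optional `phytasp_rate` fit to overlay.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, rate = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "fluorescence (RFU)") +
    ggplot2::theme_minimal()
  if (!is.null(rate)) {
    scale <- if (rate$unit == "per_hour") 60 else 1
    p <- p + ggplot2::geom_abline(intercept = rate$intercept,
                                  slope = rate$slope / scale,
                                  colour = "#d95f02")
  }
  p
}

#' Plot a pH-activity profile
#'
#' @param profile Output of [ph_profile()].
#' @return A ggplot object.
#' @export
plot_ph_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$pH, .data$percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_optimum),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02",
                                            `FALSE` = "black")) +
    ggplot2::labs(y = "% of maximum activity") +
    ggplot2::theme_minimal()
}

#' Heatmap of a substrate-panel table
#'
#' @param panel Output of [panel_table()].
#' @return A ggplot object.
#' @export
plot_panel <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(.data$substrate, .data$enzyme,
                                      fill = .data$percent_of_max)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "% of max") +
    ggplot2::theme_minimal()
}
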