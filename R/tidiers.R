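#' Tidy methods for phytasp result objects
#'
#' broom-style one-row summaries of fitted/derived objects.
#'
#' @param x A `phytasp_rate`, `phytasp_ttest` or `phytasp_enrichment`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name phytasp-tidiers
NULL

#' @rdname phytasp-tidiers
#' @export
tidy.phytasp_rate <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         unit = c("RFU", paste("RFU", x$unit)))
}

#' @rdname phytasp-tidiers
#' @export
glance.phytasp_rate <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, unit = x$unit,
         window_first = x$window[1], window_last = x$window[2], n = x$n)
}

#' @rdname phytasp-tidiers
#' @export
tidy.phytasp_ttest <- function(x, ...) {
  tibble(estimate = x$mean_a - x$mean_b,
         mean_a = x$mean_a, mean_b = x$mean_b,
         sd_a = x$sd_a, sd_b = x$sd_b, n_a = x$n_a, n_b = x$n_b,
         statistic = x$statistic, df = x$df, p.value = x$p_value,
         method = x$method)
}

#' @rdname phytasp-tidiers
#' @export
glance.phytasp_enrichment <- function(x, ...) {
  tibble(n_windows = attr(x, "n_windows"), alpha = attr(x, "alpha"),
         n_significant = sum(x$significant),
         provenance = attr(x, "provenance") %||% "windows")
}
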