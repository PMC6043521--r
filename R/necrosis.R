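# Otsu threshold on 8-bit values: maximizes the between-class variance;
# the dark class is `value <= threshold`; smallest maximizing threshold.
otsu_threshold <- function(values) {
  h <- tabulate(values + 1L, nbins = 256L)
  n <- sum(h)
  lv <- 0:255
  w0 <- cumsum(h)
  sum0 <- cumsum(h * lv)
  mu_t <- sum0[256] / n
  w0p <- w0 / n
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  between <- ifelse(w0p > 0 & w0p < 1,
                    w0p / (1 - w0p) * (mu0 - mu_t)^2, -Inf)
  lv[which.max(between[1:255])]
}

#' Quantify necrotic leaf area from a scanned image
#'
#' The trypan-blue quantification: convert to grayscale (channel mean for
#' RGB input), remove the near-white scanner background
#' (`leaf mask = gray < white_threshold`), threshold dark necrotic pixels
#' within the mask (Otsu within the mask by default, or a fixed 8-bit
#' cutoff with `dark = gray <= dark_threshold`), and report the percentage
#' of dark pixels in the leaf area.
#'
#' @param image Matrix (grayscale 0..255) or height x width x 3 array.
#' @param white_threshold Background cutoff (default 250 of 255).
#' @param dark_threshold `"otsu"` or a fixed value in 0..255.
#' @return One-row tibble: `leaf_pixels`, `dark_pixels`,
#'   `percent_necrotic`, `white_threshold`, `dark_threshold` (value used).
#' @export
necrotic_fraction <- function(image, white_threshold = 250,
                              dark_threshold = "otsu") {
  if (length(dim(image)) == 3L)
    image <- apply(image[, , 1:3, drop = FALSE], c(1, 2), mean)
  gray <- round(as.numeric(image))
  if (any(gray < 0 | gray > 255))
    abort_bad_arg("image values must lie in 0..255.")
  leaf <- gray[gray < white_threshold]
  if (length(leaf) == 0L)
    abort_bad_arg("empty leaf mask: no pixels below the white threshold.")
  th <- if (identical(dark_threshold, "otsu")) otsu_threshold(as.integer(leaf))
        else check_number(dark_threshold, "dark_threshold", 0, 255)
  dark <- sum(leaf <= th)
  tibble(leaf_pixels = length(leaf), dark_pixels = dark,
         percent_necrotic = 100 * dark / length(leaf),
         white_threshold = white_threshold, dark_threshold = th)
}

#' Unpaired two-sample t-test
#'
#' Classic Student's t-test with pooled variance (the plain "unpaired
#' t-test" of group comparisons in leaf-necrosis and electrolyte-leakage
#' assays); `var_equal = FALSE` gives the Welch variant.  Degenerate
#' zero-variance input is handled by convention: identical means give
#' t = 0, p = 1; different means with zero pooled variance are an error.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param var_equal Pooled-variance t (default `TRUE`).
#' @return An object of class `phytasp_ttest` with fields `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `n_a`, `n_b`, `statistic`, `df`, `p_value`;
#'   see [tidy()].
#' @export
#' @examples
#' unpaired_ttest(rnorm(10), rnorm(10) + 2)$p_value
unpaired_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b))))
    abort_bad_arg("both groups need >= 2 finite values.")
  pooled0 <- stats::var(a) == 0 && stats::var(b) == 0
  if (pooled0) {
    if (mean(a) != mean(b))
      abort_bad_arg("zero variance with different means: t is undefined.")
    tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
               p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (var_equal) "pooled" else "welch"),
            class = "phytasp_ttest")
}

#' @export
print.phytasp_ttest <- function(x, ...) {
  cat(sprintf("<unpaired t-test (%s)> t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}
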