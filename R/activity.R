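ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sst <- sum((y - my)^2)
  ssr <- sum(res^2)
  r2 <- if (sst <= 0) {
    if (ssr <= 1e-12) 1 else 0
  } else {
    max(0, 1 - ssr / sst)
  }
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' Initial reaction rate from a fluorescence trace
#'
#' Ordinary least-squares slope of fluorescence versus time over a
#' selected window.  The default policy (`window = "auto"`) scans all
#' contiguous prefixes of the trace covering at least `min_frac` of the
#' points and keeps the best-r-squared fit (the longest such prefix on
#' ties), capturing the initial linear phase of a progress curve;
#' `window = "full"` fits the whole trace, and an integer pair fits a
#' fixed point range.  Rates are reported per minute or per hour.
#'
#' @param trace Tibble with `time` (minutes, strictly increasing) and
#'   `value` columns.
#' @param window `"auto"`, `"full"`, or `c(first, last)` point indices.
#' @param min_frac Minimum fraction of points in the auto window.
#' @param unit `"per_min"` or `"per_hour"`.
#' @return An object of class `phytasp_rate` with fields `slope`,
#'   `intercept`, `r_squared`, `window`, `unit`, `n`; see [tidy()] /
#'   [glance()].
#' @export
#' @examples
#' initial_rate(simulate_trace(slope = 50, n_points = 10))$slope
initial_rate <- function(trace, window = "auto", min_frac = 0.3,
                         unit = c("per_min", "per_hour")) {
  unit <- match.arg(unit)
  t <- trace$time; y <- trace$value
  n <- length(t)
  if (n < 2L || length(y) != n)
    abort_bad_arg("trace needs >= 2 (time, value) points.")
  if (any(diff(t) <= 0))
    abort_bad_arg("trace times must be strictly increasing.")
  if (identical(window, "auto")) {
    kmin <- max(2L, ceiling(min_frac * n))
    fits <- map(kmin:n, function(k) c(k = k, unlist(ols_fit(t[1:k], y[1:k]))))
    fits <- do.call(rbind, fits)
    best <- fits[max(which(fits[, "r_squared"] >= max(fits[, "r_squared"]) -
                             1e-12)), ]
    win <- c(1L, as.integer(best["k"]))
    fit <- as.list(best[c("slope", "intercept", "r_squared")])
  } else {
    win <- if (identical(window, "full")) c(1L, n) else as.integer(window)
    if (win[1] < 1L || win[2] > n || win[2] - win[1] < 1L)
      abort_bad_arg("`window` must select >= 2 points within the trace.")
    idx <- win[1]:win[2]
    fit <- ols_fit(t[idx], y[idx])
  }
  scale <- if (unit == "per_hour") 60 else 1
  structure(list(slope = fit$slope * scale, intercept = fit$intercept,
                 r_squared = fit$r_squared, window = win, unit = unit,
                 n = n),
            class = "phytasp_rate")
}

#' @export
print.phytasp_rate <- function(x, ...) {
  cat(sprintf("<initial rate> %.4g RFU %s (r^2 = %.4f, points %d-%d of %d)\n",
              x$slope, sub("_", " ", x$unit), x$r_squared,
              x$window[1], x$window[2], x$n))
  invisible(x)
}

#' pH-activity profile as percent of maximum
#'
#' Normalizes per-pH rates to the maximum and reports the optimum pH (the
#' argmax; no interpolation; the lower pH wins ties).
#'
#' @param rates Tibble with `pH` and `slope` columns, or a named numeric
#'   vector (names = pH values).
#' @return Tibble with `pH`, `slope`, `percent`, `is_optimum`, sorted by
#'   pH; attribute `optimum`.
#' @export
#' @examples
#' ph_profile(c("5.5" = 10, "6.0" = 50, "6.5" = 100, "7.0" = 40))
ph_profile <- function(rates) {
  if (!is.data.frame(rates))
    rates <- tibble(pH = as.numeric(names(rates)), slope = unname(rates))
  rates <- as_tibble(rates)
  if (nrow(rates) < 2L) abort_bad_arg("need rates at >= 2 pH values.")
  mx <- max(rates$slope)
  if (mx <= 0) abort_bad_arg("all rates are <= 0; no pH optimum.")
  out <- rates |>
    arrange(.data$pH) |>
    mutate(percent = 100 * .data$slope / mx,
           is_optimum = FALSE)
  out$is_optimum[which(out$slope == mx)[1]] <- TRUE
  attr(out, "optimum") <- out$pH[out$is_optimum]
  out
}

#' Substrate-panel comparison table
#'
#' Reports raw and per-enzyme percent-of-maximum hydrolysis rates for a
#' fluorogenic peptide panel, and flags each enzyme's preferred (top)
#' substrate (lexicographically first on ties).  Enzymes with no activity
#' (all rates <= 0) get no top substrate and are flagged.
#'
#' @param rates Tibble with `enzyme`, `substrate`, `rate` columns, or a
#'   matrix (rows = enzymes, columns = substrates).
#' @return Tibble with `enzyme`, `substrate`, `rate`, `percent_of_max`,
#'   `is_top`, `no_activity`.
#' @export
panel_table <- function(rates) {
  if (is.matrix(rates)) {
    rates <- as_tibble(rates, rownames = "enzyme") |>
      pivot_longer(-"enzyme", names_to = "substrate", values_to = "rate")
  }
  rates <- as_tibble(rates)
  if (nrow(rates) == 0L) abort_bad_arg("empty rate table.")
  rates |>
    group_by(.data$enzyme) |>
    arrange(.data$substrate, .by_group = TRUE) |>
    mutate(
      no_activity = max(.data$rate) <= 0,
      percent_of_max = ifelse(.data$no_activity, NA_real_,
                              100 * .data$rate / max(.data$rate)),
      is_top = !.data$no_activity &
        row_number() == which.max(.data$rate)) |>
    ungroup()
}

#' Score a fluorogenic peptide under a specificity model
#'
#' AFC-conjugated panel substrates place their C-terminal residue at P1
#' (the fluorophore occupies the prime side), so a peptide of length L
#' fills window positions P-L...P1; positions without a residue contribute
#' 0.  The score is the sum of the model weights over the available
#' positions, linking a PICS-derived profile to panel substrates.
#'
#' @param model A [specificity_model()].
#' @param peptide Peptide string(s), C-terminus = P1 (vectorized).
#' @return Numeric score(s).
#' @export
#' @examples
#' score_peptide(strict_asp_model(), c(VEID = "VEID", VEIA = "VEIA"))
score_peptide <- function(model, peptide) {
  if (!inherits(model, "phytasp_specificity"))
    abort_bad_arg("`model` must come from specificity_model().")
  w <- model$weights
  vapply(peptide, function(p) {
    res <- str_split(p, "")[[1]]
    L <- length(res)
    if (L == 0L) abort_bad_arg("empty peptide.")
    if (anyNA(match(res, aa_alphabet())))
      abort_bad_arg("peptide must contain canonical residues only.")
    ks <- seq_len(min(L, 6L)) - 1L      # k residues upstream of P1
    sum(w[cbind(6L - ks, match(res[L - ks], aa_alphabet()))])
  }, numeric(1))
}
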