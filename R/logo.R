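#' Amino-acid background frequencies of a proteome
#'
#' Counts canonical residues over all sequences; `X` and pad symbols are
#' excluded from both numerator and denominator.  This plays the role of
#' the natural-abundance reference (e.g. the tomato proteome) against which
#' positional enrichment is tested.
#'
#' @param proteins Tibble with `sequence` column, named character vector,
#'   or a single string.
#' @return Tibble with columns `aa`, `freq`, `n_residues` (total canonical
#'   residues counted, identical in every row).
#' @export
#' @examples
#' background_frequencies("DHDH")
background_frequencies <- function(proteins) {
  if (is.character(proteins) && is.null(names(proteins)) &&
      length(proteins) >= 1L) {
    seqs <- proteins
  } else {
    seqs <- as_protein_tbl(proteins)$sequence
  }
  chars <- str_split(paste(seqs, collapse = ""), "")[[1]]
  chars <- chars[chars %in% aa_alphabet()]
  if (length(chars) == 0L)
    abort_bad_arg("no canonical residues in the proteome.")
  counts <- table(factor(chars, levels = aa_alphabet()))
  tibble(aa = aa_alphabet(), freq = as.numeric(counts) / length(chars),
         n_residues = length(chars))
}

bg_freq_vector <- function(background) {
  if (is.character(background) && length(background) == 1L &&
      background %in% c("uniform", "arabidopsis"))
    return(aa_frequencies(background))
  if (is.data.frame(background)) {
    f <- setNames(background$freq, background$aa)
  } else {
    f <- background
  }
  check_aa_freqs(f)
}

# Two-sided exact binomial p-value: double the smaller tail (each tail
# including the observed count), capped at 1.
exact_binom_p <- function(k, n, p0) {
  if (n == 0L) return(1)
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1L, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Positional amino-acid enrichment of cleavage windows
#'
#' For every window position (P6...P6') and every canonical residue,
#' compares the sample frequency among the windows against the background
#' proteome composition, as in iceLogo-style consensus displays: the
#' reported effect is `percent_difference = 100 * (sample_freq - bg_freq)`
#' and a cell is significant when its p-value is below `alpha`.  The
#' default statistic is a two-sided exact binomial test of the residue
#' count at that position against the background frequency (smaller tail
#' doubled and capped at 1); `method = "zscore"` gives the normal
#' approximation for cross-checking.  Pad symbols (`-`) at boundary
#' positions reduce that position's `n` rather than counting as a letter.
#' No multiple-testing correction is applied.  `alpha = 1` disables the
#' significance filter entirely (every cell marked significant), since the
#' capped two-sided p-value can equal 1 exactly.
#'
#' @param windows Character vector of 12-mer windows, or a tibble with a
#'   `window` column (e.g. from [call_junction()]).
#' @param background Background composition: output of
#'   [background_frequencies()], a named 20-vector, or a preset name.
#' @param alpha Significance level (default 0.05).
#' @param method `"exact"` (default) or `"zscore"`.
#' @return A tibble of class `phytasp_enrichment` with one row per
#'   position x residue: `position`, `aa`, `sample_count`, `n`,
#'   `sample_freq`, `bg_freq`, `percent_difference`, `p_value`,
#'   `significant`; attributes `n_windows` and `alpha`.
#' @export
positional_enrichment <- function(windows, background, alpha = 0.05,
                                  method = c("exact", "zscore")) {
  method <- match.arg(method)
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) < 1L) abort_bad_arg("need at least one window.")
  if (any(nchar(windows) != 12L))
    abort_bad_arg("windows must be 12 symbols long.")
  alpha <- check_number(alpha, "alpha")
  if (alpha <= 0 || alpha > 1) abort_bad_arg("`alpha` must be in (0, 1].")
  bg <- bg_freq_vector(background)
  mat <- do.call(rbind, str_split(windows, ""))
  cells <- map(seq_len(12L), function(k) {
    col <- mat[, k]
    col <- col[col %in% aa_alphabet()]
    nk <- length(col)
    counts <- as.integer(table(factor(col, levels = aa_alphabet())))
    tibble(position = WINDOW_POSITIONS[k], aa = aa_alphabet(),
           sample_count = counts, n = nk,
           sample_freq = if (nk > 0) counts / nk else NA_real_,
           bg_freq = unname(bg))
  })
  out <- bind_rows(cells) |>
    mutate(
      percent_difference = 100 * (.data$sample_freq - .data$bg_freq),
      p_value = if (method == "exact") {
        map_dbl(row_number(), function(i)
          exact_binom_p(sample_count[i], n[i], bg_freq[i]))
      } else {
        se <- sqrt(.data$n * .data$bg_freq * (1 - .data$bg_freq))
        z <- ifelse(se > 0, (.data$sample_count - .data$n * .data$bg_freq) / se,
                    ifelse(.data$sample_count == .data$n * .data$bg_freq,
                           0, Inf))
        pmin(1, 2 * stats::pnorm(-abs(z)))
      },
      significant = if (alpha >= 1) TRUE else .data$p_value < alpha) |>
    mutate(position = factor(.data$position, levels = WINDOW_POSITIONS))
  attr(out, "n_windows") <- length(windows)
  attr(out, "alpha") <- alpha
  class(out) <- c("phytasp_enrichment", class(out))
  out
}

#' Signed letter heights for an enrichment logo
#'
#' Heights equal `percent_difference` for significant cells and 0
#' elsewhere; enriched residues are positive (drawn above the axis),
#' depleted residues negative.
#'
#' @param enrichment Output of [positional_enrichment()].
#' @return A 12 x 20 numeric matrix (positions x residues).
#' @export
logo_matrix <- function(enrichment) {
  m <- enrichment |>
    mutate(height = ifelse(.data$significant, .data$percent_difference, 0)) |>
    select("position", "aa", "height") |>
    pivot_wider(names_from = "aa", values_from = "height")
  out <- as.matrix(m[, aa_alphabet()])
  rownames(out) <- as.character(m$position)
  out
}
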