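#' The canonical amino-acid alphabet
#'
#' Generators and statistics in this package are restricted to the 20
#' canonical residues; `X` is tolerated on input (flagged and excluded from
#' composition statistics) but never emitted.
#'
#' @return Character vector of the 20 one-letter residue codes, in the fixed
#'   order used by every frequency vector and weight matrix in the package.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Preset amino-acid background compositions
#'
#' `"uniform"` gives each residue probability 0.05.  `"arabidopsis"` is a
#' plant-proteome-like composition (rounded literature values for the
#' Arabidopsis thaliana proteome, renormalized), useful when a synthetic
#' background should resemble a real plant proteome rather than a uniform
#' one.
#'
#' @param preset `"uniform"` or `"arabidopsis"`.
#' @return Named numeric vector over [aa_alphabet()], summing to 1.
#' @export
#' @examples
#' aa_frequencies("arabidopsis")["D"]
aa_frequencies <- function(preset = c("uniform", "arabidopsis")) {
  preset <- match.arg(preset)
  if (preset == "uniform")
    return(setNames(rep(1 / 20, 20), aa_alphabet()))
  f <- c(A = 0.063, C = 0.018, D = 0.054, E = 0.067, F = 0.043,
         G = 0.064, H = 0.023, I = 0.052, K = 0.064, L = 0.096,
         M = 0.025, N = 0.043, P = 0.047, Q = 0.035, R = 0.054,
         S = 0.090, T = 0.049, V = 0.067, W = 0.012, Y = 0.029)
  f / sum(f)
}

check_aa_freqs <- function(aa_freqs) {
  if (is.null(names(aa_freqs))) names(aa_freqs) <- aa_alphabet()
  if (length(aa_freqs) != 20L || !setequal(names(aa_freqs), aa_alphabet()))
    abort_bad_arg("`aa_freqs` must be a 20-entry vector named by aa_alphabet().")
  aa_freqs <- aa_freqs[aa_alphabet()]
  if (any(!is.finite(aa_freqs)) || any(aa_freqs < 0))
    abort_bad_arg("`aa_freqs` entries must be finite and nonnegative.")
  if (abs(sum(aa_freqs) - 1) > 1e-9)
    abort_bad_arg("`aa_freqs` must sum to 1 within 1e-9.")
  aa_freqs
}

#' BLOSUM62 substitution matrix with conservative treatment of X
#'
#' Returns the BLOSUM62 matrix restricted to the 20 canonical residues plus
#' `X`.  Scores involving `X` are replaced by the worst (minimum) score of
#' the corresponding canonical row/column, so that unknown residues can
#' never create alignment signal.
#'
#' @return A 21 x 21 integer matrix with dimnames.
#' @export
blosum62 <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  m <- data_env$BLOSUM62
  keep <- c(aa_alphabet(), "X")
  m <- m[keep, keep]
  worst <- apply(m[aa_alphabet(), aa_alphabet()], 2, min)
  m["X", aa_alphabet()] <- worst
  m[aa_alphabet(), "X"] <- worst
  m["X", "X"] <- min(worst)
  m
}
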