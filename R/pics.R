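#' Digestion rules for peptide-library generation
#'
#' Site rules for the library-generating protease of a PICS experiment:
#' trypsin cleaves after Lys/Arg, chymotrypsin after Phe/Tyr/Trp/Leu, both
#' blocked when the next residue is Pro.  There is no default enzyme - the
#' choice must be explicit.
#'
#' @param enzyme `"trypsin"` or `"chymotrypsin"`, or `NULL` when
#'   `cleave_after` is given directly.
#' @param cleave_after Custom residue set to cleave after.
#' @param block_before_proline Suppress cleavage before Pro (default
#'   `TRUE`).
#' @param min_len,max_len Peptide length bounds retained in the library
#'   (default 8-30, the MS-observable range).
#' @return A `phytasp_digestion` rule list.
#' @export
digestion_rules <- function(enzyme = c("trypsin", "chymotrypsin"),
                            cleave_after = NULL,
                            block_before_proline = TRUE,
                            min_len = 8L, max_len = 30L) {
  if (is.null(cleave_after)) {
    enzyme <- match.arg(enzyme)
    cleave_after <- switch(enzyme, trypsin = c("K", "R"),
                           chymotrypsin = c("F", "Y", "W", "L"))
  } else {
    enzyme <- "custom"
    if (length(cleave_after) == 0L)
      abort_bad_arg("`cleave_after` must be non-empty.")
  }
  min_len <- check_count(min_len, "min_len", 1L)
  max_len <- check_count(max_len, "max_len", min_len)
  structure(list(enzyme = enzyme, cleave_after = cleave_after,
                 block_before_proline = block_before_proline,
                 min_len = min_len, max_len = max_len),
            class = "phytasp_digestion")
}

#' Digest a proteome into a peptide library
#'
#' Cleaves every protein after each residue in the rule's site set, except
#' where the following residue is Pro (if blocked); zero missed cleavages.
#' Fragments outside the rule's length bounds are dropped; source protein
#' and 1-based start offset are recorded for every retained peptide.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param rules A [digestion_rules()] object.
#' @return Tibble of class `phytasp_library`: `peptide_id`, `peptide`,
#'   `protein_id`, `start`.
#' @export
#' @examples
#' digest(tibble::tibble(id = "p", sequence = "MKRA"),
#'        digestion_rules("trypsin", min_len = 1))
digest <- function(proteins, rules) {
  if (!inherits(rules, "phytasp_digestion"))
    abort_bad_arg("`rules` must come from digestion_rules().")
  proteins <- as_protein_tbl(proteins)
  rows <- map(seq_len(nrow(proteins)), function(i) {
    res <- str_split(proteins$sequence[i], "")[[1]]
    L <- length(res)
    cut <- res %in% rules$cleave_after
    if (rules$block_before_proline && L > 1L)
      cut[seq_len(L - 1L)][res[-1L] == "P"] <- FALSE
    cut[L] <- FALSE                      # C-terminus is not a cut site
    ends <- c(which(cut), L)
    starts <- c(1L, head(ends, -1L) + 1L)
    tibble(peptide = substring(proteins$sequence[i], starts, ends),
           protein_id = proteins$id[i], start = starts)
  })
  out <- bind_rows(rows) |>
    filter(nchar(.data$peptide) >= rules$min_len,
           nchar(.data$peptide) <= rules$max_len) |>
    mutate(peptide_id = sprintf("pep_%06d", row_number())) |>
    select("peptide_id", "peptide", "protein_id", "start")
  class(out) <- c("phytasp_library", class(out))
  out
}

#' Position-weight specificity model over the P6...P6' window
#'
#' A 12 x 20 log-odds-style score matrix defining a protease's cleavage
#' preference.  The score of a bond is the sum of weights over the window
#' residues; pad positions (beyond a peptide boundary) contribute 0, so
#' boundary bonds are neither favored nor excluded.  In `"threshold"` mode
#' a bond is cleaved iff its score reaches `tau`; in `"bernoulli"` mode it
#' is cleaved with probability `plogis(steepness * (score - tau))`.
#'
#' @param weights 12 x 20 numeric matrix (rows P6..P1,P1'..P6', columns
#'   [aa_alphabet()]); defaults to all-zero.
#' @param mode `"threshold"` or `"bernoulli"`.
#' @param tau Score cutoff.
#' @param steepness Logistic slope (bernoulli mode).
#' @return A `phytasp_specificity` object.
#' @export
specificity_model <- function(weights = NULL,
                              mode = c("threshold", "bernoulli"),
                              tau = 5, steepness = 1) {
  mode <- match.arg(mode)
  if (is.null(weights))
    weights <- matrix(0, 12L, 20L,
                      dimnames = list(WINDOW_POSITIONS, aa_alphabet()))
  if (!is.matrix(weights) || !identical(dim(weights), c(12L, 20L)) ||
      any(!is.finite(weights)))
    abort_bad_arg("`weights` must be a finite 12 x 20 matrix.")
  dimnames(weights) <- list(WINDOW_POSITIONS, aa_alphabet())
  tau <- check_number(tau, "tau")
  structure(list(weights = weights, mode = mode, tau = tau,
                 steepness = check_number(steepness, "steepness")),
            class = "phytasp_specificity")
}

#' Strict Asp-P1 specificity model
#'
#' The caspase-like ground truth used throughout the synthetic PICS
#' experiments: weight `bonus` for Asp at P1, `penalty` for any other P1
#' residue, 0 elsewhere, cleaving in threshold mode at `tau`.  Additional
#' positional preferences (e.g. Ile at P4) can be layered on via `extra`.
#'
#' @param bonus,penalty P1 weights for Asp / non-Asp.
#' @param tau Score cutoff.
#' @param extra Named list of positions, each a named numeric vector of
#'   residue weights, e.g. `list("P4" = c(I = 6))`.
#' @param mode,steepness Passed to [specificity_model()].
#' @return A `phytasp_specificity` object.
#' @export
strict_asp_model <- function(bonus = 10, penalty = -10, tau = 5,
                             extra = list(), mode = "threshold",
                             steepness = 1) {
  w <- matrix(0, 12L, 20L, dimnames = list(WINDOW_POSITIONS, aa_alphabet()))
  w["P1", ] <- penalty
  w["P1", "D"] <- bonus
  for (pos in names(extra)) w[pos, names(extra[[pos]])] <-
      w[pos, names(extra[[pos]])] + extra[[pos]]
  specificity_model(w, mode = mode, tau = tau, steepness = steepness)
}

# All bond scores for each peptide under a specificity model.
peptide_bond_scores <- function(peptides, model) {
  enc <- map(str_split(peptides, ""), function(r) match(r, aa_alphabet()) - 1L)
  if (any(map_int(enc, anyNA) > 0))
    abort_bad_arg("peptides must contain canonical residues only.")
  bond_scores_cpp(enc, model$weights)
}

#' Simulate protease cleavage of a peptide library
#'
#' Scores every internal bond of every peptide under the specificity model
#' and cleaves per the model's mode.  At most one cut per peptide is
#' retained - the highest-scoring cleaved bond, leftmost on ties -
#' mirroring single-event detection per library peptide in PICS; events
#' whose prime (C-terminal) fragment is shorter than `min_prime` residues
#' are dropped as unidentifiable.
#'
#' @param library A [digest()] library.
#' @param model A [specificity_model()].
#' @param seed Integer seed (used by bernoulli mode).
#' @param min_prime Minimum prime-fragment length (default 4).
#' @return Tibble of cleavage events: `peptide_id`, `protein_id`,
#'   `peptide`, `cut_index` (bond after this many residues),
#'   `score`, `prime_fragment`, `true_window`.
#' @export
simulate_cleavage <- function(library, model, seed = 1L, min_prime = 4L) {
  if (!inherits(model, "phytasp_specificity"))
    abort_bad_arg("`model` must come from specificity_model().")
  scores <- peptide_bond_scores(library$peptide, model)
  pick <- function(sc, cleaved) {
    idx <- which(cleaved)
    if (length(idx) == 0L) return(NA_integer_)
    idx[which.max(sc[idx])]   # which.max takes the leftmost maximum
  }
  cuts <- with_seed(seed, {
    map_int(seq_along(scores), function(i) {
      sc <- scores[[i]]
      if (length(sc) == 0L) return(NA_integer_)
      cleaved <- if (model$mode == "threshold") {
        sc >= model$tau
      } else {
        runif(length(sc)) < stats::plogis(model$steepness * (sc - model$tau))
      }
      pick(sc, cleaved)
    })
  })
  keep <- !is.na(cuts)
  ev <- library[keep, , drop = FALSE]
  cuts <- cuts[keep]
  kept_scores <- scores[keep]
  out <- ev |>
    mutate(cut_index = cuts,
           score = map_dbl(seq_along(cuts),
                           function(i) kept_scores[[i]][cuts[i]]),
           prime_fragment = substring(.data$peptide, cuts + 1L),
           true_window = map_chr(seq_along(cuts), function(i)
             extract_window(.data$peptide[i], cuts[i]))) |>
    filter(nchar(.data$prime_fragment) >= min_prime) |>
    select("peptide_id", "protein_id", "peptide", "cut_index", "score",
           "prime_fragment", "true_window")
  out
}

#' Reconstruct cleavage sites from prime-side fragments
#'
#' The in-silico analog of WebPICS database lookup: each observed prime
#' fragment is located as a proper suffix of library peptides.  A unique
#' hit lets the non-prime side be read off the source peptide and the full
#' P6...P6' window rebuilt (with pads at peptide boundaries); fragments
#' with zero or multiple hits are discarded and counted in the ambiguity
#' report.
#'
#' @param prime_fragments Character vector of fragment sequences.
#' @param library The [digest()] library the fragments came from.
#' @return List with `windows` (tibble: `fragment`, `fragment_index` into
#'   `prime_fragments`, `peptide_id`, `cut_index`, `window`) and
#'   `ambiguity` (tibble: `fragment`, `fragment_index`, `n_hits` for every
#'   discarded fragment instance).
#' @export
reconstruct_sites <- function(prime_fragments, library) {
  peps <- library$peptide
  nlen <- nchar(peps)
  key <- substr(peps, nlen - 3L, nlen)
  index <- split(seq_along(peps), key)
  win_rows <- list(); amb_rows <- list()
  for (i in seq_along(prime_fragments)) {
    frag <- prime_fragments[i]
    fl <- nchar(frag)
    cand <- if (fl >= 4L) index[[substr(frag, fl - 3L, fl)]] else seq_along(peps)
    cand <- cand[nlen[cand] > fl]
    hits <- cand[str_ends(peps[cand], frag)]
    if (length(hits) == 1L) {
      cut <- nlen[hits] - fl
      win_rows[[length(win_rows) + 1L]] <-
        tibble(fragment = frag, fragment_index = i,
               peptide_id = library$peptide_id[hits], cut_index = cut,
               window = extract_window(peps[hits], cut))
    } else {
      amb_rows[[length(amb_rows) + 1L]] <-
        tibble(fragment = frag, fragment_index = i, n_hits = length(hits))
    }
  }
  list(windows = bind_rows(win_rows), ambiguity = bind_rows(amb_rows))
}

#' Positional specificity profile from reconstructed windows
#'
#' Delegates to [positional_enrichment()] and marks the result as
#' PICS-derived.
#'
#' @param windows Reconstructed windows (character vector or tibble with a
#'   `window` column, e.g. `reconstruct_sites()$windows`).
#' @param background Background composition (see
#'   [positional_enrichment()]).
#' @param alpha Significance level.
#' @return A `phytasp_enrichment` tibble with attribute
#'   `provenance = "PICS"`.
#' @export
specificity_profile <- function(windows, background, alpha = 0.05) {
  if (is.data.frame(windows)) windows <- windows$window
  if (length(windows) == 0L)
    abort_bad_arg("no windows left after ambiguity filtering.")
  out <- positional_enrichment(windows, background, alpha = alpha)
  attr(out, "provenance") <- "PICS"
  out
}
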