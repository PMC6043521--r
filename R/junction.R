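WINDOW_POSITIONS <- c("P6", "P5", "P4", "P3", "P2", "P1",
                      "P1'", "P2'", "P3'", "P4'", "P5'", "P6'")

#' Extract the P6...P6' cleavage window around a scissile bond
#'
#' `cut_index` counts the residues on the non-prime side of the bond, so
#' P1 is `substr(sequence, cut_index, cut_index)` and P1' follows it.
#' Positions beyond the sequence boundary are padded with `-`; the bond
#' itself must have a residue on both sides.
#'
#' @param sequence Amino-acid string.
#' @param cut_index Integer with `0 < cut_index < nchar(sequence)`.
#' @return A 12-character string, Schechter-Berger order P6..P1,P1'..P6'.
#' @export
#' @examples
#' extract_window("ABCDEFGHIJKL", 6)  # "ABCDEFGHIJKL"
#' extract_window("ABCD", 2)          # "----ABCD----"
extract_window <- function(sequence, cut_index) {
  n <- nchar(sequence)
  cut_index <- check_count(cut_index, "cut_index", min = 1L)
  if (cut_index >= n)
    abort_bad_arg("`cut_index` must leave at least one residue on each side of the bond.")
  res <- str_split(sequence, "")[[1]]
  pos <- (cut_index - 5L):(cut_index + 6L)
  chars <- ifelse(pos >= 1L & pos <= n, res[pmax(pos, 1L)], "-")
  paste(chars, collapse = "")
}

#' Call the prodomain junction by reference-anchored alignment
#'
#' Maps known prodomain junctions from annotated reference subtilases onto
#' query proteins through pairwise local alignment.  For each protein, the
#' reference whose alignment attains the highest score while covering its
#' own junction is used (ties broken by lexicographic reference id); the
#' query position aligned to the reference's first mature residue becomes
#' the called junction.  If that reference column falls in a query gap, the
#' nearest aligned position on the mature side is used and flagged.  A
#' non-fatal warning flag is set when P1'/P2' of the called window are not
#' both Thr (the invariant mature N-terminus of plant subtilases).
#'
#' @param proteins Tibble with `id`, `sequence`; normally the retained set
#'   of [completeness_filter()].
#' @param references Tibble with `id`, `sequence` and `junction_index`
#'   (1-based index of the first mature residue, P1').
#' @param submat,gap_open,gap_extend See [local_align()].
#' @param strict If `TRUE` (default) an uncallable junction is an error;
#'   otherwise the protein is dropped with a message.
#' @return Tibble with `protein_id`, `junction_index` (1-based first mature
#'   residue), `window`, `p1`, `reference_id`, `mapping_score`,
#'   `junction_in_gap`, `thr_warning`.
#' @export
call_junction <- function(proteins, references, submat = blosum62(),
                          gap_open = 11, gap_extend = 1, strict = TRUE) {
  proteins <- as_protein_tbl(proteins)
  references <- as_tibble(references)
  if (!all(c("id", "sequence", "junction_index") %in% names(references)) ||
      nrow(references) == 0L)
    abort_bad_arg("`references` needs columns id, sequence, junction_index.")
  references <- arrange(references, .data$id)
  rows <- map(seq_len(nrow(proteins)), function(i) {
    seq <- proteins$sequence[i]
    best <- NULL
    for (r in seq_len(nrow(references))) {
      jr <- references$junction_index[r]
      al <- local_align(references$sequence[r], seq, submat,
                        gap_open, gap_extend)
      covers <- al$score > 0 && al$query_span[1] <= jr - 1L &&
        al$query_span[2] >= jr
      if (!covers) next
      if (is.null(best) || al$score > best$score) {
        best <- list(score = al$score, al = al, jr = jr,
                     ref = references$id[r])
      }
    }
    if (is.null(best)) {
      msg <- sprintf("junction uncallable for protein '%s': no reference alignment covers a junction.",
                     proteins$id[i])
      if (strict) abort_bad_arg(msg)
      message(msg)
      return(NULL)
    }
    jm <- map_position(best$al, best$jr)
    in_gap <- is.na(jm)
    if (in_gap) {
      mature <- best$al$pairs[best$al$pairs[, "query"] >= best$jr, ,
                              drop = FALSE]
      jm <- mature[1, "target"]
    }
    window <- extract_window(seq, jm - 1L)
    tibble(protein_id = proteins$id[i], junction_index = as.integer(jm),
           window = window, p1 = substr(window, 6L, 6L),
           reference_id = best$ref, mapping_score = best$score,
           junction_in_gap = in_gap,
           thr_warning = substr(window, 7L, 8L) != "TT")
  })
  bind_rows(rows)
}

#' Classify phytaspase candidates
#'
#' Applies the two diagnostic rules: a protein is a phytaspase candidate
#' iff its prodomain junction carries Asp at P1, and candidates are
#' subtyped by the residue at the S1-pocket position homologous to residue
#' 331 of tobacco phytaspase - His-type (true phytaspases), Lys-type, or
#' Gly-type (wider, less polar S1 pocket); any other or unmapped residue
#' gives subtype `"other"`.  Non-candidates always get
#' `"non-candidate"`.
#'
#' @param junctions Output of [call_junction()].
#' @param architecture Output of [annotate_architecture()] (supplies the
#'   mapped `residue331`); alternatively a tibble with `protein_id` and
#'   `residue331`.
#' @return `junctions` with added `residue331`, `is_candidate`, `subtype`.
#' @export
classify_phytaspase <- function(junctions, architecture) {
  res <- junctions |>
    left_join(select(architecture, "protein_id", "residue331"),
              by = "protein_id") |>
    mutate(
      is_candidate = .data$p1 == "D",
      subtype = dplyr::case_when(
        !is_candidate ~ "non-candidate",
        residue331 %in% "H" ~ "His-type",
        residue331 %in% "K" ~ "Lys-type",
        residue331 %in% "G" ~ "Gly-type",
        TRUE ~ "other"))
  res
}

#' Motif-scan junction calling (non-default alternative)
#'
#' Instead of mapping a reference junction through an alignment, scores
#' every internal bond of each protein under a position-weight specificity
#' model (see [specificity_model()]) and calls the junction at the
#' highest-scoring bond (leftmost on ties).  Useful when no annotated
#' reference is available and the junction motif itself (e.g. Asp-P1
#' followed by the invariant Thr-Thr) is distinctive; with a
#' non-separating model it degrades to an arbitrary motif hit, which is
#' why the reference-anchored [call_junction()] is the default.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param model A [specificity_model()] whose weights describe the
#'   junction window.
#' @return Tibble with `protein_id`, `junction_index`, `window`, `p1`,
#'   `motif_score`.
#' @export
call_junction_pwm <- function(proteins, model) {
  proteins <- as_protein_tbl(proteins)
  scores <- peptide_bond_scores(proteins$sequence, model)
  rows <- map(seq_len(nrow(proteins)), function(i) {
    sc <- scores[[i]]
    cut <- which.max(sc)
    window <- extract_window(proteins$sequence[i], cut)
    tibble(protein_id = proteins$id[i], junction_index = cut + 1L,
           window = window, p1 = substr(window, 6L, 6L),
           motif_score = sc[cut])
  })
  bind_rows(rows)
}
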