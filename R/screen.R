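#' Annotate subtilase domain architecture by anchor alignment
#'
#' Locally aligns the S8 (catalytic domain) and I9 (prodomain) reference
#' anchors to every protein.  A domain is deemed present when the alignment
#' score reaches `score_frac` of the anchor's gapless self-alignment score
#' and the aligned anchor footprint covers at least `min_coverage` of the
#' anchor length.  The four catalytic positions of the S8 anchor are mapped
#' through the alignment and counted only where the protein carries the
#' identical residue; the diagnostic S1-pocket position (residue 331 in
#' tobacco phytaspase numbering) is mapped through the same alignment.
#'
#' @param proteins Tibble with `id` and `sequence` (or named character
#'   vector).
#' @param s8_ref,i9_ref Reference anchor sequences.
#' @param catalytic_positions 1-based positions of the catalytic residues
#'   within `s8_ref`.
#' @param residue331_position 1-based position within `s8_ref` homologous
#'   to the diagnostic S1-pocket residue.
#' @param submat,gap_open,gap_extend Alignment parameters, see
#'   [local_align()].
#' @param score_frac Fraction of the anchor self-score required (default
#'   0.5).
#' @param min_coverage Minimum aligned fraction of the anchor (default 0.6).
#' @return Tibble with one row per protein: `protein_id`, `length`,
#'   `s8_present`, `s8_score`, `s8_start`, `s8_end`, `n_catalytic`,
#'   `catalytic_positions` (list column of mapped protein positions),
#'   `residue331`, `i9_present`, `i9_score`.  Absence is encoded, never an
#'   error.
#' @export
annotate_architecture <- function(proteins, s8_ref = s8_anchor(),
                                  i9_ref = i9_anchor(),
                                  catalytic_positions = s8_catalytic_positions(),
                                  residue331_position = s8_residue331_position(),
                                  submat = blosum62(),
                                  gap_open = 11, gap_extend = 1,
                                  score_frac = 0.5, min_coverage = 0.6) {
  proteins <- as_protein_tbl(proteins)
  s8_self <- self_score(s8_ref, submat)
  i9_self <- self_score(i9_ref, submat)
  s8_res <- str_split(s8_ref, "")[[1]]
  rows <- map(seq_len(nrow(proteins)), function(i) {
    seq <- proteins$sequence[i]
    a8 <- local_align(s8_ref, seq, submat, gap_open, gap_extend)
    cov8 <- (a8$query_span[2] - a8$query_span[1] + 1) / nchar(s8_ref)
    s8_present <- a8$score >= score_frac * s8_self && cov8 >= min_coverage
    catpos <- map_int(catalytic_positions, function(p) {
      tp <- map_position(a8, p)
      if (!is.na(tp) && substr(seq, tp, tp) == s8_res[p]) tp else NA_integer_
    })
    r331 <- NA_character_
    tp331 <- map_position(a8, residue331_position)
    if (!is.na(tp331)) r331 <- substr(seq, tp331, tp331)
    a9 <- local_align(i9_ref, seq, submat, gap_open, gap_extend)
    cov9 <- (a9$query_span[2] - a9$query_span[1] + 1) / nchar(i9_ref)
    tibble(protein_id = proteins$id[i], length = nchar(seq),
           s8_present = s8_present, s8_score = a8$score,
           s8_start = a8$target_span[1], s8_end = a8$target_span[2],
           n_catalytic = sum(!is.na(catpos)),
           catalytic_positions = list(catpos),
           residue331 = r331,
           i9_present = a9$score >= score_frac * i9_self &&
             cov9 >= min_coverage,
           i9_score = a9$score)
  })
  bind_rows(rows)
}

#' Completeness filter for subtilase candidates
#'
#' Retains proteins that look like full-length subtilase precursors:
#' length within `[min_length, max_length]` (inclusive), all four
#' catalytically important residues of the S8 domain present, and the I9
#' prodomain present.  The exclusion reason reported per protein is the
#' first failing criterion, in that order.
#'
#' @param architecture Output of [annotate_architecture()].
#' @param min_length,max_length Inclusive residue-length bounds (650-800
#'   for plant subtilases).
#' @return The architecture tibble with added `retained` (logical) and
#'   `exclusion_reason` (`NA`, `"length"`, `"catalytic_residues"` or
#'   `"i9_prodomain"`).  Output is invariant to row order and the filter is
#'   idempotent on its retained set.
#' @export
completeness_filter <- function(architecture, min_length = 650L,
                                max_length = 800L) {
  architecture |>
    mutate(
      exclusion_reason = dplyr::case_when(
        length < min_length | length > max_length ~ "length",
        n_catalytic < 4L ~ "catalytic_residues",
        !i9_present ~ "i9_prodomain",
        TRUE ~ NA_character_),
      retained = is.na(exclusion_reason))
}

#' Detect tandem gene arrays
#'
#' Clusters family members that lie close together on the same chromosome:
#' a cluster is a maximal run of genes (ordered by start) in which
#' consecutive start positions differ by at most `max_gap_kb` kilobases.
#' Singletons are reported as size-1 clusters.
#'
#' @param coords Tibble with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (1-based inclusive base pairs; only family members should be
#'   supplied).
#' @param max_gap_kb Maximum start-to-start gap within a cluster, in kb.
#' @return `coords` sorted by position with `cluster_id` and `cluster_size`
#'   columns.
#' @export
find_tandem_arrays <- function(coords, max_gap_kb = 100) {
  coords <- as_tibble(coords)
  if (anyDuplicated(coords$gene_id))
    abort_bad_arg("duplicate gene_id in coordinates.")
  if (any(coords$start > coords$end))
    abort_bad_arg("gene coordinates must satisfy start <= end.")
  coords |>
    arrange(.data$chromosome, .data$start) |>
    group_by(.data$chromosome) |>
    mutate(new_cluster = is.na(lag(.data$start)) |
             .data$start - lag(.data$start) > max_gap_kb * 1000) |>
    ungroup() |>
    mutate(cluster_id = cumsum(.data$new_cluster)) |>
    group_by(.data$cluster_id) |>
    mutate(cluster_size = n()) |>
    ungroup() |>
    select(-"new_cluster")
}
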