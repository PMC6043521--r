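#' Read and write protein FASTA files
#'
#' Thin tidy wrappers around Biostrings.  `read_fasta()` tolerates wrapped
#' lines and CRLF line endings and returns one row per record; sequences
#' containing `X` are accepted and flagged in the `has_x` column.
#'
#' @param path File path.
#' @param proteins A tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @return `read_fasta()`: a tibble with columns `id`, `description`,
#'   `sequence`, `has_x`.  `write_fasta()`: the input, invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), NA_character_)
  as_protein_tbl(tibble(id = id, sequence = toupper(as.character(ss)),
                        description = desc))[, c("id", "description",
                                                 "sequence", "has_x")]
}

#' @rdname read_fasta
#' @export
write_fasta <- function(proteins, path) {
  proteins <- as_protein_tbl(proteins)
  ss <- Biostrings::AAStringSet(proteins$sequence)
  names(ss) <- ifelse(is.na(proteins$description), proteins$id,
                      paste(proteins$id, proteins$description))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(proteins)
}

#' Read gene coordinates from a GFF3 file
#'
#' Extracts `gene` features (1-based inclusive coordinates, as in GFF3) into
#' the tibble layout expected by [find_tandem_arrays()].  Requires the
#' rtracklayer package.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return Tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_coordinates <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort_bad_arg("read_gene_coordinates() requires the rtracklayer package.")
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == feature_type, , drop = FALSE]
  id <- if ("ID" %in% names(g)) as.character(g$ID) else as.character(g$Name)
  tibble(gene_id = id, chromosome = as.character(g$seqid),
         start = as.integer(g$start), end = as.integer(g$end),
         strand = as.character(g$strand))
}

#' Read a fluorescence trace from CSV
#'
#' Expects at least `time` and `value` columns (time in minutes, value in
#' relative fluorescence units); any further columns (enzyme, substrate,
#' pH, ...) are carried along as metadata.
#'
#' @param path CSV file path.
#' @return Tibble sorted by time.
#' @export
read_trace_csv <- function(path) {
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("time", "value") %in% names(x)))
    abort_bad_arg("trace CSV must have `time` and `value` columns.")
  arrange(x, .data$time)
}

#' Read and write grayscale leaf scans as PNG
#'
#' Images are represented in this package as integer matrices with values
#' in 0..255 (0 = black).  RGB PNGs are converted to grayscale by channel
#' mean on reading.
#'
#' @param path PNG file path.
#' @param image Integer matrix in 0..255.
#' @return `read_leaf_png()`: an integer matrix.  `write_leaf_png()`: the
#'   image, invisibly.
#' @export
read_leaf_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:3, drop = FALSE], c(1, 2), mean)
  round(x * 255)
}

#' @rdname read_leaf_png
#' @export
write_leaf_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(image)
}
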