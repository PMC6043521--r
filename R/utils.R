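# Internal validation and RNG helpers.

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    abort_bad_arg(sprintf("`%s` must be a single integer >= %d.", name, min))
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max)
    abort_bad_arg(sprintf("`%s` must be a single number in [%s, %s].",
                          name, format(min), format(max)))
  as.numeric(x)
}

check_residue <- function(x, name) {
  if (length(x) != 1L || !is.character(x) || !x %in% aa_alphabet())
    abort_bad_arg(sprintf("`%s` must be one of the 20 canonical amino acids.",
                          name))
  x
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  seed <- check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, code)
}

# sample() safe against the scalar-x pitfall
sample_from <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# Coerce the different protein-set representations (tibble with id/sequence,
# named character vector) to a tibble(id, sequence, description).
as_protein_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    x <- tibble(id = ids, sequence = unname(x))
  }
  x <- as_tibble(x)
  if (!all(c("id", "sequence") %in% names(x)))
    abort_bad_arg("protein table must have columns `id` and `sequence`.")
  if (!"description" %in% names(x)) x$description <- NA_character_
  if (any(is.na(x$sequence)) || any(!nzchar(x$sequence)))
    abort_bad_arg("protein sequences must be non-empty.")
  bad <- !grepl(sprintf("^[%sX]+$", paste(aa_alphabet(), collapse = "")),
                x$sequence)
  if (any(bad))
    abort_bad_arg(sprintf(
      "sequence for %s contains characters outside the 20-letter alphabet + X.",
      x$id[which(bad)[1]]))
  x$has_x <- grepl("X", x$sequence, fixed = TRUE)
  x
}
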