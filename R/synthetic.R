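#' Simulate a background proteome
#'
#' Draws protein sequences whose residues are i.i.d. from a 20-letter
#' background composition, emulating the role of a natural proteome (e.g.
#' the tomato proteome) as the reference set for enrichment statistics and
#' as decoys for the subtilase screen.  Generators are bit-reproducible
#' under a fixed seed and never emit non-canonical letters.
#'
#' @param n_proteins Number of records (0 allowed).
#' @param length_range Inclusive integer range of sequence lengths.
#' @param aa_freqs 20-entry probability vector named by [aa_alphabet()]
#'   (nonnegative, summing to 1 within 1e-9).  Presets via
#'   [aa_frequencies()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for record identifiers.
#' @return Tibble with columns `id`, `sequence`, `description`.
#' @export
#' @examples
#' simulate_proteome(3, c(50, 60), seed = 1)
simulate_proteome <- function(n_proteins, length_range = c(300, 900),
                              aa_freqs = aa_frequencies("uniform"),
                              seed = 1L, id_prefix = "bg") {
  n_proteins <- check_count(n_proteins, "n_proteins")
  aa_freqs <- check_aa_freqs(aa_freqs)
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2])
    abort_bad_arg("`length_range` must be an increasing pair of lengths >= 1.")
  if (n_proteins == 0L)
    return(tibble(id = character(), sequence = character(),
                  description = character()))
  with_seed(seed, {
    lens <- sample_from(seq(length_range[1], length_range[2]), n_proteins)
    seqs <- map_chr(lens, function(L)
      paste(sample(aa_alphabet(), L, replace = TRUE, prob = aa_freqs),
            collapse = ""))
    tibble(id = sprintf("%s_%04d", id_prefix, seq_len(n_proteins)),
           sequence = seqs, description = NA_character_)
  })
}

#' Simulate a subtilase with planted ground truth
#'
#' Constructs a protein with the layout of a plant subtilase precursor:
#' random background residues, the I9 prodomain anchor ending immediately
#' before the junction window, a 12-residue P6...P6' window around the
#' prodomain junction, a conserved mature-N-terminus segment bridging the
#' window to the catalytic domain (plant subtilases are strongly conserved
#' just downstream of the junction), and the S8 catalytic anchor starting
#' 30 residues into the mature enzyme.  The designated S1-pocket position of the S8
#' anchor (see [s8_residue331_position()]) is substituted with
#' `residue331`, so the same alignment machinery that maps the diagnostic
#' residue-331 position on real references maps it on fixtures.
#'
#' `junction_index` is the 1-based index of the first mature residue
#' (P1'); the window occupies positions `junction_index - 6` to
#' `junction_index + 5`.
#'
#' @param id Record identifier.
#' @param total_length Protein length in residues.
#' @param junction_index 1-based index of the first mature residue.
#' @param p1_residue Residue planted at P1 (Asp for phytaspase candidates).
#' @param window_residues Optional explicit 12-mer (P6...P6'); its sixth
#'   character must equal `p1_residue`.  By default a random window with
#'   `p1_residue` at P1 and the invariant Thr-Thr at P1'/P2' is used.
#' @param residue331 Residue planted at the S1-pocket diagnostic position
#'   (His in true phytaspases, Lys or Gly in related candidates).
#' @param has_i9,has_catalytic Whether to include the I9 / S8 anchors.
#' @param aa_freqs Background composition for filler residues.
#' @param seed Integer seed.
#' @return One-row tibble: `id`, `sequence`, `description` plus the truth
#'   annotation columns `junction_index`, `p1_residue`, `window`,
#'   `residue331`, `has_i9`, `has_catalytic`, `i9_start`, `s8_start`.
#' @export
simulate_sbt <- function(id = "sbt_1", total_length = 720L,
                         junction_index = 121L, p1_residue = "D",
                         window_residues = NULL, residue331 = "H",
                         has_i9 = TRUE, has_catalytic = TRUE,
                         aa_freqs = aa_frequencies("uniform"), seed = 1L) {
  total_length <- check_count(total_length, "total_length", min = 12L)
  junction_index <- check_count(junction_index, "junction_index", min = 7L)
  p1_residue <- check_residue(p1_residue, "p1_residue")
  residue331 <- check_residue(residue331, "residue331")
  aa_freqs <- check_aa_freqs(aa_freqs)
  j <- junction_index
  if (j + 5L > total_length)
    abort_bad_arg("junction window extends past the end of the protein.")
  i9 <- i9_anchor(); s8 <- s8_anchor()
  i9_start <- j - 6L - nchar(i9)
  s8_start <- j + .S8_JUNCTION_OFFSET
  if (has_i9 && i9_start < 1L)
    abort_bad_arg("I9 anchor collides with the start of the protein.")
  if (has_catalytic && s8_start + nchar(s8) - 1L > total_length)
    abort_bad_arg("S8 anchor collides with the end of the protein.")
  with_seed(seed, {
    res <- sample(aa_alphabet(), total_length, replace = TRUE,
                  prob = aa_freqs)
    if (is.null(window_residues)) {
      window_residues <- paste(c(sample(aa_alphabet(), 5, replace = TRUE,
                                        prob = aa_freqs),
                                 p1_residue, "T", "T",
                                 sample(aa_alphabet(), 4, replace = TRUE,
                                        prob = aa_freqs)), collapse = "")
    }
    if (nchar(window_residues) != 12L ||
        !all(str_split(window_residues, "")[[1]] %in% aa_alphabet()))
      abort_bad_arg("`window_residues` must be 12 canonical residues.")
    if (substr(window_residues, 6L, 6L) != p1_residue)
      abort_bad_arg("`window_residues` position 6 must equal `p1_residue`.")
    res[(j - 6L):(j + 5L)] <- str_split(window_residues, "")[[1]]
    if (has_i9)
      res[i9_start:(j - 7L)] <- str_split(i9, "")[[1]]
    if (has_catalytic) {
      res[(j + 6L):(s8_start - 1L)] <- str_split(.MATURE_SPACER, "")[[1]]
      s8res <- str_split(s8, "")[[1]]
      s8res[.S8_RES331] <- residue331
      res[s8_start:(s8_start + nchar(s8) - 1L)] <- s8res
    }
    tibble(id = id, sequence = paste(res, collapse = ""),
           description = NA_character_,
           junction_index = j, p1_residue = p1_residue,
           window = window_residues, residue331 = residue331,
           has_i9 = has_i9, has_catalytic = has_catalytic,
           i9_start = if (has_i9) i9_start else NA_integer_,
           s8_start = if (has_catalytic) s8_start else NA_integer_)
  })
}

#' Simulate a subtilase family with planted phytaspase candidates
#'
#' Generates a set of complete subtilases mirroring the composition
#' reported for the tomato family: by default 82 full-length members, of
#' which 12 carry Asp at P1 (the phytaspase candidates) - 5 with His, 1
#' with Lys and 6 with Gly at the diagnostic S1-pocket position - while
#' the remaining 70 carry the predominant His at P1.
#'
#' @param n_his,n_lys,n_gly Numbers of Asp-P1 candidates with His / Lys /
#'   Gly at the S1-pocket position.
#' @param n_noncandidate Number of complete subtilases with His at P1.
#' @param length_range Protein length range (the completeness filter
#'   expects 650-800).
#' @param aa_freqs Background composition.
#' @param seed Integer seed.
#' @return Tibble of one row per protein, as from [simulate_sbt()], plus a
#'   `planted_subtype` column with the expected classification.
#' @export
simulate_sbt_family <- function(n_his = 5L, n_lys = 1L, n_gly = 6L,
                                n_noncandidate = 70L,
                                length_range = c(650L, 800L),
                                aa_freqs = aa_frequencies("uniform"),
                                seed = 1L) {
  spec <- tibble(
    p1 = c(rep("D", n_his + n_lys + n_gly), rep("H", n_noncandidate)),
    r331 = c(rep("H", n_his), rep("K", n_lys), rep("G", n_gly),
             rep("H", n_noncandidate)),
    planted_subtype = c(rep("His-type", n_his), rep("Lys-type", n_lys),
                        rep("Gly-type", n_gly),
                        rep("non-candidate", n_noncandidate)))
  n <- nrow(spec)
  with_seed(seed, {
    lens <- sample_from(seq(length_range[1], length_range[2]), n)
    juncs <- sample_from(115:135, n)
    seeds <- sample.int(2^20, n)
    out <- pmap(list(seq_len(n), lens, juncs, seeds, spec$p1, spec$r331),
                function(i, L, j, s, p1, r331)
                  simulate_sbt(id = sprintf("sbt_%03d", i), total_length = L,
                               junction_index = j, p1_residue = p1,
                               residue331 = r331, aa_freqs = aa_freqs,
                               seed = s))
    bind_rows(out) |> mutate(planted_subtype = spec$planted_subtype)
  })
}

#' Simulate a linear fluorescence trace
#'
#' `value[i] = intercept + slope * time[i] + noise`, with time on a regular
#' grid `0, dt, 2*dt, ...` in minutes and Gaussian noise; emulates a
#' plate-reader progress curve for a fluorogenic AFC substrate.
#'
#' @param intercept Fluorescence units at time 0.
#' @param slope Fluorescence units per minute.
#' @param noise_sd Gaussian noise SD (0 for a noiseless line).
#' @param n_points Number of time points (>= 2).
#' @param dt Time step in minutes (> 0).
#' @param seed Integer seed.
#' @return Tibble with columns `time`, `value`.
#' @export
simulate_trace <- function(intercept = 0, slope = 1, noise_sd = 0,
                           n_points = 60L, dt = 1, seed = 1L) {
  n_points <- check_count(n_points, "n_points", min = 2L)
  dt <- check_number(dt, "dt"); if (dt <= 0) abort_bad_arg("`dt` must be > 0.")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    time <- (seq_len(n_points) - 1) * dt
    tibble(time = time,
           value = intercept + slope * time + rnorm(n_points, 0, noise_sd))
  })
}

#' Simulate a scanned-leaf image with a planted necrotic fraction
#'
#' Produces an 8-bit grayscale image: near-white scanner background (255),
#' a mid-gray leaf blob (150) of `leaf_fraction` of all pixels (the pixels
#' nearest the image center), and exactly
#' `round(leaf_pixels * necrotic_fraction)` dark necrotic pixels (20)
#' sampled within the leaf.
#'
#' @param width,height Image size in pixels.
#' @param leaf_fraction Proportion of the image covered by the leaf mask
#'   (0 < leaf_fraction <= 1).
#' @param necrotic_fraction Proportion of leaf pixels set dark (0..1).
#' @param seed Integer seed.
#' @return List with `image` (height x width integer matrix in 0..255),
#'   `leaf_pixels` and `dark_pixels` (the planted counts).
#' @export
simulate_leaf_image <- function(width = 100L, height = 100L,
                                leaf_fraction = 0.6, necrotic_fraction = 0,
                                seed = 1L) {
  width <- check_count(width, "width", 1L)
  height <- check_count(height, "height", 1L)
  leaf_fraction <- check_number(leaf_fraction, "leaf_fraction", 1e-12, 1)
  necrotic_fraction <- check_number(necrotic_fraction, "necrotic_fraction",
                                    0, 1)
  n_leaf <- max(1L, round(width * height * leaf_fraction))
  n_dark <- round(n_leaf * necrotic_fraction)
  rc <- expand.grid(row = seq_len(height), col = seq_len(width))
  d2 <- (rc$row - (height + 1) / 2)^2 + (rc$col - (width + 1) / 2)^2
  ord <- order(d2, rc$row, rc$col)
  leaf_idx <- ord[seq_len(n_leaf)]
  img <- matrix(255L, nrow = height, ncol = width)
  img[cbind(rc$row[leaf_idx], rc$col[leaf_idx])] <- 150L
  with_seed(seed, {
    if (n_dark > 0) {
      dark_idx <- leaf_idx[sample.int(n_leaf, n_dark)]
      img[cbind(rc$row[dark_idx], rc$col[dark_idx])] <- 20L
    }
  })
  list(image = img, leaf_pixels = n_leaf, dark_pixels = n_dark)
}
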