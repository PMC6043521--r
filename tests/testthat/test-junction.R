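test_that("window extraction pads at boundaries and validates the bond", {
  expect_identical(extract_window("ABCDEFGHIJKL", 6), "ABCDEFGHIJKL")
  expect_identical(extract_window("ABCD", 2), "----ABCD----")
  expect_error(extract_window("ABCD", 0), "cut_index")
  expect_error(extract_window("ABCD", 4), "residue on each side")
  # re-splicing a window (pads removed) reproduces the local sequence
  withr::with_seed(3, {
    s <- paste(sample(aa_alphabet(), 30, replace = TRUE), collapse = "")
    for (cut in c(1, 3, 15, 29)) {
      w <- gsub("-", "", extract_window(s, cut))
      lo <- max(1, cut - 5); hi <- min(30, cut + 6)
      expect_identical(w, substr(s, lo, hi))
    }
  })
})

test_that("junctions are recovered exactly on planted subtilases", {
  fam <- simulate_sbt_family(n_his = 2, n_lys = 0, n_gly = 1,
                             n_noncandidate = 5, seed = 13)
  ref <- simulate_sbt(id = "ref", seed = 99)
  jc <- call_junction(fam, ref[, c("id", "sequence", "junction_index")])
  expect_identical(jc$junction_index, fam$junction_index)
  expect_identical(jc$window, fam$window)
  expect_true(all(!jc$junction_in_gap))
  expect_true(all(!jc$thr_warning))  # planted windows carry the Thr-Thr mark
})

test_that("a junction falling in a query gap maps to the mature side", {
  ref <- simulate_sbt(id = "ref", junction_index = 121, seed = 42,
                      window_residues = "ACDEFDTTWHYK")
  # delete P1' and P2' (the Thr-Thr) from the query: the reference junction
  # column now sits in a deletion; the call must land on the first aligned
  # mature-side residue and be flagged
  query <- ref
  query$id <- "del"
  query$sequence <- paste0(substr(ref$sequence, 1, 120),
                           substr(ref$sequence, 123, nchar(ref$sequence)))
  jc <- call_junction(query[, c("id", "sequence")],
                      ref[, c("id", "sequence", "junction_index")])
  expect_true(jc$junction_in_gap)
  expect_identical(jc$junction_index, 121L)
  expect_true(jc$thr_warning)
})

test_that("dissimilar proteins are uncallable", {
  bg <- simulate_proteome(1, c(700, 700), seed = 5)
  ref <- simulate_sbt(id = "ref", seed = 99)
  expect_error(call_junction(bg, ref[, c("id", "sequence", "junction_index")]),
               "uncallable")
  expect_message(
    out <- call_junction(bg, ref[, c("id", "sequence", "junction_index")],
                         strict = FALSE),
    "uncallable")
  expect_identical(nrow(out), 0L)
})

test_that("classification follows the Asp-P1 and S1-pocket rules", {
  jc <- tibble::tibble(
    protein_id = paste0("p", 1:5),
    junction_index = 100L,
    window = c("AAAAADTTAAAA", "AAAAADTTAAAA", "AAAAADTTAAAA",
               "AAAAAHTTAAAA", "AAAAADTTAAAA"),
    p1 = substr(window, 6, 6))
  arch <- tibble::tibble(protein_id = paste0("p", 1:5),
                         residue331 = c("H", "K", "G", "H", NA))
  cls <- classify_phytaspase(jc, arch)
  expect_identical(cls$is_candidate, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(cls$subtype, c("His-type", "Lys-type", "Gly-type",
                                  "non-candidate", "other"))
  expect_identical(cls, classify_phytaspase(jc, arch))  # pure function
})

test_that("candidate calls agree with an independent truth re-scan", {
  fam <- simulate_sbt_family(seed = 31)
  arch <- annotate_architecture(fam)
  ref <- simulate_sbt(id = "ref", seed = 99)
  cls <- classify_phytaspase(
    call_junction(fam, ref[, c("id", "sequence", "junction_index")]), arch)
  # oracle: read the planted truth straight off the generator annotations
  truth_candidates <- fam$id[fam$p1_residue == "D"]
  expect_setequal(cls$protein_id[cls$is_candidate], truth_candidates)
  expect_identical(sum(cls$is_candidate), length(truth_candidates))
  expect_identical(cls$subtype[match(fam$id, cls$protein_id)],
                   fam$planted_subtype)
})

test_that("motif-scan junction calling finds a distinctive junction motif", {
  # a model that scores the Asp-P1 + Thr-Thr mature N-terminus
  w <- matrix(0, 12, 20, dimnames = list(c("P6", "P5", "P4", "P3", "P2",
                                           "P1", "P1'", "P2'", "P3'",
                                           "P4'", "P5'", "P6'"),
                                         aa_alphabet()))
  w["P1", "D"] <- 10; w["P1'", "T"] <- 5; w["P2'", "T"] <- 5
  model <- specificity_model(w, tau = 0)
  fam <- simulate_sbt_family(n_his = 3, n_lys = 0, n_gly = 0,
                             n_noncandidate = 0, seed = 19)
  out <- call_junction_pwm(fam, model)
  expect_identical(out$junction_index, fam$junction_index)
  expect_identical(out$window, fam$window)
  expect_true(all(out$motif_score == 20))
})
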