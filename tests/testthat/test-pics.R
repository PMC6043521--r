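test_that("digestion applies the site rules by hand-checkable examples", {
  chymo <- digestion_rules("chymotrypsin", min_len = 1, max_len = 50)
  lib <- digest(tibble::tibble(id = "p", sequence = "AAFPAAYK"), chymo)
  expect_identical(lib$peptide, c("AAFPAAY", "K"))   # F|P blocked, Y|K cut
  tryp <- digestion_rules("trypsin", min_len = 1, max_len = 50)
  lib2 <- digest(tibble::tibble(id = "p", sequence = "MKRA"), tryp)
  expect_identical(lib2$peptide, c("MK", "R", "A"))
  expect_identical(lib2$start, c(1L, 3L, 4L))
})

test_that("fragments reassemble to the source proteins", {
  prot <- simulate_proteome(100, c(200, 200), seed = 15)
  rules <- digestion_rules("trypsin", min_len = 1, max_len = 10000)
  lib <- digest(prot, rules)
  rebuilt <- lib |>
    dplyr::group_by(protein_id) |>
    dplyr::summarise(seq = paste(peptide, collapse = ""))
  expect_identical(rebuilt$seq[match(prot$id, rebuilt$protein_id)],
                   prot$sequence)
  expect_equal(sum(nchar(lib$peptide)), sum(nchar(prot$sequence)))
})

test_that("threshold cleavage is forced by a strict Asp-P1 model", {
  model <- strict_asp_model()
  lib <- tibble::tibble(peptide_id = "pep_1", peptide = "AAADGGGG",
                        protein_id = "p", start = 1L)
  class(lib) <- c("phytasp_library", class(lib))
  ev <- simulate_cleavage(lib, model)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$cut_index, 4L)
  expect_identical(ev$prime_fragment, "GGGG")
  expect_identical(ev$true_window, "--AAADGGGG--")
  lib$peptide <- "AAAGGGGG"  # no Asp anywhere: no event
  expect_identical(nrow(simulate_cleavage(lib, model)), 0L)
})

test_that("bernoulli cleavage rates follow the logistic probability", {
  tau <- 10 - stats::qlogis(0.3)   # P1-Asp bond fires with probability 0.3
  model <- strict_asp_model(mode = "bernoulli", tau = tau)
  lib <- tibble::tibble(peptide_id = sprintf("pep_%05d", 1:10000),
                        peptide = "AAADGGGG", protein_id = "p", start = 1L)
  class(lib) <- c("phytasp_library", class(lib))
  ev <- simulate_cleavage(lib, model, seed = 4)
  frac <- nrow(ev) / nrow(lib)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(lib)))
  expect_identical(nrow(simulate_cleavage(lib, model, seed = 4)), nrow(ev))
})

test_that("site reconstruction rebuilds windows and reports ambiguity", {
  lib <- tibble::tibble(peptide_id = c("pep_1", "pep_2", "pep_3"),
                        peptide = c("AVNLDSTKGW", "MMMMMSTKGW", "QQQQWHYKEL"),
                        protein_id = "p", start = 1L)
  class(lib) <- c("phytasp_library", class(lib))
  rec <- reconstruct_sites(c("WHYKEL", "STKGW"), lib)
  expect_identical(rec$windows$fragment, "WHYKEL")
  expect_identical(rec$windows$window, "--QQQQWHYKEL")
  expect_identical(rec$ambiguity$fragment, "STKGW")  # suffix of two peptides
  expect_identical(rec$ambiguity$n_hits, 2L)
  one <- reconstruct_sites("STKGW", lib[1, ])
  expect_identical(one$windows$window, "-AVNLDSTKGW-")
})

test_that("simulate-reconstruct round trip recovers every retained window", {
  prot <- simulate_proteome(150, c(400, 600), seed = 23)
  lib <- digest(prot, digestion_rules("trypsin"))
  ev <- simulate_cleavage(lib, strict_asp_model(), seed = 1)
  rec <- reconstruct_sites(ev$prime_fragment, lib)
  expect_gt(nrow(rec$windows), 500)
  expect_identical(rec$windows$window,
                   ev$true_window[rec$windows$fragment_index])
  expect_identical(nrow(rec$windows) + nrow(rec$ambiguity), nrow(ev))
  # every retained window carries the planted Asp at P1
  expect_true(all(substr(rec$windows$window, 6, 6) == "D"))
})

test_that("planted specificity is recovered in the enrichment profile", {
  prot <- simulate_proteome(150, c(400, 600), seed = 29)
  lib <- digest(prot, digestion_rules("chymotrypsin"))
  ev <- simulate_cleavage(lib, strict_asp_model(), seed = 1)
  rec <- reconstruct_sites(ev$prime_fragment, lib)
  prof <- specificity_profile(rec$windows, "uniform")
  expect_identical(attr(prof, "provenance"), "PICS")
  sig <- dplyr::filter(prof, significant, percent_difference > 0)
  top <- sig[which.max(sig$percent_difference), ]
  expect_identical(as.character(top$position), "P1")
  expect_identical(top$aa, "D")
  expect_error(specificity_profile(character(0), "uniform"), "no windows")
  # an added P4-Ile requirement surfaces as a second significant cell
  model2 <- strict_asp_model(extra = list(P4 = c(I = 6)), tau = 12)
  ev2 <- simulate_cleavage(lib, model2, seed = 1)
  rec2 <- reconstruct_sites(ev2$prime_fragment, lib)
  prof2 <- specificity_profile(rec2$windows, "uniform")
  cell <- dplyr::filter(prof2, position == "P4", aa == "I")
  expect_true(cell$significant && cell$percent_difference > 50)
})
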