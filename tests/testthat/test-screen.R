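test_that("planted anchors are annotated with all landmarks", {
  s <- simulate_sbt(seed = 3)
  arch <- annotate_architecture(s)
  expect_true(arch$s8_present)
  expect_true(arch$i9_present)
  expect_identical(arch$n_catalytic, 4L)
  expect_identical(arch$residue331, "H")
  expect_identical(arch$s8_start, s$s8_start)
  # mapped catalytic positions agree with planted geometry
  expect_identical(arch$catalytic_positions[[1]],
                   s$s8_start + s8_catalytic_positions() - 1L)
})

test_that("background proteins carry no domain architecture", {
  bg <- simulate_proteome(5, c(650, 800), seed = 21)
  arch <- annotate_architecture(bg)
  expect_true(all(!arch$s8_present))
  expect_true(all(!arch$i9_present))
  expect_true(all(arch$n_catalytic == 0L))
})

test_that("a mutated catalytic residue drops exactly one match", {
  s <- simulate_sbt(seed = 8)
  pos <- s$s8_start + s8_catalytic_positions()[2] - 1L
  substr(s$sequence, pos, pos) <- "A"
  arch <- annotate_architecture(s)
  expect_identical(arch$n_catalytic, 3L)
  expect_true(arch$s8_present)  # one point mutation does not lose the domain
})

test_that("completeness filter applies inclusive length bounds", {
  lens <- c(649L, 650L, 800L, 801L)
  prots <- bind_fam(lapply(seq_along(lens), function(i)
    simulate_sbt(id = sprintf("len_%d", lens[i]), total_length = lens[i],
                 junction_index = 120L, seed = 30 + i)))
  filt <- completeness_filter(annotate_architecture(prots))
  expect_identical(filt$retained, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(filt$exclusion_reason[c(1, 4)], c("length", "length"))
})

test_that("the filter recovers exactly the planted complete set", {
  set <- planted_screen_set(seed = 4)
  decoys <- simulate_proteome(50, c(650, 800), seed = 77)
  all_prot <- dplyr::bind_rows(set$complete[, c("id", "sequence")],
                               set$incomplete[, c("id", "sequence")],
                               decoys[, c("id", "sequence")])
  filt <- completeness_filter(annotate_architecture(all_prot))
  expect_identical(sum(filt$retained), 10L)
  expect_setequal(filt$protein_id[filt$retained], set$complete$id)
  reasons <- filt$exclusion_reason[match(set$incomplete$id, filt$protein_id)]
  expect_identical(reasons,
                   c(rep("length", 5), rep("i9_prodomain", 3),
                     rep("catalytic_residues", 2)))
  # order invariance and idempotence
  shuffled <- filt[rev(seq_len(nrow(filt))), ]
  refilt <- completeness_filter(shuffled)
  expect_setequal(refilt$protein_id[refilt$retained],
                  filt$protein_id[filt$retained])
  twice <- completeness_filter(dplyr::filter(filt, retained))
  expect_true(all(twice$retained))
})

test_that("tandem arrays follow the start-to-start gap rule", {
  four <- tibble::tibble(gene_id = paste0("g", 1:4), chromosome = "chr4",
                         start = c(10, 40, 70, 100) * 1000,
                         end = c(12, 42, 72, 102) * 1000, strand = "+")
  cl <- find_tandem_arrays(four, max_gap_kb = 100)
  expect_identical(unique(cl$cluster_size), 4L)
  two_chr <- tibble::tibble(gene_id = c("a", "b"),
                            chromosome = c("chr1", "chr2"),
                            start = c(1, 1), end = c(10, 10), strand = "+")
  expect_identical(find_tandem_arrays(two_chr)$cluster_size, c(1L, 1L))
  gapped <- tibble::tibble(gene_id = c("a", "b"), chromosome = "chr1",
                           start = c(0, 150000), end = c(10, 150010),
                           strand = "+")
  expect_identical(find_tandem_arrays(gapped, 100)$cluster_size, c(1L, 1L))
  dup <- tibble::tibble(gene_id = c("a", "a"), chromosome = "chr1",
                        start = c(1, 2), end = c(3, 4), strand = "+")
  expect_error(find_tandem_arrays(dup), "duplicate")
})

test_that("gene coordinates are read from GFF3", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ch04\tsrc\tgene\t2000000\t2003000\t.\t+\t.\tID=Phyt2",
    "ch04\tsrc\tmRNA\t2000000\t2003000\t.\t+\t.\tID=Phyt2.1;Parent=Phyt2",
    "ch04\tsrc\tgene\t2040000\t2043000\t.\t-\t.\tID=Phyt3"), path)
  g <- read_gene_coordinates(path)
  expect_identical(g$gene_id, c("Phyt2", "Phyt3"))
  expect_identical(g$start, c(2000000L, 2040000L))
  expect_identical(g$strand, c("+", "-"))
  expect_identical(find_tandem_arrays(g, 100)$cluster_size, c(2L, 2L))
})
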