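test_that("background proteome generator is seeded, bounded and validated", {
  expect_equal(nrow(simulate_proteome(0, seed = 1)), 0L)
  a <- simulate_proteome(3, c(50, 60), seed = 1)
  b <- simulate_proteome(3, c(50, 60), seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, simulate_proteome(3, c(50, 60), seed = 2)))
  expect_true(all(nchar(a$sequence) >= 50 & nchar(a$sequence) <= 60))
  expect_error(simulate_proteome(2, aa_freqs = rep(0.1, 20)), "sum to 1")
  expect_error(simulate_proteome(2, aa_freqs = c(-0.05, rep(0.05, 18), 0.15)),
               "nonnegative")
})

test_that("residue draws follow the requested composition", {
  # freq(D) = 0.05: the observed fraction over ~1e5 residues must fall
  # within 3 binomial SDs of the target
  p <- simulate_proteome(1000, c(100, 100), seed = 42)
  chars <- strsplit(paste(p$sequence, collapse = ""), "")[[1]]
  n <- length(chars)
  expect_identical(n, 100000L)
  obs <- mean(chars == "D")
  expect_lt(abs(obs - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("large-proteome composition passes chi-square goodness of fit", {
  freqs <- aa_frequencies("arabidopsis")
  rejections <- vapply(1:20, function(s) {
    p <- simulate_proteome(200, c(500, 500), aa_freqs = freqs, seed = s)
    chars <- strsplit(paste(p$sequence, collapse = ""), "")[[1]]
    counts <- table(factor(chars, levels = aa_alphabet()))
    stats::chisq.test(counts, p = freqs)$p.value < 0.01
  }, logical(1))
  expect_lte(sum(rejections), 2L)
})

test_that("planted subtilase truth matches direct string inspection", {
  s <- simulate_sbt(id = "x", total_length = 720, junction_index = 121,
                    p1_residue = "D", residue331 = "K", seed = 9)
  expect_identical(substr(s$sequence, s$junction_index - 6L,
                          s$junction_index + 5L), s$window)
  expect_identical(substr(s$window, 6, 6), "D")
  expect_identical(substr(s$window, 7, 8), "TT")
  # anchors present verbatim (S8 anchor modulo the planted S1-pocket residue)
  expect_identical(substr(s$sequence, s$i9_start,
                          s$i9_start + nchar(i9_anchor()) - 1L), i9_anchor())
  r331_pos <- s$s8_start + s8_residue331_position() - 1L
  expect_identical(substr(s$sequence, r331_pos, r331_pos), "K")
  planted_s8 <- substr(s$sequence, s$s8_start,
                       s$s8_start + nchar(s8_anchor()) - 1L)
  ref <- s8_anchor()
  substr(ref, s8_residue331_position(), s8_residue331_position()) <- "K"
  expect_identical(planted_s8, ref)
  expect_identical(s, simulate_sbt(id = "x", total_length = 720,
                                   junction_index = 121, p1_residue = "D",
                                   residue331 = "K", seed = 9))
})

test_that("planted subtilase rejects impossible layouts", {
  expect_error(simulate_sbt(junction_index = 40, total_length = 720),
               "collides")
  expect_error(simulate_sbt(junction_index = 121, total_length = 250),
               "collides")
  expect_error(simulate_sbt(window_residues = "AAAAAHTTAAAA"),
               "p1_residue")
})

test_that("fluorescence traces are linear plus seeded noise", {
  tr <- simulate_trace(intercept = 3, slope = 50, noise_sd = 0,
                       n_points = 10, dt = 1)
  expect_equal(tr$value, 3 + 50 * tr$time)
  expect_equal(initial_rate(tr)$slope, 50)
  flat <- simulate_trace(intercept = 7, slope = 0, noise_sd = 0,
                         n_points = 5)
  expect_equal(flat$value, rep(7, 5))
  expect_error(simulate_trace(n_points = 1), "n_points")
  # Monte-Carlo: mean independently fitted slope within 2 SE of truth
  slopes <- vapply(1:200, function(s) {
    tr <- simulate_trace(slope = 50, noise_sd = 5, n_points = 100, seed = s)
    unname(coef(lm(value ~ time, tr))[2])
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 50), 2 * se)
})

test_that("leaf images plant an exact dark-pixel count", {
  img0 <- simulate_leaf_image(50, 40, leaf_fraction = 0.5,
                              necrotic_fraction = 0, seed = 1)
  expect_identical(sum(img0$image <= 40), 0L)
  img <- simulate_leaf_image(100, 100, leaf_fraction = 1,
                             necrotic_fraction = 0.05, seed = 1)
  expect_identical(img$dark_pixels, 500)
  expect_identical(sum(img$image == 20L), 500L)
  expect_identical(img$leaf_pixels, 10000)
  again <- simulate_leaf_image(100, 100, leaf_fraction = 1,
                               necrotic_fraction = 0.05, seed = 1)
  expect_identical(img$image, again$image)
  # background near-white, leaf mid-gray, necrosis dark
  part <- simulate_leaf_image(60, 60, leaf_fraction = 0.4,
                              necrotic_fraction = 0.1, seed = 2)
  expect_setequal(unique(as.vector(part$image)), c(255L, 150L, 20L))
})
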