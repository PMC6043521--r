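# Shared fixtures and independent oracles for the test suite.

# Independent exact two-sided binomial p-value (smaller tail doubled,
# capped), computed from log-binomial coefficients rather than pbinom.
oracle_binom_p <- function(k, n, p0) {
  if (n == 0L) return(1)
  x <- 0:n
  logpmf <- lchoose(n, x) + x * log(p0) + (n - x) * log1p(-p0)
  if (p0 == 0) logpmf <- ifelse(x == 0, 0, -Inf)
  if (p0 == 1) logpmf <- ifelse(x == n, 0, -Inf)
  pmf <- exp(logpmf)
  lower <- sum(pmf[x <= k])
  upper <- sum(pmf[x >= k])
  min(1, 2 * min(lower, upper))
}

# Random unrooted tree with strictly positive branch lengths, plus its
# additive (path-length) distance matrix.
random_additive_tree <- function(n_leaves, seed) {
  withr::with_seed(seed, {
    tr <- ape::unroot(ape::rtree(n_leaves, br = NULL))
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

# All-pairs patristic distances via igraph shortest paths (oracle for
# assign_clades / cophenetic-based code paths).
patristic_oracle <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  w <- tree$edge.length
  d <- igraph::distances(g, weights = w)
  tips <- as.character(seq_along(tree$tip.label))
  out <- d[tips, tips]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# A planted screening set: `n_complete` full-length subtilases plus decoy
# classes that each fail one completeness criterion.
planted_screen_set <- function(seed = 1L) {
  withr::with_seed(seed, {
    complete <- simulate_sbt_family(n_his = 2, n_lys = 1, n_gly = 1,
                                    n_noncandidate = 6, seed = seed)
    short <- bind_fam(lapply(1:5, function(i)
      simulate_sbt(id = sprintf("short_%d", i), total_length = 600L,
                   junction_index = 120L, seed = seed + 100 + i)))
    noi9 <- bind_fam(lapply(1:3, function(i)
      simulate_sbt(id = sprintf("noi9_%d", i), has_i9 = FALSE,
                   seed = seed + 200 + i)))
    mutcat <- bind_fam(lapply(1:2, function(i) {
      s <- simulate_sbt(id = sprintf("mutcat_%d", i), seed = seed + 300 + i)
      pos <- s$s8_start + s8_catalytic_positions()[1] - 1L
      substr(s$sequence, pos, pos) <- "A"
      s
    }))
    list(complete = complete, incomplete = rbind(short, noi9, mutcat))
  })
}

bind_fam <- function(lst) do.call(rbind, lst)
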