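#' Pairwise distances from a protein multiple sequence alignment
#'
#' Computes p-distances with pairwise deletion: for each pair of rows, the
#' proportion of mismatches over the sites where both rows carry a
#' canonical residue (gaps `-`/`.` and `X` are excluded).  With
#' `correction = "kimura"` the Kimura protein correction
#' `d = -ln(1 - p - 0.2 p^2)` is applied, as in ClustalX's default
#' distances; `"none"` returns p itself.
#'
#' @param msa Tibble with `id`, `sequence` (aligned, equal lengths) or a
#'   named character vector.
#' @param correction `"none"` (default) or `"kimura"`.
#' @return A labelled symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(msa, correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  if (is.character(msa)) msa <- tibble(id = names(msa), sequence = unname(msa))
  msa <- as_tibble(msa)
  n <- nrow(msa)
  if (n < 2L) abort_bad_arg("need at least two aligned sequences.")
  lens <- nchar(msa$sequence)
  if (length(unique(lens)) != 1L)
    abort_bad_arg("aligned sequences must have equal length.")
  m <- do.call(rbind, str_split(toupper(msa$sequence), ""))
  ok <- matrix(m %in% aa_alphabet(), nrow = n)
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns == 0L)
        abort_bad_arg(sprintf("no shared non-gap sites between '%s' and '%s'.",
                              msa$id[i], msa$id[j]))
      p <- sum(m[i, shared] != m[j, shared]) / ns
      if (correction == "kimura") {
        arg <- 1 - p - 0.2 * p^2
        if (arg <= 0)
          abort_bad_arg(sprintf(
            "p-distance %.3f between '%s' and '%s' too large for the Kimura correction; use correction = \"none\".",
            p, msa$id[i], msa$id[j]))
        p <- -log(arg)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || is.null(rownames(d)))
    abort_bad_arg("`d` must be a square labelled matrix.")
  if (any(!is.finite(d)))
    abort_bad_arg("distances must be finite.")
  if (max(abs(d - t(d))) > 1e-12)
    abort_bad_arg("distance matrix must be symmetric within 1e-12.")
  if (any(abs(diag(d)) > 0))
    abort_bad_arg("distance matrix must have a zero diagonal.")
  d
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree reconstruction
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair (i, j) minimizing
#' `Q(i, j) = (r - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)` (ties broken
#' by the smallest index pair, for determinism), compute the two branch
#' lengths by the standard two-point formulas, and close the tree with a
#' final three-way join.  On additive distances NJ recovers the generating
#' topology and branch lengths exactly.  Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch (so their
#' sum is preserved) unless `clamp_negative = FALSE`.
#'
#' @param d Labelled symmetric distance matrix (e.g. from
#'   [pairwise_distances()]), at least 3 taxa; for exactly 2 taxa a single
#'   edge is returned, split at its midpoint.
#' @param clamp_negative Clamp negative branch lengths (default `TRUE`).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighbor_joining(d)
neighbor_joining <- function(d, clamp_negative = TRUE) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  if (n < 2L) abort_bad_arg("need at least 2 taxa.")
  if (n == 2L) {
    h <- d[1, 2] / 2
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labels[1],
                                         fmt_len(h), labels[2], fmt_len(h))))
  }
  node <- labels
  D <- d
  fix_pair <- function(bi, bj, dij) {
    if (clamp_negative) {
      if (bi < 0) { bj <- dij; bi <- 0 }
      if (bj < 0) { bi <- dij; bj <- 0 }
    }
    c(bi, bj)
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    Tsum <- rowSums(D)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        q <- (r - 2) * D[i, j] - Tsum[i] - Tsum[j]
        if (q < best[1]) best <- c(q, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    bi <- 0.5 * D[i, j] + (Tsum[i] - Tsum[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    b <- fix_pair(bi, bj, D[i, j])
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt_len(b[1]),
                      node[j], fmt_len(b[2]))
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    Dn <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    node <- c(node[keep], merged)
    D <- Dn
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) { b1 <- max(b1, 0); b2 <- max(b2, 0); b3 <- max(b3, 0) }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt_len(b1),
                 node[2], fmt_len(b2), node[3], fmt_len(b3))
  ape::read.tree(text = nwk)
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick reader/writer so trees round-trip
#' losslessly (topology, labels, branch lengths to printed precision).
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional file path; if `NULL`, `write_newick()` returns the
#'   Newick string.
#' @return `write_newick()`: the Newick string (invisibly when written to a
#'   file); `read_newick()`: an `ape::phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' @rdname write_newick
#' @param x Newick string or file path.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}

#' Assign query leaves to labelled subfamilies
#'
#' Each unlabelled leaf receives the subfamily of its nearest labelled
#' leaf by patristic (path-length) distance along the tree; ties are
#' broken by lexicographic reference label.
#'
#' @param tree An `ape::phylo`.
#' @param labels Named character vector mapping reference leaf names to
#'   subfamily labels (or a tibble with `leaf` and `subfamily`).
#' @return Tibble with `leaf`, `subfamily`, `nearest_reference`,
#'   `distance` for every leaf of the tree.
#' @export
assign_clades <- function(tree, labels) {
  if (is.data.frame(labels)) labels <- setNames(labels$subfamily, labels$leaf)
  refs <- names(labels)
  if (length(refs) == 0L) abort_bad_arg("at least one labelled leaf required.")
  if (!all(refs %in% tree$tip.label))
    abort_bad_arg("all labelled leaves must be tips of the tree.")
  pd <- ape::cophenetic.phylo(tree)
  rows <- map(tree$tip.label, function(leaf) {
    if (leaf %in% refs)
      return(tibble(leaf = leaf, subfamily = unname(labels[leaf]),
                    nearest_reference = leaf, distance = 0))
    dd <- pd[leaf, refs]
    ord <- order(dd, refs)
    tibble(leaf = leaf, subfamily = unname(labels[refs[ord[1]]]),
           nearest_reference = refs[ord[1]], distance = unname(dd[ord[1]]))
  })
  bind_rows(rows)
}
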