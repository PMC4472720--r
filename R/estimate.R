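# In-house gene tree estimation: JC distances + neighbor joining, with
# nonparametric site bootstrapping. This stands in for ML gene tree
# estimation so binned/unbinned pipelines run end-to-end with no
# external tools; both estimators are statistically consistent on
# JC-generated data.

#' Jukes-Cantor distance matrix
#'
#' Pairwise comparisons ignore columns with a gap or N in either row.
#' `d = -(3/4) log(1 - (4/3) p)` for mismatch fraction `p`; saturated
#' pairs (`p >= 0.75`) are capped at 5.0.
#'
#' @param alignment a [dna_alignment] with at least two taxa.
#' @return a `distance_matrix`: list with `taxa` and symmetric `values`.
#' @export
jc_distance_matrix <- function(alignment) {
  mat <- alignment$mat
  n <- nrow(mat)
  if (n < 2) stop_validation("need at least two taxa")
  taxa <- rownames(mat)
  valid <- mat != "-" & mat != "N"
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      ncomp <- sum(ok)
      if (ncomp == 0) stop_validation("no comparable columns between %s and %s", taxa[i], taxa[j])
      p <- sum(mat[i, ok] != mat[j, ok]) / ncomp
      d[i, j] <- d[j, i] <- if (p >= 0.75) 5.0 else -0.75 * log(1 - 4 * p / 3)
    }
  }
  structure(list(taxa = taxa, values = d), class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ (via [ape::nj()]) with negative estimated branch lengths
#' clamped to zero. Three taxa yield the unique star.
#'
#' @param dm a `distance_matrix`.
#' @return an unrooted [support_tree] without supports.
#' @export
nj_tree <- function(dm) {
  n <- length(dm$taxa)
  if (n < 3) stop_validation("need at least 3 taxa for a tree")
  if (n == 3) {
    st <- parse_newick(sprintf("(%s,%s,%s);", dm$taxa[1], dm$taxa[2], dm$taxa[3]))
    st$rooted <- FALSE
    return(st)
  }
  phy <- ape::nj(stats::as.dist(dm$values))
  phy$edge.length[phy$edge.length < 0] <- 0
  st <- support_tree(phy, supports = rep(NA_real_, phy$Nnode), rooted = FALSE)
  st
}

#' Nonparametric site bootstrap of an NJ gene tree
#'
#' Replicate r resamples columns with replacement using a stream seed
#' derived from (`seed`, r), so increasing `b` never perturbs earlier
#' replicates; trees are re-estimated by JC distances + NJ. The point
#' tree is estimated on the original columns and carries, on each
#' internal edge, 100 times the fraction of replicate trees containing
#' that bipartition.
#'
#' @param alignment a [dna_alignment].
#' @param b number of bootstrap replicates (>= 1).
#' @param seed master integer seed.
#' @return a `bootstrap_result`: list with `point_tree` (supports
#'   attached) and `replicate_trees` (length `b`).
#' @export
bootstrap_gene_tree <- function(alignment, b, seed = 1L) {
  if (b < 1) stop_validation("b must be >= 1")
  k <- aln_length(alignment)
  point <- nj_tree(jc_distance_matrix(alignment))
  reps <- lapply(seq_len(b), function(r) {
    idx <- with_seed(derive_seed(seed, r), sample.int(k, k, replace = TRUE))
    nj_tree(jc_distance_matrix(dna_alignment(alignment$mat[, idx, drop = FALSE])))
  })
  sp <- tree_splits(point)
  if (nrow(sp)) {
    rep_masks <- lapply(reps, function(t) tree_splits(t)$mask)
    frac <- vapply(sp$mask, function(m) {
      mean(vapply(rep_masks, function(rm) m %in% rm, logical(1)))
    }, numeric(1))
    point <- tree_from_splits(attr(sp, "leaves"), sp$mask,
                              support = 100 * frac, length = sp$length,
                              pendant = pendant_lengths(point))
  }
  structure(list(point_tree = point, replicate_trees = reps),
            class = "bootstrap_result")
}
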