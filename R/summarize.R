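# Species tree summaries: greedy consensus, rooted-triplet counting,
# the R* (plurality triplet + BUILD) estimator, and site-only
# multi-locus bootstrapping over replicate tree sets.

#' Greedy (majority-rule extended) consensus
#'
#' Bipartitions are ordered by frequency (most frequent first; ties
#' broken by canonical split order) and added greedily whenever
#' compatible with everything already added. Retained splits carry
#' support = 100 x their input frequency.
#'
#' @param trees non-empty list of [support_tree]s on one leaf set.
#' @return a [support_tree] with frequency supports.
#' @export
greedy_consensus <- function(trees) {
  if (!length(trees)) stop_validation("no input trees")
  for (t in trees[-1]) check_same_leaves(trees[[1]], t)
  leaves <- leaf_labels(trees[[1]])
  full <- full_mask(length(leaves))
  all_masks <- unlist(lapply(trees, function(t) tree_splits(t)$mask))
  if (!length(all_masks)) return(tree_from_splits(leaves, integer(0)))
  tab <- table(all_masks)
  masks <- as.integer(names(tab))
  freq <- as.numeric(tab) / length(trees)
  ord <- order(-freq, popcount(masks), masks)
  masks <- masks[ord]; freq <- freq[ord]
  kept <- integer(0); kept_freq <- numeric(0)
  for (i in seq_along(masks)) {
    if (masks_pairwise_compatible(masks[i], kept, full)) {
      kept <- c(kept, masks[i]); kept_freq <- c(kept_freq, freq[i])
    }
  }
  tree_from_splits(leaves, kept, support = 100 * kept_freq)
}

## ---- rooted triplets -------------------------------------------------

triplet_index <- function(n) {
  trip <- utils::combn(n, 3)  # columns i<j<k
  list(trip = trip,
       # linear indices into an n x n matrix for the three pairs
       ij = (trip[2, ] - 1) * n + trip[1, ],
       ik = (trip[3, ] - 1) * n + trip[1, ],
       jk = (trip[3, ] - 1) * n + trip[2, ])
}

# n x n matrix of the clade size of the MRCA of each leaf pair (leaves
# in sorted-label order).
pair_mrca_sizes <- function(st) {
  phy <- st$phy
  ntip <- length(phy$tip.label)
  leaves <- sort(phy$tip.label)
  rank <- match(phy$tip.label, leaves)
  masks <- integer(ntip + phy$Nnode)
  masks[seq_len(ntip)] <- bitwShiftL(1L, rank - 1L)
  po <- stats::reorder(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    masks[po$edge[k, 1]] <- bitwOr(masks[po$edge[k, 1]], masks[po$edge[k, 2]])
  }
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  sz <- popcount(masks[internal])
  D <- matrix(NA_real_, ntip, ntip)
  for (v in internal[order(sz)]) {
    members <- which(bitwAnd(bitwShiftL(1L, seq_len(ntip) - 1L), masks[v]) != 0L)
    D_sub <- D[members, members]
    D_sub[is.na(D_sub)] <- popcount(masks[v])
    D[members, members] <- D_sub
  }
  diag(D) <- 0
  D
}

#' Rooted triplet topology counts across a set of trees
#'
#' For every 3-subset of taxa `i < j < k` (sorted labels), counts how
#' many input trees induce each of the three rooted resolutions
#' (column 1: `ij|k`, column 2: `ik|j`, column 3: `jk|i`); triplets left
#' unresolved by a polytomy are tallied separately.
#'
#' @param trees non-empty list of rooted [support_tree]s on one leaf set.
#' @return a `triplet_distribution`: list with `taxa`, `trip` (3 x T
#'   index matrix), `counts` (T x 3), `unresolved` (length T), `n_trees`.
#' @export
triplet_counts <- function(trees) {
  if (!length(trees)) stop_validation("no input trees")
  if (any(!vapply(trees, `[[`, logical(1), "rooted"))) {
    stop_validation("triplet extraction requires rooted trees")
  }
  for (t in trees[-1]) check_same_leaves(trees[[1]], t)
  taxa <- leaf_labels(trees[[1]])
  n <- length(taxa)
  if (n < 3) stop_validation("need at least 3 taxa")
  ti <- triplet_index(n)
  ntrip <- ncol(ti$trip)
  counts <- matrix(0L, ntrip, 3)
  unresolved <- integer(ntrip)
  for (t in trees) {
    D <- pair_mrca_sizes(t)
    a <- D[ti$ij]; b <- D[ti$ik]; c_ <- D[ti$jk]
    r1 <- a < b & a < c_
    r2 <- b < a & b < c_
    r3 <- c_ < a & c_ < b
    counts[, 1] <- counts[, 1] + r1
    counts[, 2] <- counts[, 2] + r2
    counts[, 3] <- counts[, 3] + r3
    unresolved <- unresolved + !(r1 | r2 | r3)
  }
  structure(list(taxa = taxa, trip = ti$trip, counts = counts,
                 unresolved = unresolved, n_trees = length(trees)),
            class = "triplet_distribution")
}

#' @export
print.triplet_distribution <- function(x, ...) {
  cat(sprintf("triplet_distribution: %d taxa, %d triplets, %d trees\n",
              length(x$taxa), ncol(x$trip), x$n_trees))
  invisible(x)
}

# Per-triplet frequency matrix (rows summing to 1 over resolved counts;
# NA rows when a triplet was never resolved).
triplet_frequencies <- function(dist) {
  tot <- rowSums(dist$counts)
  f <- dist$counts / ifelse(tot == 0, NA_real_, tot)
  f
}

#' R* species tree from a triplet distribution
#'
#' For each triplet the strict-plurality rooted topology is selected
#' (ties omit the triplet), and the selected triplets are assembled into
#' a rooted supertree with the BUILD algorithm; components that cannot
#' be separated yield polytomies rather than failure.
#'
#' @param dist a `triplet_distribution`.
#' @return a rooted [support_tree].
#' @export
rstar_species_tree <- function(dist) {
  n <- length(dist$taxa)
  cnt <- dist$counts
  win <- integer(ncol(dist$trip))  # 0 = omitted
  mx <- pmax(cnt[, 1], cnt[, 2], cnt[, 3])
  strict <- (cnt[, 1] == mx) + (cnt[, 2] == mx) + (cnt[, 3] == mx) == 1 & mx > 0
  win[strict] <- max.col(cnt[strict, , drop = FALSE])
  # chosen triplets as (cherry1, cherry2, out)
  sel <- which(win > 0)
  ch <- t(vapply(sel, function(s) {
    ijk <- dist$trip[, s]
    switch(win[s],
           c(ijk[1], ijk[2], ijk[3]),
           c(ijk[1], ijk[3], ijk[2]),
           c(ijk[2], ijk[3], ijk[1]))
  }, integer(3)))
  build <- function(S) {
    if (length(S) == 1) return(dist$taxa[S])
    if (length(S) == 2) return(sprintf("(%s,%s)", dist$taxa[S[1]], dist$taxa[S[2]]))
    inS <- matrix(ch %in% S, ncol = 3)
    use <- which(inS[, 1] & inS[, 2] & inS[, 3])
    comp <- stats::setNames(seq_along(S), S)  # union-find over members of S
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (u in use) {
      a <- find(match(ch[u, 1], S)); b <- find(match(ch[u, 2], S))
      if (a != b) comp[b] <- a
    }
    roots <- vapply(seq_along(S), find, numeric(1))
    groups <- split(S, roots)
    if (length(groups) == 1) {
      # unresolvable: polytomy over the taxa of S
      return(sprintf("(%s)", paste(dist$taxa[S], collapse = ",")))
    }
    sprintf("(%s)", paste(vapply(groups, build, character(1)), collapse = ","))
  }
  txt <- build(seq_len(n))
  if (!startsWith(txt, "(")) txt <- sprintf("(%s)", txt)
  st <- parse_newick(paste0(txt, ";"))
  st$rooted <- TRUE
  st
}

#' Assemble MLBS replicate sets from per-gene bootstrap trees
#'
#' Replicate `R_i` contains the i-th bootstrap tree of every
#' gene/supergene. When a `binning` is supplied as `weighting`, the
#' input must hold one bootstrap list per bin and each bin's i-th tree
#' is replicated by the bin size (the weighted pipeline).
#'
#' @param per_gene_bootstrap list (per gene or per bin) of lists of `b`
#'   trees each, all the same length.
#' @param weighting optional `binning`.
#' @return a `replicate_set`: list with `replicates` (length `b`, each a
#'   list of trees) and `b`.
#' @export
assemble_replicates <- function(per_gene_bootstrap, weighting = NULL) {
  bs <- lengths(per_gene_bootstrap)
  if (!length(bs)) stop_validation("no bootstrap trees")
  if (length(unique(bs)) != 1) {
    stop_validation("unequal replicate counts across genes: %s", paste(unique(bs), collapse = ","))
  }
  b <- bs[1]
  if (!is.null(weighting)) {
    if (length(per_gene_bootstrap) != length(weighting$bins)) {
      stop_validation("weighting expects one bootstrap list per bin (%d bins, %d lists)",
                      length(weighting$bins), length(per_gene_bootstrap))
    }
    mult <- lengths(weighting$bins)
  } else {
    mult <- rep(1L, length(per_gene_bootstrap))
  }
  reps <- lapply(seq_len(b), function(i) {
    unlist(lapply(seq_along(per_gene_bootstrap), function(g) {
      rep(per_gene_bootstrap[[g]][i], mult[g])
    }), recursive = FALSE)
  })
  structure(list(replicates = reps, b = b), class = "replicate_set")
}

#' Site-only multi-locus bootstrapping
#'
#' Applies the summary method to every replicate tree list and returns
#' the greedy consensus of the resulting species trees, with supports
#' counting bipartition occurrences across replicates.
#'
#' @param replicates a `replicate_set`.
#' @param summary function mapping a list of trees to a species tree
#'   (e.g. `function(ts) rstar_species_tree(triplet_counts(ts))`).
#' @return a [support_tree] with frequency supports.
#' @export
mlbs <- function(replicates, summary) {
  if (!inherits(replicates, "replicate_set")) stop_validation("`replicates` must be a replicate_set")
  species <- lapply(replicates$replicates, summary)
  greedy_consensus(species)
}
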