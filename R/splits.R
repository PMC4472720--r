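# Bipartition (split) machinery. Splits are encoded as bitmasks over the
# sorted leaf labels: bit i set <=> i-th smallest taxon on the split side.
# The canonical side is the one NOT containing the lexicographically
# smallest taxon, so two encodings of one split always compare equal.
# Masks are plain 31-bit integers, which caps trees at 30 taxa -- far
# beyond the desk scale this package targets.

MAX_TAXA <- 30L

full_mask <- function(n) as.integer(2^n - 1)

canonical_mask <- function(mask, n) {
  ifelse(bitwAnd(mask, 1L) == 1L, bitwXor(full_mask(n), mask), mask)
}

#' Non-trivial bipartitions of a tree
#'
#' Returns the non-trivial splits of the unrooted view of the tree, with
#' the support and branch length attached to each. A binary unrooted
#' tree on n leaves has n - 3 such splits; trees with fewer than 4
#' leaves have none.
#'
#' @param st a [support_tree].
#' @return a data.frame with columns `mask` (canonical bitmask over the
#'   sorted leaf labels), `support`, `length`; attributes `leaves`
#'   (sorted labels) and `full` (the full-set mask).
#' @export
tree_splits <- function(st) {
  phy <- st$phy
  ntip <- length(phy$tip.label)
  if (ntip > MAX_TAXA) stop_validation("split operations support at most %d taxa", MAX_TAXA)
  leaves <- sort(phy$tip.label)
  empty <- data.frame(mask = integer(0), support = numeric(0), length = numeric(0))
  attr(empty, "leaves") <- leaves
  attr(empty, "full") <- full_mask(ntip)
  if (ntip < 4) return(empty)

  nnode <- phy$Nnode
  masks <- integer(ntip + nnode)
  masks[seq_len(ntip)] <- bitwShiftL(1L, match(phy$tip.label, leaves) - 1L)
  po <- stats::reorder(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    masks[po$edge[k, 1]] <- bitwOr(masks[po$edge[k, 1]], masks[po$edge[k, 2]])
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  internal <- setdiff((ntip + 1L):(ntip + nnode), root)
  if (!length(internal)) return(empty)

  edge_of <- match(internal, phy$edge[, 2])
  cm <- canonical_mask(masks[internal], ntip)
  sz <- popcount(cm)
  keep <- sz >= 2 & sz <= ntip - 2
  cm <- cm[keep]; internal <- internal[keep]; edge_of <- edge_of[keep]
  sup <- st$supports[internal - ntip]
  len <- if (is.null(phy$edge.length)) rep(NA_real_, length(edge_of)) else phy$edge.length[edge_of]

  # A rooted binary root yields the same unrooted split from both of its
  # children: merge, preferring a recorded support and pooling the two
  # edge lengths into the single unrooted edge.
  if (anyDuplicated(cm)) {
    first <- match(cm, cm)
    for (i in which(first != seq_along(cm))) {
      j <- first[i]
      if (is.na(sup[j]) && !is.na(sup[i])) sup[j] <- sup[i]
      if (!is.na(len[i])) len[j] <- ifelse(is.na(len[j]), len[i], len[j] + len[i])
    }
    keep2 <- first == seq_along(cm)
    cm <- cm[keep2]; sup <- sup[keep2]; len <- len[keep2]
  }
  out <- data.frame(mask = cm, support = sup, length = len)
  attr(out, "leaves") <- leaves
  attr(out, "full") <- full_mask(ntip)
  out
}

#' Robinson-Foulds distance between two trees
#'
#' @param t1,t2 [support_tree]s on identical leaf sets.
#' @return list with `count` (size of the symmetric difference of split
#'   sets) and `normalized` (count divided by the total number of splits
#'   in the two trees; 0 when both trees are stars). For two binary
#'   trees the normalized value equals the missing-branch (FN) rate of
#'   either tree against the other.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  m1 <- tree_splits(t1)$mask
  m2 <- tree_splits(t2)$mask
  count <- sum(!(m1 %in% m2)) + sum(!(m2 %in% m1))
  denom <- length(m1) + length(m2)
  list(count = as.integer(count),
       normalized = if (denom == 0) 0 else count / denom)
}

# Non-trivial rooted clade masks (2 <= size <= n-1) over sorted leaves;
# used where the unrooted split set is degenerate (n < 4).
rooted_clade_masks <- function(st) {
  phy <- st$phy
  ntip <- length(phy$tip.label)
  leaves <- sort(phy$tip.label)
  masks <- integer(ntip + phy$Nnode)
  masks[seq_len(ntip)] <- bitwShiftL(1L, match(phy$tip.label, leaves) - 1L)
  po <- stats::reorder(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    masks[po$edge[k, 1]] <- bitwOr(masks[po$edge[k, 1]], masks[po$edge[k, 2]])
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  m <- masks[setdiff((ntip + 1L):(ntip + phy$Nnode), root)]
  sz <- popcount(m)
  m[sz >= 2 & sz <= ntip - 1]
}

# Are all pairs (a in ma) x (b in mb) of splits pairwise compatible?
# Splits A|A' and B|B' are compatible iff one of the four intersections
# A&B, A&B', A'&B, A'&B' is empty; on bitmasks that is x == 0, x == a
# (a within b), x == b, or a|b == full.
masks_pairwise_compatible <- function(ma, mb, full) {
  if (!length(ma) || !length(mb)) return(TRUE)
  a <- rep(ma, each = length(mb))
  b <- rep(mb, times = length(ma))
  x <- bitwAnd(a, b)
  all(x == 0L | x == a | x == b | bitwOr(a, b) == full)
}

#' Build a tree from a compatible set of splits
#'
#' Canonical split sides (excluding the smallest taxon) of a pairwise
#' compatible set form a laminar family; the tree is reassembled by
#' containment. The result is an unrooted tree represented with a basal
#' polytomy at the smallest taxon.
#'
#' @param leaves character vector of taxon labels.
#' @param mask integer vector of canonical split masks (may be empty).
#' @param support,length optional per-split annotation vectors.
#' @param pendant optional named vector of pendant branch lengths.
#' @return a [support_tree] with `rooted = FALSE`.
#' @export
tree_from_splits <- function(leaves, mask, support = NULL, length = NULL, pendant = NULL) {
  leaves <- sort(leaves)
  n <- base::length(leaves)
  if (n > MAX_TAXA) stop_validation("at most %d taxa supported", MAX_TAXA)
  k <- base::length(mask)
  support <- support %||% rep(NA_real_, k)
  length <- length %||% rep(NA_real_, k)
  full <- full_mask(n)
  ord <- order(popcount(mask))
  mask <- mask[ord]; support <- support[ord]; length <- length[ord]

  # parent[i]: index of the smallest split strictly containing split i (0 = root)
  parent <- integer(k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      sup_idx <- which(bitwAnd(mask[(i + 1):k], mask[i]) == mask[i]) + i
      parent[i] <- if (base::length(sup_idx)) sup_idx[1] else 0L
    }
  }
  leaf_bits <- bitwShiftL(1L, seq_len(n) - 1L)
  leaf_parent <- vapply(seq_len(n), function(j) {
    inside <- which(bitwAnd(mask, leaf_bits[j]) == leaf_bits[j])
    if (base::length(inside)) inside[1] else 0L
  }, integer(1))

  pend_str <- function(j) {
    if (is.null(pendant) || is.na(pendant[leaves[j]])) leaves[j]
    else sprintf("%s:%.10g", leaves[j], pendant[leaves[j]])
  }
  emit <- function(i) { # i = split index, 0 = root
    kids_s <- which(parent == i)
    kids_l <- which(leaf_parent == i)
    parts <- c(vapply(kids_s, emit, character(1)),
               vapply(kids_l, pend_str, character(1)))
    if (i == 0L) return(sprintf("(%s);", paste(parts, collapse = ",")))
    lab <- if (is.na(support[i])) "" else sprintf("%.10g", support[i])
    len <- if (is.na(length[i])) "" else sprintf(":%.10g", length[i])
    sprintf("(%s)%s%s", paste(parts, collapse = ","), lab, len)
  }
  st <- parse_newick(emit(0L))
  st$rooted <- FALSE
  st
}

#' Collapse branches with low bootstrap support
#'
#' Contracts every internal (non-trivial) edge whose support is strictly
#' below the threshold `B`; edges with support `>= B` survive. The leaf
#' set is unchanged. Internal branch lengths of surviving edges are
#' kept; the contracted edges' lengths are discarded (as in
#' [ape::di2multi()]).
#'
#' @param st a [support_tree]; every non-trivial split must carry a
#'   support value (a missing support is a validation error -- the
#'   caller must decide a default).
#' @param B support threshold on the 0--100 scale.
#' @return a [support_tree] on the same leaves (unrooted view).
#' @export
collapse_low_support <- function(st, B) {
  sp <- tree_splits(st)
  if (nrow(sp) && anyNA(sp$support)) {
    stop_validation("missing support on %d internal edge(s); assign supports before collapsing",
                    sum(is.na(sp$support)))
  }
  keep <- sp$support >= B
  pend <- pendant_lengths(st)
  tree_from_splits(attr(sp, "leaves"), sp$mask[keep],
                   support = sp$support[keep], length = sp$length[keep],
                   pendant = pend)
}

# Pendant branch lengths in the unrooted view (a leaf hanging directly
# off a degree-2 root absorbs the opposite root edge).
pendant_lengths <- function(st) {
  phy <- st$phy
  if (is.null(phy$edge.length)) return(NULL)
  ntip <- length(phy$tip.label)
  out <- stats::setNames(rep(NA_real_, ntip), phy$tip.label)
  for (j in seq_len(ntip)) {
    e <- match(j, phy$edge[, 2])
    out[j] <- phy$edge.length[e]
  }
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  root_children <- phy$edge[phy$edge[, 1] == root, 2]
  if (length(root_children) == 2) {
    leaf_child <- root_children[root_children <= ntip]
    if (length(leaf_child) == 1) {
      other <- setdiff(root_children, leaf_child)
      out[leaf_child] <- out[leaf_child] +
        phy$edge.length[match(other, phy$edge[, 2])]
    }
  }
  out[sort(names(out))]
}
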