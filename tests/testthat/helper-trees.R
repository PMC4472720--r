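# Shared fixtures: all generated in code, seeded by the caller.

# Random unrooted binary tree with supports on every internal edge.
rand_support_tree <- function(n, support = NULL) {
  phy <- ape::rtree(n, rooted = FALSE)
  phy$node.label <- NULL
  sup <- if (is.null(support)) round(stats::runif(phy$Nnode, 0, 100), 1)
         else rep(support, phy$Nnode)
  support_tree(phy, supports = sup, rooted = FALSE)
}

# Canonical topology fingerprint (same leaf set assumed).
topology_key <- function(st) paste(sort(tree_splits(st)$mask), collapse = "-")

# K topologically distinct random binary trees on n taxa, all with the
# given support on every internal edge.
distinct_topologies <- function(K, n, support = 100) {
  out <- list(); keys <- character(0)
  while (length(out) < K) {
    t <- rand_support_tree(n, support = support)
    k <- topology_key(t)
    if (!k %in% keys) { out[[length(out) + 1L]] <- t; keys <- c(keys, k) }
  }
  out
}

# Multiset equality of topologies.
same_topology_multiset <- function(ts1, ts2) {
  identical(sort(vapply(ts1, topology_key, character(1))),
            sort(vapply(ts2, topology_key, character(1))))
}

# Brute-force compatibility oracle: two support trees are combinable at
# B iff some binary tree on the leaf set refines both collapsed trees.
oracle_compatible <- function(t1, t2, B) {
  c1 <- collapse_low_support(t1, B)
  c2 <- collapse_low_support(t2, B)
  taxa <- sort(t1$phy$tip.label)
  n <- length(taxa)
  m1 <- tree_splits(c1)$mask
  m2 <- tree_splits(c2)$mask
  topos <- statbin:::enumerate_topologies(n)
  for (e in topos) {
    bm <- tree_splits(statbin:::topology_to_support_tree(e, n, taxa))$mask
    if (all(m1 %in% bm) && all(m2 %in% bm)) return(TRUE)
  }
  FALSE
}

# Alignment with every taxon identical (constant partition).
constant_alignment <- function(taxa, k, base = "A") {
  dna_alignment(stats::setNames(rep(paste(rep(base, k), collapse = ""), length(taxa)), taxa))
}
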