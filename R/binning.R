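# Statistical binning: threshold compatibility, the incompatibility
# graph, and the clique-seeded balanced greedy (Brelaz-style) coloring.
#
# Threshold semantics, fixed here for the whole package: a conflict
# between two gene trees requires incompatible branches supported at
# >= B in BOTH trees; equivalently, collapsing removes branches with
# support strictly below B.

# Split masks surviving the support threshold.
thresholded_masks <- function(st, B) {
  sp <- tree_splits(st)
  if (nrow(sp) && anyNA(sp$support)) {
    stop_validation("gene tree has %d internal edge(s) without support",
                    sum(is.na(sp$support)))
  }
  sp$mask[sp$support >= B]
}

#' Are two support-annotated gene trees combinable at threshold B?
#'
#' True iff, after collapsing all branches with support below `B`, the
#' two trees share a common refinement. Pairwise compatibility of every
#' split of one with every split of the other is necessary and
#' sufficient, since pairwise-compatible splits on one leaf set are
#' jointly realizable in a single tree.
#'
#' @param t1,t2 [support_tree]s on identical leaf sets with supports on
#'   all internal edges.
#' @param B bootstrap support threshold (0--100).
#' @return logical.
#' @export
are_compatible <- function(t1, t2, B) {
  check_same_leaves(t1, t2)
  m1 <- thresholded_masks(t1, B)
  m2 <- thresholded_masks(t2, B)
  masks_pairwise_compatible(m1, m2, full_mask(n_tips(t1)))
}

#' Build the incompatibility graph over a set of gene trees
#'
#' Vertices are genes in input order; an edge joins genes i and j iff
#' their trees are not combinable at threshold `B`. Trees with identical
#' thresholded split sets are recognized up front so that only distinct
#' pairs pay for the pairwise test.
#'
#' @param trees list of [support_tree]s on identical leaf sets.
#' @param B support threshold (0--100).
#' @return an `incompatibility_graph`: list with `n` (vertex count),
#'   `adj` (logical adjacency matrix), `B`.
#' @export
build_incompatibility_graph <- function(trees, B) {
  p <- length(trees)
  if (p < 1) stop_validation("need at least one gene tree")
  for (i in seq_len(p - 1) + 1L) check_same_leaves(trees[[1]], trees[[i]])
  full <- full_mask(n_tips(trees[[1]]))
  masks <- lapply(seq_len(p), function(i) {
    tryCatch(thresholded_masks(trees[[i]], B), error = function(e) {
      stop_validation("gene %d: %s", i, conditionMessage(e))
    })
  })
  keys <- vapply(masks, function(m) paste(sort(m), collapse = "."), character(1))
  uk <- unique(keys)
  ui <- match(uk, keys)
  nu <- length(uk)
  uadj <- matrix(FALSE, nu, nu)
  if (nu > 1) {
    for (a in seq_len(nu - 1)) {
      for (b in (a + 1):nu) {
        inc <- !masks_pairwise_compatible(masks[[ui[a]]], masks[[ui[b]]], full)
        uadj[a, b] <- uadj[b, a] <- inc
      }
    }
  }
  grp <- match(keys, uk)
  adj <- uadj[grp, grp, drop = FALSE]
  diag(adj) <- FALSE
  dimnames(adj) <- NULL
  structure(list(n = p, adj = adj, B = B), class = "incompatibility_graph")
}

#' @export
print.incompatibility_graph <- function(x, ...) {
  cat(sprintf("incompatibility_graph: %d genes, %d edges (B = %g)\n",
              x$n, sum(x$adj) / 2, x$B))
  invisible(x)
}

#' Greedy seed clique of the incompatibility graph
#'
#' Repeatedly adds the highest-degree vertex adjacent to all current
#' members, breaking ties by lowest input index. The empty graph yields
#' a singleton clique (its first vertex).
#'
#' @param graph an `incompatibility_graph`.
#' @return integer vector of gene indices, pairwise adjacent.
#' @export
seed_clique <- function(graph) {
  n <- graph$n
  if (n == 0) return(integer(0))
  deg <- rowSums(graph$adj)
  clique <- integer(0)
  candidates <- seq_len(n)
  repeat {
    v <- candidates[which.max(deg[candidates])] # which.max takes lowest index on ties
    clique <- c(clique, v)
    candidates <- candidates[graph$adj[candidates, v]]
    if (!length(candidates)) break
  }
  sort(clique)
}

#' Balanced greedy coloring of the incompatibility graph
#'
#' Stage 1 places each member of the greedy seed clique in its own bin
#' (in input-index order). Stage 2 repeatedly selects the unplaced gene
#' that conflicts with the largest number of existing bins (ties broken
#' by lowest input index) and places it in the smallest bin with which
#' it has no conflict; bin-size ties are broken uniformly at random from
#' the seeded RNG, and a new bin is opened only when no existing bin
#' admits the gene.
#'
#' @param graph an `incompatibility_graph`.
#' @param seed integer RNG seed for the random bin-size tie-break
#'   (default 42); the caller's RNG state is untouched.
#' @return a `binning`: list with `bins` (list of integer gene-index
#'   vectors), `threshold`, `n_genes`.
#' @export
balanced_color <- function(graph, seed = 42L) {
  n <- graph$n
  adj <- graph$adj
  with_seed(seed, {
    clique <- seed_clique(graph)
    bins <- lapply(clique, function(v) v)
    placed <- rep(FALSE, n)
    placed[clique] <- TRUE
    while (!all(placed)) {
      # conflict counts against existing bins, for the dynamic ordering
      todo <- which(!placed)
      nconf <- vapply(todo, function(v) {
        sum(vapply(bins, function(b) any(adj[v, b]), logical(1)))
      }, numeric(1))
      v <- todo[which.max(nconf)]
      ok <- which(!vapply(bins, function(b) any(adj[v, b]), logical(1)))
      if (!length(ok)) {
        bins[[length(bins) + 1L]] <- v
      } else {
        sizes <- lengths(bins)[ok]
        best <- ok[sizes == min(sizes)]
        pick <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
        bins[[pick]] <- c(bins[[pick]], v)
      }
      placed[v] <- TRUE
    }
    structure(list(bins = bins, threshold = graph$B, n_genes = n),
              class = "binning")
  })
}

#' @export
print.binning <- function(x, ...) {
  cat(sprintf("binning: %d genes in %d bins (sizes %s)\n", x$n_genes,
              length(x$bins), paste(sort(lengths(x$bins), decreasing = TRUE), collapse = ",")))
  invisible(x)
}

check_supergene_trees <- function(binning, supergene_trees) {
  nb <- length(binning$bins)
  if (length(supergene_trees) != nb) {
    stop_validation("need one supergene tree per bin (%d bins, %d trees)",
                    nb, length(supergene_trees))
  }
  for (b in seq_len(nb)) {
    if (length(binning$bins[[b]]) > 0 && is.null(supergene_trees[[b]])) {
      stop_validation("missing supergene tree for non-empty bin %d", b)
    }
  }
}

#' Weighted supergene tree output
#'
#' Each bin's supergene tree is repeated as many times as the bin has
#' genes, so the output multiset has one tree per input gene and the
#' supergene-tree distribution tracks the gene-tree distribution.
#' Output order: bins in order, genes within a bin in order.
#'
#' @param binning a `binning`.
#' @param supergene_trees list of [support_tree], one per bin.
#' @return list of [support_tree] of length `binning$n_genes`.
#' @export
weight_bins <- function(binning, supergene_trees) {
  check_supergene_trees(binning, supergene_trees)
  out <- list()
  for (b in seq_along(binning$bins)) {
    out <- c(out, rep(supergene_trees[b], length(binning$bins[[b]])))
  }
  out
}

#' Unweighted supergene tree output (one tree per non-empty bin)
#'
#' @inheritParams weight_bins
#' @return list of [support_tree], one per non-empty bin, in bin order.
#' @export
unweighted_output <- function(binning, supergene_trees) {
  check_supergene_trees(binning, supergene_trees)
  supergene_trees[lengths(binning$bins) > 0]
}

#' Write a gene-to-bin membership table
#'
#' @param binning a `binning`.
#' @param file path for a two-column TSV (`gene_id`, `bin_id`).
#' @param gene_ids optional character ids (default `g1..gp`).
#' @export
write_bin_table <- function(binning, file, gene_ids = NULL) {
  gene_ids <- gene_ids %||% paste0("g", seq_len(binning$n_genes))
  rows <- do.call(rbind, lapply(seq_along(binning$bins), function(b) {
    cbind(gene = gene_ids[binning$bins[[b]]], bin = b)
  }))
  rows <- rows[order(match(rows[, 1], gene_ids)), , drop = FALSE]
  utils::write.table(data.frame(gene_id = rows[, 1], bin_id = rows[, 2]),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Dump the incompatibility graph in GraphViz DOT format
#'
#' @param graph an `incompatibility_graph`.
#' @param file output path.
#' @export
write_dot <- function(graph, file) {
  ij <- which(graph$adj & upper.tri(graph$adj), arr.ind = TRUE)
  writeLines(c("graph incompatibility {",
               sprintf("  g%d;", seq_len(graph$n)),
               sprintf("  g%d -- g%d;", ij[, 1], ij[, 2]),
               "}"), file)
  invisible(file)
}
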