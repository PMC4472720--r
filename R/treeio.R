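#' Support-annotated phylogenetic trees
#'
#' A `support_tree` wraps an [ape::phylo] topology together with a
#' per-internal-node vector of bootstrap supports on the 0--100 scale
#' (`NA` = missing, which is distinct from 0) and an explicit `rooted`
#' flag. Rooted operations (triplet extraction, coalescent simulation)
#' require `rooted = TRUE`; all split-based operations act on the
#' unrooted view of the tree.
#'
#' @param phy an [ape::phylo] object.
#' @param supports numeric vector of length `phy$Nnode` with values in
#'   `[0, 100]` or `NA`; if `NULL`, supports are taken from numeric
#'   `phy$node.label` entries when present.
#' @param rooted logical; defaults to [ape::is.rooted()] of `phy`.
#' @return an object of class `support_tree`.
#' @export
support_tree <- function(phy, supports = NULL, rooted = NULL) {
  if (!inherits(phy, "phylo")) stop_validation("`phy` must be an ape phylo object")
  tips <- phy$tip.label
  if (anyDuplicated(tips)) {
    stop_validation("duplicate taxon label(s): %s",
                    paste(unique(tips[duplicated(tips)]), collapse = ", "))
  }
  if (any(!nzchar(tips))) stop_validation("empty taxon label")
  if (any(grepl("[(),:;]", tips))) {
    stop_validation("taxon labels may not contain Newick metacharacters")
  }
  if (is.null(supports)) {
    labs <- phy$node.label
    if (is.null(labs)) {
      supports <- rep(NA_real_, phy$Nnode)
    } else {
      supports <- suppressWarnings(as.numeric(labs))
      supports[!nzchar(labs)] <- NA_real_
    }
  }
  supports <- as.numeric(supports)
  if (length(supports) != phy$Nnode) {
    stop_validation("supports must have one entry per internal node (%d), got %d",
                    phy$Nnode, length(supports))
  }
  ok <- is.na(supports) | (supports >= 0 & supports <= 100)
  if (!all(ok)) stop_validation("supports must lie in [0, 100]")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0, na.rm = TRUE)) {
    stop_validation("negative branch length")
  }
  phy$node.label <- NULL
  structure(
    list(phy = phy, supports = supports,
         rooted = if (is.null(rooted)) ape::is.rooted(phy) else isTRUE(rooted)),
    class = "support_tree"
  )
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("support_tree: %d tips, %s, %d/%d internal supports\n",
              length(x$phy$tip.label), if (x$rooted) "rooted" else "unrooted",
              sum(!is.na(x$supports)), x$phy$Nnode))
  invisible(x)
}

n_tips <- function(st) length(st$phy$tip.label)

leaf_labels <- function(st) sort(st$phy$tip.label)

#' Parse a Newick string into a support tree
#'
#' Bootstrap supports can be encoded either as internal-node labels
#' (RAxML bipartition style, the default) or as bracketed branch
#' comments following the branch length (`):0.1[95]`).
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @param support_convention `"node_label"` or `"branch_comment"`.
#' @return a [support_tree].
#' @export
parse_newick <- function(text, support_convention = c("node_label", "branch_comment")) {
  support_convention <- match.arg(support_convention)
  text <- trimws(text)
  depth <- cumsum((strsplit(text, "")[[1]] == "(") - (strsplit(text, "")[[1]] == ")"))
  if (any(depth < 0)) {
    stop_validation("malformed Newick: unbalanced ')' at character %d",
                    which(depth < 0)[1])
  }
  if (length(depth) && depth[length(depth)] != 0) {
    stop_validation("malformed Newick: %d unclosed '(' at end of string",
                    depth[length(depth)])
  }
  if (support_convention == "branch_comment") {
    # move "[support]" after a branch length onto the node label position
    text <- gsub("\\)(:[0-9.eE+-]+)?\\[([0-9.]+)\\]", ")\\2\\1", text)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop_validation("malformed Newick near character 1: cannot parse")
  support_tree(phy)
}

#' Write a support tree as Newick
#'
#' Supports are written as internal-node labels; branch lengths, when
#' present, follow `:` as usual.
#'
#' @param st a [support_tree].
#' @param file optional path; when `NULL` the string is returned.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(st, file = NULL) {
  phy <- st$phy
  if (any(!is.na(st$supports))) {
    phy$node.label <- ifelse(is.na(st$supports), "", sprintf("%.10g", st$supports))
  }
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read / write multi-tree Newick files (one tree per line)
#'
#' @param file path to a file of Newick strings, one per line.
#' @param support_convention passed to [parse_newick()].
#' @return a list of [support_tree] objects.
#' @export
read_gene_trees <- function(file, support_convention = "node_label") {
  if (!file.exists(file)) stop_io("no such file: %s", file)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick, support_convention = support_convention)
}

#' @rdname read_gene_trees
#' @param trees list of [support_tree] objects.
#' @export
write_gene_trees <- function(trees, file) {
  writeLines(vapply(trees, write_newick, character(1)), file)
  invisible(file)
}

#' Root a tree at an outgroup taxon
#'
#' Supports are dropped: after rerooting, node labels no longer map onto
#' the same internal edges, so carrying them over would be misleading.
#'
#' @param st a [support_tree].
#' @param outgroup a taxon name present in the tree.
#' @return a rooted [support_tree] without supports.
#' @export
root_at_outgroup <- function(st, outgroup) {
  if (!outgroup %in% st$phy$tip.label) {
    stop_validation("outgroup '%s' is not a taxon of the tree", outgroup)
  }
  phy <- st$phy
  phy$node.label <- NULL
  phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  support_tree(phy, supports = rep(NA_real_, phy$Nnode), rooted = TRUE)
}

check_same_leaves <- function(t1, t2) {
  l1 <- leaf_labels(t1); l2 <- leaf_labels(t2)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop_validation("leaf sets differ (only in first: %s; only in second: %s)",
                    paste(only1, collapse = ","), paste(only2, collapse = ","))
  }
  invisible(TRUE)
}
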