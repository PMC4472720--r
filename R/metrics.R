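# Evaluation statistics: missing-branch (FN) rate, branch-length
# ratios, per-triplet Jensen-Shannon divergence with its ECDF, and the
# support-ordered edge-quality curve.

#' Missing-branch (false negative) rate
#'
#' The proportion of internal branches of the (binary) true tree absent
#' from the estimated tree.
#'
#' @param true_tree binary [support_tree] (the model tree).
#' @param est_tree estimated [support_tree] on the same leaves.
#' @return fraction in `[0, 1]`.
#' @export
fn_rate <- function(true_tree, est_tree) {
  check_same_leaves(true_tree, est_tree)
  tm <- tree_splits(true_tree)$mask
  n <- n_tips(true_tree)
  if (length(tm) != n - 3) {
    stop_validation("true tree must be binary (%d of %d splits present)", length(tm), n - 3)
  }
  em <- tree_splits(est_tree)$mask
  sum(!(tm %in% em)) / length(tm)
}

#' Branch-length ratios for shared true branches
#'
#' For every internal branch of the true tree that also appears in the
#' estimated tree, the ratio estimated/true length. 1 means correct
#' estimation; values below 1 flag under-estimated branch lengths
#' (over-estimated ILS).
#'
#' @param true_tree,est_tree [support_tree]s with internal branch
#'   lengths, identical leaf sets.
#' @return data.frame with `split` (taxa on the canonical side) and
#'   `ratio`; zero rows when no split is shared.
#' @export
branch_length_ratios <- function(true_tree, est_tree) {
  check_same_leaves(true_tree, est_tree)
  ts <- tree_splits(true_tree)
  es <- tree_splits(est_tree)
  shared <- match(ts$mask, es$mask)
  keep <- !is.na(shared)
  if (!any(keep)) return(data.frame(split = character(0), ratio = numeric(0)))
  if (any(is.na(ts$length[keep])) || any(is.na(es$length[shared[keep]]))) {
    stop_validation("both trees must carry lengths on shared internal edges")
  }
  if (any(ts$length[keep] == 0)) stop_validation("shared true branch with zero length")
  leaves <- attr(ts, "leaves")
  lab <- vapply(ts$mask[keep], function(m) {
    paste(leaves[bitwAnd(bitwShiftL(1L, seq_along(leaves) - 1L), m) != 0L], collapse = "|")
  }, character(1))
  data.frame(split = lab, ratio = es$length[shared[keep]] / ts$length[keep])
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' `JS(P,Q) = KL(P,M)/2 + KL(Q,M)/2` with `M = (P+Q)/2`, natural
#' logarithm, and the convention `0 log 0 = 0`. Bounded by `log(2)`.
#'
#' @param p,q non-negative vectors of equal length; normalized
#'   internally.
#' @param base logarithm base (default `exp(1)`).
#' @return a scalar in `[0, log(2)/log(base)]`.
#' @export
js_divergence <- function(p, q, base = exp(1)) {
  if (length(p) != length(q)) stop_validation("distributions differ in length")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i]) - log(b[i])))
  }
  (kl(p, m) / 2 + kl(q, m) / 2) / log(base)
}

#' Per-triplet Jensen-Shannon divergence between triplet distributions
#'
#' One divergence per taxon triplet between the two per-triplet
#' frequency vectors over the three rooted topologies, plus the
#' empirical cumulative distribution of those divergences. Triplets
#' unresolved in either distribution give `NA` and are excluded from
#' the ECDF.
#'
#' @param true_dist,est_dist `triplet_distribution`s over the same taxa.
#' @param base logarithm base (natural log by default).
#' @return list with `js` (per-triplet vector), `ecdf` (an
#'   [stats::ecdf] over the non-`NA` values), `trip`, `taxa`.
#' @export
triplet_js_divergence <- function(true_dist, est_dist, base = exp(1)) {
  if (!identical(true_dist$taxa, est_dist$taxa)) {
    stop_validation("triplet distributions are over different taxon sets")
  }
  P <- triplet_frequencies(true_dist)
  Q <- triplet_frequencies(est_dist)
  js <- vapply(seq_len(nrow(P)), function(i) {
    if (anyNA(P[i, ]) || anyNA(Q[i, ])) return(NA_real_)
    js_divergence(P[i, ], Q[i, ], base = base)
  }, numeric(1))
  ok <- js[!is.na(js)]
  list(js = js, ecdf = if (length(ok)) stats::ecdf(ok) else NULL,
       trip = true_dist$trip, taxa = true_dist$taxa)
}

#' Support-ordered edge quality curve
#'
#' Orders the internal branches of an estimated species tree by
#' quality: true positive branches by descending support, then false
#' positive branches by ascending support. Flags false positives with
#' support above 75, the branches most likely to mislead.
#'
#' @param est_trees a [support_tree] with supports, or a list of them
#'   (edges are pooled in input order).
#' @param true_tree the reference [support_tree].
#' @param fp_flag_support threshold for flagging high-support false
#'   positives (default 75).
#' @return data.frame with `class` ("TP"/"FP"), `support`,
#'   `cum_fraction`, `flagged`, ordered as plotted.
#' @export
edge_quality_curve <- function(est_trees, true_tree, fp_flag_support = 75) {
  if (inherits(est_trees, "support_tree")) est_trees <- list(est_trees)
  tm <- tree_splits(true_tree)$mask
  rows <- do.call(rbind, lapply(est_trees, function(t) {
    check_same_leaves(t, true_tree)
    sp <- tree_splits(t)
    if (!nrow(sp)) return(NULL)
    data.frame(class = ifelse(sp$mask %in% tm, "TP", "FP"), support = sp$support)
  }))
  if (is.null(rows) || !nrow(rows)) {
    return(data.frame(class = character(0), support = numeric(0),
                      cum_fraction = numeric(0), flagged = logical(0)))
  }
  tp <- rows[rows$class == "TP", , drop = FALSE]
  fp <- rows[rows$class == "FP", , drop = FALSE]
  out <- rbind(tp[order(-tp$support), , drop = FALSE],
               fp[order(fp$support), , drop = FALSE])
  out$cum_fraction <- seq_len(nrow(out)) / nrow(out)
  out$flagged <- out$class == "FP" & out$support > fp_flag_support
  rownames(out) <- NULL
  out
}
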