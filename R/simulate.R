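# Synthetic data: multispecies-coalescent gene trees within a species
# tree, and GTR+Gamma sequence evolution down gene trees.

#' Species tree model for coalescent simulation
#'
#' @param tree a rooted binary [support_tree] whose branch lengths are
#'   in coalescent units (internal branches strictly positive).
#' @param theta optional population-size parameter (theta = 4*N*mu),
#'   recorded for provenance only; simulation works directly in
#'   coalescent units.
#' @return a `species_tree_model`.
#' @export
species_tree_model <- function(tree, theta = NULL) {
  if (!inherits(tree, "support_tree")) stop_validation("`tree` must be a support_tree")
  if (!tree$rooted) stop_validation("species tree must be rooted")
  if (!ape::is.binary(tree$phy)) stop_validation("species tree must be binary")
  if (is.null(tree$phy$edge.length)) stop_validation("species tree needs branch lengths (coalescent units)")
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  internal_edge <- phy$edge[, 2] > ntip
  if (any(phy$edge.length[internal_edge] <= 0)) {
    stop_validation("internal branches must have positive coalescent length")
  }
  structure(list(tree = tree, theta = theta), class = "species_tree_model")
}

#' The 15-taxon high-ILS caterpillar fixture (and its generalization)
#'
#' A rooted ultrametric caterpillar (pectinate ladder): the cherry
#' `(t01, t02)` sits at the tip of a ladder of short internal branches,
#' each `internal_len` coalescent units long; the cherry's pendant
#' branches also have length `internal_len`, and ultrametricity fixes
#' the remaining pendant lengths. For `n = 15`, `internal_len = 0.1`
#' this is the high-ILS model with 12 successive unrooted internal
#' branches of 0.1 coalescent units.
#'
#' @param n number of taxa (>= 4), default 15.
#' @param internal_len internal branch length in coalescent units,
#'   default 0.1.
#' @return a `species_tree_model`.
#' @export
make_caterpillar_species_tree <- function(n = 15, internal_len = 0.1) {
  if (n < 4) stop_validation("need at least 4 taxa for a caterpillar")
  lab <- sprintf("t%02d", seq_len(n))
  s <- sprintf("(%s:%.10g,%s:%.10g)", lab[1], internal_len, lab[2], internal_len)
  for (j in 3:n) {
    s <- sprintf("(%s:%.10g,%s:%.10g)", s, internal_len, lab[j], (j - 1) * internal_len)
  }
  st <- parse_newick(paste0(s, ";"))
  st$rooted <- TRUE
  species_tree_model(st)
}

# Heights above the tips for every node of a rooted tree with edge
# lengths (root height = max tip depth; works for non-ultrametric trees
# by sampling tips at their own heights).
node_heights <- function(phy) {
  phy <- stats::reorder(phy, "postorder")
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  depth <- rep(NA_real_, ntip + phy$Nnode)
  depth[root] <- 0
  for (k in rev(seq_len(nrow(phy$edge)))) {
    depth[phy$edge[k, 2]] <- depth[phy$edge[k, 1]] + phy$edge.length[k]
  }
  max(depth[seq_len(ntip)]) - depth
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Within each species-tree branch of duration T coalescent units, k
#' entering lineages coalesce after Exp(k(k-1)/2) waiting times;
#' lineages that fail to coalesce pass to the parent branch, and
#' coalescence continues above the root until one lineage remains.
#' Output trees are rooted, ultrametric in coalescent time (for an
#' ultrametric species tree), with branch lengths in coalescent units.
#'
#' @param model a `species_tree_model`.
#' @param p number of gene trees (>= 1).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of rooted [support_tree]s.
#' @export
simulate_gene_trees <- function(model, p, seed = 1L) {
  if (p < 1) stop_validation("p must be >= 1")
  phy <- stats::reorder(model$tree$phy, "postorder")
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  h <- node_heights(phy)
  # postorder species-node sequence and per-node children
  sp_children <- vector("list", ntip + phy$Nnode)
  for (k in seq_len(nrow(phy$edge))) {
    sp_children[[phy$edge[k, 1]]] <- c(sp_children[[phy$edge[k, 1]]], phy$edge[k, 2])
  }
  po_nodes <- unique(phy$edge[, 1])  # postorder parents: children first
  with_seed(seed, {
    lapply(seq_len(p), function(g) one_msc_tree(phy, ntip, root, h, sp_children, po_nodes))
  })
}

one_msc_tree <- function(phy, ntip, root, h, sp_children, po_nodes) {
  max_nodes <- 2L * ntip
  g_parent <- integer(max_nodes)
  g_time <- numeric(max_nodes)
  g_time[seq_len(ntip)] <- h[seq_len(ntip)]
  next_id <- ntip + 1L
  # lineage sets present at the TOP of each species node's branch
  lin <- vector("list", length(h))
  coalesce <- function(L, t0, duration) {
    t <- t0
    while (length(L) >= 2) {
      k <- length(L)
      dt <- stats::rexp(1, rate = k * (k - 1) / 2)
      if (t + dt - t0 > duration) break
      t <- t + dt
      pick <- sample.int(k, 2)
      new <- next_id; next_id <<- next_id + 1L
      g_time[new] <<- t
      g_parent[L[pick]] <<- new
      L <- c(L[-pick], new)
    }
    L
  }
  for (tip in seq_len(ntip)) {
    e <- match(tip, phy$edge[, 2])
    lin[[tip]] <- coalesce(tip, h[tip], phy$edge.length[e])
  }
  for (v in po_nodes) {
    L <- unlist(lin[sp_children[[v]]])
    if (v == root) {
      lin[[v]] <- coalesce(L, h[v], Inf)
    } else {
      e <- match(v, phy$edge[, 2])
      lin[[v]] <- coalesce(L, h[v], phy$edge.length[e])
    }
  }
  n_nodes <- next_id - 1L
  root_g <- lin[[root]]
  # edges parent -> child; renumber internals to ape convention
  kids <- seq_len(n_nodes)[g_parent[seq_len(n_nodes)] != 0L]
  internals <- (ntip + 1L):n_nodes
  newid <- integer(n_nodes)
  newid[seq_len(ntip)] <- seq_len(ntip)
  # root must become ntip+1
  ord <- c(root_g, setdiff(internals, root_g))
  newid[ord] <- ntip + seq_along(ord)
  edge <- cbind(newid[g_parent[kids]], newid[kids])
  len <- g_time[g_parent[kids]] - g_time[kids]
  phy_out <- structure(list(edge = edge, tip.label = phy$tip.label,
                            Nnode = n_nodes - ntip, edge.length = len),
                       class = "phylo")
  phy_out <- stats::reorder(phy_out, "postorder")
  support_tree(phy_out, supports = rep(NA_real_, n_nodes - ntip), rooted = TRUE)
}

#' GTR+Gamma simulation parameters
#'
#' Defaults are Jukes-Cantor (equal exchangeabilities and base
#' frequencies, no rate heterogeneity). The rate matrix is normalized
#' to one expected substitution per unit branch length at stationarity;
#' `rate_scale` converts coalescent-unit branch lengths to substitution
#' units (substitutions per site per coalescent unit).
#'
#' @param exchangeabilities six non-negative rates (AC, AG, AT, CG, CT, GT).
#' @param base_freqs four stationary frequencies summing to 1.
#' @param gamma_shape positive shape of the discrete Gamma rate
#'   distribution, or `NULL` for rate homogeneity.
#' @param n_categories number of discrete Gamma categories (default 4).
#' @param rate_scale substitutions per coalescent unit (default 1).
#' @return a `gtr_params` list.
#' @export
gtr_params <- function(exchangeabilities = rep(1, 6),
                       base_freqs = rep(0.25, 4),
                       gamma_shape = NULL, n_categories = 4L,
                       rate_scale = 1) {
  if (length(exchangeabilities) != 6 || any(exchangeabilities < 0)) {
    stop_validation("need 6 non-negative exchangeabilities")
  }
  if (length(base_freqs) != 4 || abs(sum(base_freqs) - 1) > 1e-12 || any(base_freqs <= 0)) {
    stop_validation("base_freqs must be 4 positive values summing to 1")
  }
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop_validation("gamma_shape must be positive")
  structure(list(exchangeabilities = exchangeabilities, base_freqs = base_freqs,
                 gamma_shape = gamma_shape, n_categories = as.integer(n_categories),
                 rate_scale = rate_scale), class = "gtr_params")
}

#' The 15-taxon high-ILS model, at the scale of the original protocol
#'
#' The published 15-taxon condition sets every internal branch (and the
#' cherry's pendant branches) to 0.005 substitutions per site with a
#' population parameter theta = 4*N*mu = 0.05 on all branches. In the
#' classical coalescent-unit convention used by
#' [simulate_gene_trees()] (k lineages coalesce at rate k(k-1)/2 per
#' unit of 2N generations) this is `2 * 0.005 / 0.05 = 0.2` units per
#' branch; the protocol's quoted "0.1 coalescence units" counts time in
#' 4N-generation (tau/theta) units. This fixture applies the
#' conversion, so that the mean gene-tree/species-tree discordance is
#' the published ~82%.
#'
#' @param subs_len internal branch length in substitutions per site
#'   (default 0.005).
#' @param theta population parameter 4*N*mu (default 0.05).
#' @return a `species_tree_model` (15 taxa, internal branches
#'   `2 * subs_len / theta` coalescent units).
#' @export
fifteen_taxon_model <- function(subs_len = 0.005, theta = 0.05) {
  m <- make_caterpillar_species_tree(15, 2 * subs_len / theta)
  m$theta <- theta
  m
}

#' Sequence-simulation preset for the 15-taxon fixture
#'
#' JC substitution process scaled so a 0.2 coalescent-unit internal
#' branch of [fifteen_taxon_model()] is 0.005 substitutions per site,
#' i.e. `rate_scale = theta / 2 = 0.025` substitutions per coalescent
#' unit.
#'
#' @param theta population parameter (default 0.05).
#' @return a `gtr_params`.
#' @export
fifteen_taxon_seq_params <- function(theta = 0.05) gtr_params(rate_scale = theta / 2)

# Normalized GTR generator and its eigendecomposition (reversible).
gtr_eigen <- function(params) {
  r <- params$exchangeabilities
  pi_ <- params$base_freqs
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- r[1]; Q[1, 3] <- r[2]; Q[1, 4] <- r[3]
  Q[2, 3] <- r[4]; Q[2, 4] <- r[5]; Q[3, 4] <- r[6]
  Q <- Q + t(Q)
  Q <- Q * rep(pi_, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_ * diag(Q))
  Q <- Q / mu
  sp <- sqrt(pi_)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = ev$values,
       left = diag(1 / sp) %*% ev$vectors,
       right = t(ev$vectors) %*% diag(sp))
}

gtr_pmat <- function(eig, t) {
  P <- eig$left %*% (exp(eig$values * t) * eig$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Mean-one discrete Gamma category rates (equal-probability categories,
# category mean rates).
discrete_gamma_rates <- function(shape, k) {
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape, rate = shape)
  diff(stats::pgamma(b, shape + 1, rate = shape)) * k
}

#' Simulate sequences down a gene tree under GTR+Gamma
#'
#' Sites are i.i.d.; when a Gamma shape is configured each site draws a
#' mean-one discrete-Gamma rate multiplier. The root state is drawn
#' from the stationary frequencies and states evolve down each branch
#' with transition matrix `expm(Q * rate_scale * length * rate)`.
#'
#' @param gene_tree a rooted [support_tree] with branch lengths (in
#'   coalescent units; `rate_scale` converts to substitution units).
#' @param params a [gtr_params].
#' @param k number of sites (>= 1).
#' @param seed integer seed.
#' @return a [dna_alignment].
#' @export
simulate_sequences <- function(gene_tree, params, k, seed = 1L) {
  if (k < 1) stop_validation("k must be >= 1")
  if (!gene_tree$rooted) stop_validation("gene tree must be rooted")
  phy <- stats::reorder(gene_tree$phy, "postorder")
  ntip <- length(phy$tip.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  eig <- gtr_eigen(params)
  rates <- if (is.null(params$gamma_shape)) 1
           else discrete_gamma_rates(params$gamma_shape, params$n_categories)
  with_seed(seed, {
    cat_of <- if (length(rates) == 1) rep(1L, k) else sample.int(length(rates), k, replace = TRUE)
    states <- matrix(0L, ntip + phy$Nnode, k)
    states[root, ] <- sample.int(4, k, replace = TRUE, prob = params$base_freqs)
    for (e in rev(seq_len(nrow(phy$edge)))) {  # preorder
      par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      d <- phy$edge.length[e] * params$rate_scale
      for (c_ in seq_along(rates)) {
        idx <- which(cat_of == c_)
        if (!length(idx)) next
        if (d * rates[c_] <= 0) { states[child, idx] <- states[par, idx]; next }
        P <- gtr_pmat(eig, d * rates[c_])
        for (s in 1:4) {
          at <- idx[states[par, idx] == s]
          if (length(at)) states[child, at] <- sample.int(4, length(at), replace = TRUE, prob = P[s, ])
        }
      }
    }
    mat <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), , drop = FALSE]],
                  ntip, k, dimnames = list(phy$tip.label, NULL))
    dna_alignment(mat)
  })
}

#' Mean topological discordance between gene trees and the species tree
#'
#' The mean, over genes, of the normalized bipartition (missing-branch)
#' distance between each gene tree and the species tree, as a
#' percentage. Trees with fewer than four taxa have no unrooted
#' internal branches, so for those the rooted clade sets are compared
#' instead (for three taxa this is the rooted-triplet mismatch
#' probability, `(2/3) exp(-T)` under the coalescent).
#'
#' @param model a `species_tree_model`.
#' @param gene_trees list of [support_tree]s on the species taxa.
#' @return percent in `[0, 100]`.
#' @export
discordance <- function(model, gene_trees) {
  if (!length(gene_trees)) stop_validation("no gene trees")
  use_rooted <- n_tips(model$tree) < 4
  get_masks <- function(st) {
    if (use_rooted) rooted_clade_masks(st) else tree_splits(st)$mask
  }
  sp_masks <- get_masks(model$tree)
  nsp <- length(sp_masks)
  vals <- vapply(gene_trees, function(gt) {
    check_same_leaves(model$tree, gt)
    gm <- get_masks(gt)
    cnt <- sum(!(gm %in% sp_masks)) + sum(!(sp_masks %in% gm))
    denom <- length(gm) + nsp
    if (denom == 0) 0 else cnt / denom
  }, numeric(1))
  mean(vals) * 100
}
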