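test_that("greedy consensus: frequency ordering and supports", {
  t1 <- parse_newick("((a,b),(c,(d,e)));")
  expect_equal(rf_distance(greedy_consensus(list(t1, t1, t1)), t1)$count, 0)
  expect_true(all(tree_splits(greedy_consensus(list(t1, t1, t1)))$support == 100))

  t3 <- parse_newick("((a,c),(b,(d,e)));")
  gc <- greedy_consensus(list(t1, t1, t3))
  sp <- tree_splits(gc)
  leaves <- attr(sp, "leaves")
  side <- function(m) paste(leaves[bitwAnd(bitwShiftL(1L, seq_along(leaves) - 1L), m) != 0L],
                            collapse = "")
  got <- stats::setNames(sp$support, vapply(sp$mask, side, character(1)))
  expect_equal(unname(got[["de"]]), 100)
  expect_equal(unname(got[["cde"]]), 200 / 3, tolerance = 1e-9)  # ab|cde in 2 of 3

  # disjoint compatible split sets: union retained at 50 each
  u1 <- parse_newick("((a,b),c,d,e,f);")
  u2 <- parse_newick("(a,b,c,d,(e,f));")
  u1$supports[!is.na(u1$supports) | TRUE] <- 100
  gcu <- greedy_consensus(list(u1, u2))
  spu <- tree_splits(gcu)
  expect_equal(nrow(spu), 2)
  expect_true(all(spu$support == 50))

  # retained splits always mutually compatible (own-output sanity)
  set.seed(15)
  trees <- replicate(7, rand_support_tree(8), simplify = FALSE)
  spr <- tree_splits(greedy_consensus(trees))
  expect_true(statbin:::masks_pairwise_compatible(spr$mask, spr$mask, statbin:::full_mask(8)))
  expect_error(greedy_consensus(list()), class = "statbin_validation_error")
})

test_that("triplet_counts resolves triplets correctly", {
  t <- parse_newick("(((a,b),c),d);"); t$rooted <- TRUE
  tc <- triplet_counts(list(t))
  expect_equal(ncol(tc$trip), 4)
  expect_true(all(rowSums(tc$counts) == 1))
  # triplet abc -> ab|c (column 1); abd -> ab|d; acd -> ac|d; bcd -> bc|d
  expect_equal(unname(tc$counts[, 1]), c(1, 1, 1, 1))

  # p identical copies == single tree distribution scaled
  tc5 <- triplet_counts(rep(list(t), 5))
  expect_equal(tc5$counts, tc$counts * 5L)

  # the three rooted triplets on {a,b,c}: each resolution once
  r1 <- parse_newick("((a,b),c);"); r2 <- parse_newick("((a,c),b);"); r3 <- parse_newick("((b,c),a);")
  for (r in list(r1, r2, r3)) r$rooted <- TRUE
  r1$rooted <- r2$rooted <- r3$rooted <- TRUE
  sym <- triplet_counts(list(r1, r2, r3))
  expect_equal(unname(sym$counts[1, ]), c(1L, 1L, 1L))

  # polytomies count as unresolved
  poly <- parse_newick("((a,b,c),d);"); poly$rooted <- TRUE
  tp <- triplet_counts(list(poly))
  expect_equal(sum(tp$unresolved), 1)  # abc unresolved; abd/acd/bcd resolved
  un <- parse_newick("(a,b,c,d);"); un$rooted <- FALSE
  expect_error(triplet_counts(list(un)), class = "statbin_validation_error")
})

test_that("R* reconstructs the source tree from its own triplets (n <= 8 fuzz)", {
  set.seed(16)
  for (n in 4:8) {
    for (rep in 1:4) {
      phy <- ape::rtree(n, rooted = TRUE)
      phy$node.label <- NULL
      t <- support_tree(phy, supports = rep(NA_real_, phy$Nnode), rooted = TRUE)
      rs <- rstar_species_tree(triplet_counts(list(t)))
      expect_equal(rf_distance(rs, t)$count, 0)
      # rooted clades must match too
      expect_setequal(statbin:::rooted_clade_masks(rs), statbin:::rooted_clade_masks(t))
    }
  }
  # all triplets tied -> star
  r1 <- parse_newick("((a,b),c);"); r2 <- parse_newick("((a,c),b);"); r3 <- parse_newick("((b,c),a);")
  r1$rooted <- r2$rooted <- r3$rooted <- TRUE
  star <- rstar_species_tree(triplet_counts(list(r1, r2, r3)))
  expect_equal(nrow(tree_splits(star)), 0)
})

test_that("R* is consistent on MSC gene trees (seeded)", {
  m5 <- make_caterpillar_species_tree(5, 0.5)
  gts <- simulate_gene_trees(m5, 2000, seed = 17)
  rs <- rstar_species_tree(triplet_counts(gts))
  expect_equal(rf_distance(rs, m5$tree)$count, 0)
})

test_that("assemble_replicates shapes match the weighted and unweighted pipelines", {
  set.seed(18)
  tops <- distinct_topologies(4, 6, support = 100)
  trees <- c(rep(tops[1], 2), rep(tops[2], 3), rep(tops[3], 3), rep(tops[4], 4))
  bb <- balanced_color(build_incompatibility_graph(trees, 75))
  per_bin_boot <- lapply(seq_along(bb$bins), function(b) rep(tops[b], 5))  # b = 5 replicates
  w <- assemble_replicates(per_bin_boot, weighting = bb)
  expect_equal(w$b, 5L)
  expect_true(all(lengths(w$replicates) == 12))   # weighted: one per gene
  u <- assemble_replicates(per_bin_boot)
  expect_true(all(lengths(u$replicates) == 4))    # unweighted: one per bin
  pg <- lapply(1:7, function(i) rep(tops[1], 3))
  expect_true(all(lengths(assemble_replicates(pg)$replicates) == 7))
  ragged <- list(rep(tops[1], 3), rep(tops[1], 2))
  expect_error(assemble_replicates(ragged), class = "statbin_validation_error")
})

test_that("mlbs consensus over replicates", {
  t1 <- parse_newick("((a,b),(c,(d,e)));")
  reps1 <- structure(list(replicates = list(list(t1, t1)), b = 1L), class = "replicate_set")
  out1 <- mlbs(reps1, greedy_consensus)
  expect_equal(rf_distance(out1, t1)$count, 0)
  expect_true(all(tree_splits(out1)$support == 100))

  reps3 <- structure(list(replicates = rep(list(list(t1, t1)), 3), b = 3L),
                     class = "replicate_set")
  out3 <- mlbs(reps3, greedy_consensus)
  expect_true(all(tree_splits(out3)$support == 100))
})

test_that("end-to-end MLBS on seeded 6-taxon simulation recovers the truth", {
  m <- make_caterpillar_species_tree(6, 0.5)
  tr <- m$tree
  boots <- lapply(1:30, function(i) {
    gt <- simulate_gene_trees(m, 1, seed = 100 + i)[[1]]
    aln <- simulate_sequences(gt, gtr_params(rate_scale = 0.2), 2000, seed = 200 + i)
    bootstrap_gene_tree(aln, 10, seed = 300 + i)$replicate_trees
  })
  reps <- assemble_replicates(boots)
  summary <- function(ts) {
    rooted <- lapply(ts, root_at_outgroup, outgroup = "t06")
    rstar_species_tree(triplet_counts(rooted))
  }
  cons <- mlbs(reps, summary)
  expect_equal(rf_distance(cons, tr)$count, 0)
  expect_true(all(tree_splits(cons)$support >= 90))
})
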