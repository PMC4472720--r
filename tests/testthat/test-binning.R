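test_that("are_compatible: worked examples and threshold semantics", {
  x100 <- parse_newick("((a,b)100,(c,d)100);")
  y100 <- parse_newick("((a,c)100,(b,d)100);")
  expect_false(are_compatible(x100, y100, 75))
  x60 <- parse_newick("((a,b)60,(c,d)60);")
  y60 <- parse_newick("((a,c)60,(b,d)60);")
  expect_true(are_compatible(x60, y60, 75))      # both collapse to stars
  expect_true(are_compatible(x100, x60, 75))     # identical topologies
  # conflict needs support >= B in BOTH trees
  expect_true(are_compatible(x100, parse_newick("((a,c)74,(b,d)74);"), 75))
  expect_false(are_compatible(x100, parse_newick("((a,c)75,(b,d)75);"), 75))
  expect_error(are_compatible(x100, parse_newick("((a,b)100,(c,e)100);"), 75),
               class = "statbin_validation_error")
})

test_that("are_compatible agrees with the exhaustive refinement oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    # share a leaf set: relabel both trees onto sorted labels
    t1 <- rand_support_tree(n)
    t2 <- rand_support_tree(n)
    B <- sample(c(30, 60, 90), 1)
    expect_equal(are_compatible(t1, t2, B), oracle_compatible(t1, t2, B),
                 info = sprintf("rep %d n %d B %d", rep, n, B))
  }
})

test_that("incompatibility graph has the defined edge structure", {
  set.seed(5)
  t <- rand_support_tree(8, support = 100)
  g <- build_incompatibility_graph(rep(list(t), 6), 50)
  expect_equal(sum(g$adj), 0)
  low <- replicate(5, rand_support_tree(8, support = 30), simplify = FALSE)
  expect_equal(sum(build_incompatibility_graph(low, 50)$adj), 0)  # all stars

  tops <- distinct_topologies(2, 6, support = 100)
  g4 <- build_incompatibility_graph(list(tops[[1]], tops[[1]], tops[[2]], tops[[2]]), 75)
  expect_equal(g4$adj, matrix(c(F,F,T,T, F,F,T,T, T,T,F,F, T,T,F,F), 4, 4))  # K2,2
})

test_that("seed_clique is greedy, deterministic and returns a clique", {
  set.seed(5)
  tops <- distinct_topologies(2, 6, support = 100)
  g <- build_incompatibility_graph(list(tops[[1]], tops[[1]], tops[[2]], tops[[2]]), 75)
  expect_equal(seed_clique(g), c(1L, 3L))
  edgeless <- build_incompatibility_graph(rep(list(tops[[1]]), 4), 75)
  expect_equal(seed_clique(edgeless), 1L)
  k5 <- distinct_topologies(5, 7, support = 100)
  gk5 <- build_incompatibility_graph(k5, 50)
  expect_equal(seed_clique(gk5), 1:5)
  cl <- seed_clique(gk5)
  expect_true(all(gk5$adj[t(utils::combn(cl, 2))]))
})

test_that("balanced_color: proper coloring, balance, determinism", {
  set.seed(6)
  tops <- distinct_topologies(4, 8, support = 100)
  edgeless <- build_incompatibility_graph(rep(list(tops[[1]]), 12), 50)
  b1 <- balanced_color(edgeless)
  expect_equal(lengths(b1$bins), 12L)
  k4 <- build_incompatibility_graph(tops, 50)
  expect_equal(lengths(balanced_color(k4)$bins), rep(1L, 4))

  # proper coloring on random graphs + determinism under a fixed seed
  for (rep in 1:5) {
    trees <- sample(tops, 20, replace = TRUE)
    g <- build_incompatibility_graph(trees, 50)
    bb <- balanced_color(g, seed = 7)
    expect_equal(sort(unlist(bb$bins)), 1:20)  # partition
    for (bin in bb$bins) {
      if (length(bin) > 1) expect_false(any(g$adj[t(utils::combn(bin, 2))]))
    }
    expect_identical(bb, balanced_color(g, seed = 7))
  }
})

test_that("Lemma 1 mechanism: fully supported trees bin by topology", {
  set.seed(41)
  for (rep in 1:15) {
    n <- sample(6:15, 1)
    K <- sample(2:8, 1)
    tops <- distinct_topologies(K, n, support = 100)
    mult <- sample(1:8, K, replace = TRUE)
    trees <- list(); class_of <- integer(0)
    for (k in seq_len(K)) {
      trees <- c(trees, rep(tops[k], mult[k]))
      class_of <- c(class_of, rep(k, mult[k]))
    }
    ord <- sample(seq_along(trees))
    trees <- trees[ord]; class_of <- class_of[ord]
    bb <- balanced_color(build_incompatibility_graph(trees, 75), seed = rep)
    got <- lapply(bb$bins, sort)
    want <- unname(lapply(split(seq_along(trees), class_of), sort))
    expect_setequal(lapply(got, paste, collapse = ","), lapply(want, paste, collapse = ","))
  }
})

test_that("weighted and unweighted outputs have the stated shapes", {
  set.seed(8)
  tops <- distinct_topologies(4, 6, support = 100)
  trees <- c(rep(tops[1], 2), rep(tops[2], 3), rep(tops[3], 3), rep(tops[4], 4))
  bb <- balanced_color(build_incompatibility_graph(trees, 75))
  expect_equal(sort(lengths(bb$bins)), c(2L, 3L, 3L, 4L))
  sg <- lapply(bb$bins, function(b) trees[[b[1]]])
  w <- weight_bins(bb, sg)
  u <- unweighted_output(bb, sg)
  expect_length(w, 12)                       # weighted: one tree per gene
  expect_length(u, 4)                        # unweighted: one per bin
  expect_true(same_topology_multiset(w, trees))
  # all-singleton bins: weighting is the identity
  k4 <- balanced_color(build_incompatibility_graph(tops, 50))
  expect_identical(weight_bins(k4, lapply(k4$bins, function(b) tops[[b[1]]])),
                   unweighted_output(k4, lapply(k4$bins, function(b) tops[[b[1]]])))
  expect_error(weight_bins(bb, sg[1:3]), class = "statbin_validation_error")
})

test_that("bin table and DOT outputs are well formed", {
  set.seed(2)
  tops <- distinct_topologies(2, 5, support = 100)
  bb <- balanced_color(build_incompatibility_graph(c(tops, tops), 50))
  f <- tempfile(fileext = ".tsv")
  write_bin_table(bb, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$gene_id, paste0("g", 1:4))
  d <- tempfile(fileext = ".dot")
  write_dot(build_incompatibility_graph(c(tops, tops), 50), d)
  expect_true(any(grepl("--", readLines(d))))
})
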