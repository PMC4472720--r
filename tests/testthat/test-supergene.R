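test_that("concatenate_bin appends ranges and gap-fills missing taxa", {
  a1 <- dna_alignment(c(a = strrep("AC", 50), b = strrep("AC", 50), c = strrep("AC", 50)))
  a2 <- dna_alignment(c(a = strrep("GT", 100), b = strrep("GT", 100)))
  sa <- concatenate_bin(list(g1 = a1, g2 = a2), c("g1", "g2"))
  expect_equal(aln_length <- ncol(sa$alignment$mat), 300)
  expect_equal(sa$partitions$start, c(1L, 101L))
  expect_equal(sa$partitions$end, c(100L, 300L))
  # taxon c present only in gene 1: gaps across gene 2's range
  expect_true(all(sa$alignment$mat["c", 101:300] == "-"))
  expect_equal(paste(sa$alignment$mat["c", 1:100], collapse = ""), strrep("AC", 50))

  one <- concatenate_bin(list(g1 = a1), "g1")
  expect_equal(one$alignment$mat, a1$mat[order(rownames(a1$mat)), , drop = FALSE])
  expect_equal(one$partitions$end, 100L)
  expect_error(concatenate_bin(list(g1 = a1), character(0)), class = "statbin_validation_error")
  expect_error(concatenate_bin(list(g1 = a1), c("g1", "g1")), class = "statbin_validation_error")
})

test_that("partition file dialect and round-trip", {
  a1 <- dna_alignment(c(a = strrep("A", 100), b = strrep("A", 100)))
  a2 <- dna_alignment(c(a = strrep("C", 200), b = strrep("C", 200)))
  sa <- concatenate_bin(list(g1 = a1, g2 = a2), c("g1", "g2"))
  txt <- write_partition_file(sa)
  expect_equal(txt, c("DNA, g1 = 1-100", "DNA, g2 = 101-300"))
  expect_equal(parse_partition_file(txt), sa$partitions, ignore_attr = TRUE)
  expect_error(parse_partition_file("PROT, x = 1-2"), class = "statbin_io_error")
})

sim_jc_alignment <- function(tree_newick, k, seed) {
  tr <- parse_newick(tree_newick); tr$rooted <- TRUE
  simulate_sequences(tr, gtr_params(), k, seed = seed)
}

test_that("fully partitioned ML: reduction to single-alignment ML and Eq-1 decomposition", {
  aln <- sim_jc_alignment("(((a:0.3,b:0.3):0.2,c:0.5):0.2,(d:0.3,e:0.3):0.4);", 250, seed = 13)
  single <- fully_partitioned_ml_exhaustive(aln)
  truth <- parse_newick("(((a,b),c),(d,e));")
  expect_equal(rf_distance(single$topology, truth)$count, 0)

  a2 <- sim_jc_alignment("(((a:0.3,b:0.3):0.2,c:0.5):0.2,(d:0.3,e:0.3):0.4);", 200, seed = 14)
  sa <- concatenate_bin(list(g1 = aln, g2 = a2), c("g1", "g2"))
  multi <- fully_partitioned_ml_exhaustive(sa)
  # decomposition: total = sum of per-partition optimized log-likelihoods
  expect_equal(multi$log_likelihood, sum(multi$per_partition_loglik), tolerance = 1e-9)
  # per-partition branch lengths are free to differ across partitions
  expect_length(multi$per_partition_branch_lengths, 2)
  expect_equal(names(multi$per_partition_branch_lengths), c("g1", "g2"))

  expect_error(fully_partitioned_ml_exhaustive(
    concatenate_bin(list(g1 = constant_alignment(letters[1:9], 10)), "g1")),
    class = "statbin_validation_error")
})

test_that("constant partitions never change the fully partitioned argmax", {
  aln <- sim_jc_alignment("((a:0.4,b:0.4):0.3,(c:0.4,(d:0.3,e:0.3):0.2):0.2);", 250, seed = 17)
  base <- fully_partitioned_ml_exhaustive(aln)
  sa <- concatenate_bin(list(g1 = aln,
                             c1 = constant_alignment(letters[1:5], 60),
                             c2 = constant_alignment(letters[1:5], 40, base = "G")),
                        c("g1", "c1", "c2"))
  with_const <- fully_partitioned_ml_exhaustive(sa)
  expect_equal(rf_distance(base$topology, with_const$topology)$count, 0)
  # constant partitions score identically on every topology
  expect_equal(with_const$per_partition_loglik[["g1"]], base$log_likelihood, tolerance = 1e-4)
})

test_that("unpartitioned ML shares one branch-length set and shrinks under dilution", {
  aln <- sim_jc_alignment("((a:0.5,b:0.5):0.3,(c:0.5,(d:0.4,e:0.4):0.3):0.2);", 300, seed = 19)
  solo <- unpartitioned_ml_exhaustive(aln)
  part <- fully_partitioned_ml_exhaustive(aln)
  expect_equal(rf_distance(solo$topology, part$topology)$count, 0)
  # duplicating the alignment leaves the topology unchanged
  dup <- concatenate_bin(list(g1 = aln, g2 = aln), c("g1", "g2"))
  expect_equal(rf_distance(unpartitioned_ml_exhaustive(dup)$topology, solo$topology)$count, 0)
  # adding constant sites drives shared branch lengths down
  mix <- concatenate_bin(list(g1 = aln, c1 = constant_alignment(letters[1:5], 300)),
                         c("g1", "c1"))
  mixed <- unpartitioned_ml_exhaustive(mix)
  expect_lt(sum(mixed$per_partition_branch_lengths$all),
            sum(solo$per_partition_branch_lengths$all))
})

test_that("Lemma 2 mechanism holds on seeded random instances", {
  set.seed(23)
  done <- 0; tries <- 0
  while (done < 6 && tries < 20) {
    tries <- tries + 1
    tr <- rand_support_tree(5, support = 100)
    tr$phy$edge.length <- stats::runif(nrow(tr$phy$edge), 0.15, 0.5)
    nwk <- write_newick(tr)
    alns <- lapply(1:3, function(i) sim_jc_alignment(nwk, 150, seed = tries * 10 + i))
    names(alns) <- paste0("g", 1:3)
    singles <- lapply(alns, fully_partitioned_ml_exhaustive)
    keys <- vapply(singles, function(s) topology_key(s$topology), character(1))
    if (length(unique(keys)) != 1) next   # Lemma 2 premise not met
    done <- done + 1
    sa <- concatenate_bin(alns, names(alns))
    full <- fully_partitioned_ml_exhaustive(sa)
    expect_equal(topology_key(full$topology), keys[[1]])
  }
  expect_gte(done, 3)
})

test_that("RAxML adapter renders the partitioned command without executing", {
  a1 <- dna_alignment(c(a = "ACGTACGT", b = "ACGAACGT", c = "AGGTACGT", d = "ACGTTCGT"))
  a2 <- dna_alignment(c(a = "AAAA", b = "AAAT", c = "AATA", d = "ATAA"))
  sa <- concatenate_bin(list(g1 = a1, g2 = a2), c("g1", "g2"))
  res <- external_raxml_adapter(sa, list(dry_run = TRUE, workdir = tempfile()))
  expect_true(grepl(" -M ", res$command))
  expect_true(grepl("-q ", res$command))
  expect_true(file.exists(res$files[["alignment"]]))
  expect_equal(length(readLines(res$files[["partitions"]])), 2)
  # parsing a RAxML-style result: n - 3 internal edges
  t <- parse_newick("((a:1,b:1)95:1,((c:1,d:1)88:1,e:1)72:1,f:1);")
  expect_equal(nrow(tree_splits(t)), 3)
})
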