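# Supergene assembly: per-bin concatenated alignments with partition
# maps, RAxML-dialect partition files, and an external-tool adapter.

#' Concatenate the alignments of a bin into a supergene alignment
#'
#' Columns are appended in the bin's gene order. Taxa absent from a gene
#' are filled with gaps across that gene's column range. The partition
#' map records each gene's 1-based inclusive column range.
#'
#' @param alignments named list of [dna_alignment] keyed by gene id.
#' @param bin character vector of gene ids (non-empty, no duplicates).
#' @return a `supergene_alignment`: list with `alignment`
#'   ([dna_alignment]) and `partitions` (data.frame gene/start/end).
#' @export
concatenate_bin <- function(alignments, bin) {
  if (length(bin) < 1) stop_validation("empty bin")
  if (anyDuplicated(bin)) stop_validation("duplicate gene in bin")
  missing <- setdiff(bin, names(alignments))
  if (length(missing)) stop_validation("no alignment for gene(s): %s", paste(missing, collapse = ", "))
  taxa <- sort(unique(unlist(lapply(alignments[bin], aln_taxa))))
  lens <- vapply(alignments[bin], aln_length, integer(1))
  end <- cumsum(lens)
  start <- end - lens + 1L
  mat <- matrix("-", length(taxa), sum(lens), dimnames = list(taxa, NULL))
  for (i in seq_along(bin)) {
    a <- alignments[[bin[i]]]
    mat[aln_taxa(a), start[i]:end[i]] <- a$mat
  }
  structure(list(alignment = dna_alignment(mat),
                 partitions = data.frame(gene = bin, start = start, end = end,
                                         row.names = NULL)),
            class = "supergene_alignment")
}

#' @export
print.supergene_alignment <- function(x, ...) {
  cat(sprintf("supergene_alignment: %d taxa, %d sites, %d partitions\n",
              nrow(x$alignment$mat), ncol(x$alignment$mat), nrow(x$partitions)))
  invisible(x)
}

#' Write / parse a RAxML-style partition file
#'
#' One line per partition in the dialect `DNA, <gene> = <start>-<end>`
#' with 1-based inclusive ranges.
#'
#' @param sa a `supergene_alignment`.
#' @param file optional path; when `NULL` the text is returned.
#' @return the partition-file text (one element per line).
#' @export
write_partition_file <- function(sa, file = NULL) {
  txt <- sprintf("DNA, %s = %d-%d", sa$partitions$gene, sa$partitions$start, sa$partitions$end)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' @rdname write_partition_file
#' @param text character vector of partition-file lines.
#' @return for `parse_partition_file`, a data.frame gene/start/end.
#' @export
parse_partition_file <- function(text) {
  m <- regmatches(text, regexec("^\\s*DNA,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)\\s*$", text))
  bad <- lengths(m) != 4
  if (any(bad)) stop_io("bad partition line: %s", text[bad][1])
  data.frame(gene = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             end = as.integer(vapply(m, `[`, character(1), 4)))
}

## ---- exhaustive JC maximum likelihood -------------------------------
## The in-house solver is intentionally restricted to Jukes-Cantor and
## exhaustive topology enumeration (n <= 8): it exists to realize the
## fully partitioned likelihood score exactly on desk-scale instances,
## not to compete with RAxML.

# All unrooted binary topologies on leaves 1..n as (2n-3) x 2 edge
# matrices; internal node ids start at n+1.
enumerate_topologies <- function(n) {
  if (n < 3) stop_validation("need at least 3 taxa")
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2, byrow = TRUE)
  trees <- list(list(edges = base, next_id = n + 2L))
  if (n > 3) {
    for (t in 4:n) {
      trees <- unlist(lapply(trees, function(tr) {
        lapply(seq_len(nrow(tr$edges)), function(e) {
          u <- tr$edges[e, 1]; v <- tr$edges[e, 2]; w <- tr$next_id
          list(edges = rbind(tr$edges[-e, , drop = FALSE],
                             c(u, w), c(w, v), c(w, t)),
               next_id = w + 1L)
        })
      }), recursive = FALSE)
    }
  }
  lapply(trees, `[[`, "edges")
}

# Orient an edge matrix away from the root (node n+1): postorder node
# sequence, per-node children with connecting edge indices, and a
# (parent, child) edge array ordered so each child's subtree edges come
# first (the order the C pruning kernel consumes).
orient_topology <- function(edges, n) {
  m <- max(edges)
  adj <- vector("list", m)
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, k))
    adj[[v]] <- rbind(adj[[v]], c(u, k))
  }
  root <- n + 1L
  po <- integer(0)
  kids <- vector("list", m)
  stack <- list(c(root, 0L))
  visited <- logical(m)
  order_stack <- integer(0)
  while (length(stack)) {
    cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- cur[1]
    visited[v] <- TRUE
    order_stack <- c(order_stack, v)
    for (r in seq_len(nrow(adj[[v]]))) {
      w <- adj[[v]][r, 1]; e <- adj[[v]][r, 2]
      if (!visited[w]) {
        kids[[v]] <- rbind(kids[[v]], c(w, e))
        stack[[length(stack) + 1L]] <- c(w, e)
      }
    }
  }
  po <- rev(order_stack)
  pos <- integer(m); pos[po] <- seq_along(po)
  rows <- do.call(rbind, lapply(seq_len(m), function(v) {
    if (is.null(kids[[v]])) return(NULL)
    cbind(v, kids[[v]])
  }))  # columns: parent, child, edge index
  ord <- order(pos[rows[, 2]])
  cedges <- rows[ord, 1:2, drop = FALSE]
  storage.mode(cedges) <- "integer"
  list(po = po, kids = kids, root = as.integer(root), n = n,
       n_edges = nrow(edges), n_nodes = as.integer(m),
       cedges = cedges, cedge_map = rows[ord, 3])
}

# Site-pattern compression: integer matrix taxa x sites (1..4, 0 = gap/N)
# -> list(upat = taxa x npat state codes, wts = pattern counts).
compress_patterns <- function(mat) {
  code <- matrix(match(mat, c("A", "C", "G", "T")), nrow(mat))
  code[is.na(code)] <- 0L
  key <- apply(code, 2, paste, collapse = ",")
  wts <- as.vector(table(factor(key, levels = unique(key))))
  upat <- code[, match(unique(key), key), drop = FALSE]
  storage.mode(upat) <- "integer"
  list(upat = upat, wts = wts)
}

# Per-pattern JC69 site likelihoods of an oriented topology with branch
# lengths `bl` (indexed by edge), given precomputed exp factors
# e = exp(-4 bl / 3) when supplied. Delegates to the C pruning kernel.
jc_sitelik <- function(struct, bl, pat, efac = exp(-4 * bl / 3)) {
  .Call(C_jc_sitelik, pat$upat,
        struct$cedges, as.double(efac[struct$cedge_map]),
        struct$n_nodes, struct$root)
}

jc_loglik <- function(struct, bl, pat) sum(pat$wts * log(jc_sitelik(struct, bl, pat)))

# Coordinate-ascent branch-length optimization with per-branch Brent
# search on [1e-8, 10] (deterministic 0.1 initialization). For JC the
# site likelihood is linear in e = exp(-4 d / 3) of any single branch,
# so each 1-D problem needs only two prunings (e = 0 and e = 1) and a
# scalar Brent search over e. Sweeps continue until two consecutive
# full sweeps each improve the log-likelihood by less than `tol`.
optimize_bl_jc <- function(struct, pat, tol = 1e-6, init = 0.1) {
  bl <- rep(init, struct$n_edges)
  efac <- exp(-4 * bl / 3)
  e_lo <- exp(-4 * 10 / 3); e_hi <- exp(-4 * 1e-8 / 3)
  ll <- sum(pat$wts * log(jc_sitelik(struct, bl, pat, efac)))
  quiet <- 0L
  for (sweep in seq_len(40L)) {
    old_ll <- ll
    for (e in seq_len(struct$n_edges)) {
      ef <- efac
      ef[e] <- 0
      a <- jc_sitelik(struct, bl, pat, ef)       # site lik at e = 0
      ef[e] <- 1
      b <- jc_sitelik(struct, bl, pat, ef) - a   # linear coefficient
      opt <- stats::optimize(function(x) sum(pat$wts * log(a + b * x)),
                             interval = c(e_lo, e_hi), maximum = TRUE,
                             tol = .Machine$double.eps^0.4)
      if (opt$objective > ll) { efac[e] <- opt$maximum; ll <- opt$objective }
    }
    quiet <- if (ll - old_ll < tol) quiet + 1L else 0L
    if (quiet >= 2L && sweep >= 2L) break
  }
  list(bl = -3 / 4 * log(efac), loglik = ll)
}

# Log-likelihood table: one row per enumerated topology, one column per
# partition (pattern set); shared by the exhaustive solvers.
ml_loglik_table <- function(pats, topos, n, tol = 1e-6) {
  res <- vapply(topos, function(edges) {
    struct <- orient_topology(edges, n)
    vapply(pats, function(pat) optimize_bl_jc(struct, pat, tol = tol)$loglik, numeric(1))
  }, numeric(length(pats)))
  if (is.null(dim(res))) matrix(res, ncol = 1) else t(res)
}

# Human-readable edge labels for an oriented topology: the sorted taxa
# below each edge's child node.
edge_labels <- function(edges, n, taxa) {
  struct <- orient_topology(edges, n)
  below <- vector("list", length(struct$kids))
  for (v in struct$po) {
    if (v <= n) { below[[v]] <- taxa[v]; next }
    below[[v]] <- sort(unlist(lapply(struct$kids[[v]][, 1], function(w) below[[w]])))
  }
  labs <- character(struct$n_edges)
  for (v in struct$po) {
    kk <- struct$kids[[v]]
    if (is.null(kk)) next
    for (r in seq_len(nrow(kk))) labs[kk[r, 2]] <- paste(below[[kk[r, 1]]], collapse = "|")
  }
  labs
}

topology_to_support_tree <- function(edges, n, taxa) {
  struct <- orient_topology(edges, n)
  emit <- function(v) {
    if (v <= n) return(taxa[v])
    sprintf("(%s)", paste(vapply(struct$kids[[v]][, 1], emit, character(1)), collapse = ","))
  }
  st <- parse_newick(paste0(emit(struct$root), ";"))
  st$rooted <- FALSE
  st
}

#' Exhaustive fully partitioned maximum likelihood (JC69)
#'
#' Enumerates every unrooted binary topology (at most 8 taxa), optimizes
#' branch lengths independently for each partition by per-branch Brent
#' search, and returns the topology maximizing the summed per-partition
#' log-likelihood. Realizes the fully partitioned score
#' `score(t) = sup_Theta prod_i Pr(S_i | t, theta_i)` exactly, up to the
#' numerical tolerance of the branch-length optimizer. Columns that are
#' entirely gap/N contribute likelihood 1.
#'
#' @param sa a `supergene_alignment` (or a [dna_alignment], treated as a
#'   single partition).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return a `partitioned_ml_result`: list with `topology` (unrooted
#'   [support_tree], no supports), `per_partition_branch_lengths`
#'   (list per gene of named branch-length vectors), `log_likelihood`,
#'   and `per_partition_loglik`.
#' @export
fully_partitioned_ml_exhaustive <- function(sa, tol = 1e-6) {
  if (inherits(sa, "dna_alignment")) {
    sa <- structure(list(alignment = sa,
                         partitions = data.frame(gene = "g1", start = 1L,
                                                 end = aln_length(sa))),
                    class = "supergene_alignment")
  }
  mat <- sa$alignment$mat
  taxa <- sort(rownames(mat))
  mat <- mat[taxa, , drop = FALSE]
  n <- length(taxa)
  if (n > 8) {
    stop_validation("exhaustive ML is limited to 8 taxa (got %d); use the external RAxML adapter", n)
  }
  if (n < 4) stop_validation("need at least 4 taxa")
  pats <- lapply(seq_len(nrow(sa$partitions)), function(i) {
    compress_patterns(mat[, sa$partitions$start[i]:sa$partitions$end[i], drop = FALSE])
  })
  topos <- enumerate_topologies(n)
  tab <- ml_loglik_table(pats, topos, n, tol = tol)
  total <- rowSums(tab)
  ti <- which.max(total)  # first topology in enumeration order on ties
  edges <- topos[[ti]]
  struct <- orient_topology(edges, n)
  fits <- lapply(pats, function(pat) optimize_bl_jc(struct, pat, tol = tol))
  labs <- edge_labels(edges, n, taxa)
  per_part <- lapply(fits, function(f) stats::setNames(f$bl, labs))
  names(per_part) <- sa$partitions$gene
  structure(list(topology = topology_to_support_tree(edges, n, taxa),
                 per_partition_branch_lengths = per_part,
                 per_partition_loglik = stats::setNames(tab[ti, ], sa$partitions$gene),
                 log_likelihood = total[ti]),
            class = "partitioned_ml_result")
}

#' Exhaustive unpartitioned maximum likelihood (JC69)
#'
#' As [fully_partitioned_ml_exhaustive()], but with a single set of
#' branch lengths shared by every column of the alignment.
#'
#' @param alignment a [dna_alignment] or `supergene_alignment`.
#' @param tol log-likelihood convergence tolerance.
#' @return a `partitioned_ml_result` with one branch-length set.
#' @export
unpartitioned_ml_exhaustive <- function(alignment, tol = 1e-6) {
  if (inherits(alignment, "supergene_alignment")) alignment <- alignment$alignment
  mat <- alignment$mat
  taxa <- sort(rownames(mat))
  mat <- mat[taxa, , drop = FALSE]
  n <- length(taxa)
  if (n > 8) stop_validation("exhaustive ML is limited to 8 taxa (got %d)", n)
  if (n < 4) stop_validation("need at least 4 taxa")
  pat <- compress_patterns(mat)
  topos <- enumerate_topologies(n)
  tab <- ml_loglik_table(list(pat), topos, n, tol = tol)
  ti <- which.max(tab[, 1])
  edges <- topos[[ti]]
  struct <- orient_topology(edges, n)
  fit <- optimize_bl_jc(struct, pat, tol = tol)
  labs <- edge_labels(edges, n, taxa)
  structure(list(topology = topology_to_support_tree(edges, n, taxa),
                 per_partition_branch_lengths = list(all = stats::setNames(fit$bl, labs)),
                 per_partition_loglik = c(all = fit$loglik),
                 log_likelihood = fit$loglik),
            class = "partitioned_ml_result")
}

#' @export
print.partitioned_ml_result <- function(x, ...) {
  cat(sprintf("partitioned_ml_result: %d partitions, logL = %.4f\n",
              length(x$per_partition_branch_lengths), x$log_likelihood))
  cat(" ", write_newick(x$topology), "\n")
  invisible(x)
}

#' Adapter for fully partitioned RAxML supergene-tree estimation
#'
#' Writes the supergene alignment (relaxed PHYLIP) and partition file,
#' renders the configured command template, and -- unless `dry_run` --
#' executes it and parses the resulting Newick. The test suite only
#' exercises the dry-run path; the adapter is never required.
#'
#' @param sa a `supergene_alignment`.
#' @param config list with `template` (command string with
#'   `[input_alignment]`, `[partition_file]`, `[output_name]`
#'   placeholders), `workdir`, optional `dry_run`, `result_file`.
#' @return dry run: list with `files` and `command`; otherwise the
#'   parsed [support_tree].
#' @export
external_raxml_adapter <- function(sa, config) {
  workdir <- config$workdir %||% tempfile("raxml")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  aln_file <- file.path(workdir, "supergene.phylip")
  part_file <- file.path(workdir, "supergene.part")
  write_phylip(sa$alignment, aln_file)
  write_partition_file(sa, part_file)
  template <- config$template %||%
    "raxmlHPC-SSE3 -m GTRGAMMA -s [input_alignment] -n [output_name] -N 20 -M -q [partition_file] -p [seed]"
  cmd <- template
  for (sub in list(c("[input_alignment]", aln_file),
                   c("[partition_file]", part_file),
                   c("[output_name]", config$output_name %||% "supergene"),
                   c("[seed]", as.character(config$seed %||% 12345)))) {
    cmd <- gsub(sub[1], sub[2], cmd, fixed = TRUE)
  }
  if (isTRUE(config$dry_run)) {
    return(list(files = c(alignment = aln_file, partitions = part_file), command = cmd))
  }
  exe <- strsplit(cmd, "\\s+")[[1]][1]
  if (Sys.which(exe) == "") stop_io("external binary not found on PATH: %s", exe)
  res <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0) stop_io("external command failed (exit %d): %s", status, paste(res, collapse = "\n"))
  result_file <- config$result_file %||%
    file.path(workdir, sprintf("RAxML_bestTree.%s", config$output_name %||% "supergene"))
  if (!file.exists(result_file)) stop_io("expected result file missing: %s", result_file)
  parse_newick(readLines(result_file)[1])
}
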