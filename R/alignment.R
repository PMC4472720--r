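#' DNA multiple sequence alignments
#'
#' A thin matrix-backed container: one row per taxon, one single-character
#' column per site, alphabet `A C G T - N` (lower case accepted on input).
#'
#' @param seqs either a named character vector of equal-length strings or
#'   a character matrix with taxon rownames.
#' @return an object of class `dna_alignment`.
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop_validation("sequences must be named by taxon")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      stop_validation("sequences have unequal lengths (%s)",
                      paste(unique(lens), collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(unname(as.character(seqs)), ""))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) stop_validation("alignment rows must be named")
  if (anyDuplicated(rownames(mat))) stop_validation("duplicate taxon in alignment")
  if (ncol(mat) < 1) stop_validation("alignment must have at least one column")
  mat[] <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stop_validation("illegal alignment character(s): %s", paste(bad, collapse = " "))
  structure(list(mat = mat), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d taxa x %d sites\n", nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

aln_taxa <- function(aln) rownames(aln$mat)
aln_length <- function(aln) ncol(aln$mat)
aln_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1, paste, collapse = ""), rownames(aln$mat))
}

#' Read and write FASTA / relaxed PHYLIP alignments
#'
#' Relaxed PHYLIP: a `ntax nchar` header line, then one
#' whitespace-separated `name sequence` record per line.
#'
#' @param file path.
#' @return a [dna_alignment].
#' @export
read_fasta <- function(file) {
  if (!file.exists(file)) stop_io("no such file: %s", file)
  lines <- readLines(file)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_io("not a FASTA file: %s", file)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(seq_along(names_), function(i) {
    paste(lines[idx == i & !hdr], collapse = "")
  }, character(1))
  dna_alignment(stats::setNames(gsub("\\s", "", seqs), names_))
}

#' @rdname read_fasta
#' @param aln a [dna_alignment].
#' @export
write_fasta <- function(aln, file) {
  s <- aln_strings(aln)
  writeLines(as.vector(rbind(paste0(">", names(s)), s)), file)
  invisible(file)
}

#' @rdname read_fasta
#' @export
read_phylip <- function(file) {
  if (!file.exists(file)) stop_io("no such file: %s", file)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) stop_io("bad PHYLIP header in %s", file)
  recs <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(recs) != hdr[1]) stop_io("expected %d sequences, found %d", hdr[1], length(recs))
  seqs <- stats::setNames(vapply(recs, function(r) paste(r[-1], collapse = ""), character(1)),
                          vapply(recs, `[`, character(1), 1))
  if (any(nchar(seqs) != hdr[2])) stop_io("sequence length disagrees with header")
  dna_alignment(seqs)
}

#' @rdname read_fasta
#' @export
write_phylip <- function(aln, file) {
  s <- aln_strings(aln)
  writeLines(c(sprintf("%d %d", length(s), aln_length(aln)),
               sprintf("%s  %s", names(s), s)), file)
  invisible(file)
}
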