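# shared fixture builders: everything is generated in code at test time

alnFromStrings <- function(..., outgroup = NULL, offset = 1L) {
  seqs <- c(...)
  ids <- paste0("h", seq_along(seqs))
  if (!is.null(outgroup)) {
    seqs <- c(seqs, outgroup)
    ids <- c(ids, "og")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  haplotypeAlignment(mat, ids,
                     outgroupId = if (is.null(outgroup)) NA_character_
                                  else "og",
                     regionOffset = offset)
}

randomAlignment <- function(n, L, seed, outgroup = FALSE) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), (n + outgroup) * L,
                       replace = TRUE), nrow = n + outgroup)
  ids <- c(paste0("h", seq_len(n)), if (outgroup) "og")
  haplotypeAlignment(mat, ids,
                     outgroupId = if (outgroup) "og" else NA_character_)
}

emptyAnnotation <- function() {
  GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(),
    strand = character(), type = character(), gene_id = character(),
    phase = integer())
}

cdsAnnotation <- function(starts, ends, strand = "+", gene = "g1",
                          phase = NULL) {
  if (is.null(phase)) {
    phase <- integer(length(starts))
    if (strand == "+") {
      done <- 0L
      for (i in seq_along(starts)) {
        phase[i] <- (3L - done %% 3L) %% 3L
        done <- done + ends[i] - starts[i] + 1L
      }
    } else {
      done <- 0L
      for (i in rev(seq_along(starts))) {
        phase[i] <- (3L - done %% 3L) %% 3L
        done <- done + ends[i] - starts[i] + 1L
      }
    }
  }
  GenomicRanges::GRanges(
    seqnames = "region", ranges = IRanges::IRanges(starts, ends),
    strand = strand, type = "CDS", gene_id = gene, phase = phase)
}

writeFasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  f <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), f)
  f
}

# a monomorphic coding alignment from a repeated codon string
codingAlignment <- function(cds, n = 4L, outgroup = NULL) {
  seqs <- rep(cds, n)
  aln <- if (is.null(outgroup)) alnFromStrings(seqs)
         else alnFromStrings(seqs, outgroup = outgroup)
  ann <- cdsAnnotation(1L, nchar(cds))
  list(aln = aln, ann = ann, map = classifySites(aln, ann))
}
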