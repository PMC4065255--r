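#' Read an aligned multi-FASTA of phased haplotypes
#'
#' Reads an aligned multi-FASTA file into a [HaplotypeAlignment-class].
#' Sequences must be equal length and restricted to A, C, G, T, N and the
#' gap character `-`: inputs are assumed to be phased haplotypes, so IUPAC
#' ambiguity codes are rejected with an instruction to phase first.
#'
#' @param path path to an aligned multi-FASTA file.
#' @param outgroupId optional record id to flag as the outgroup haplotype.
#' @param regionOffset 1-based genomic coordinate of alignment column 1.
#' @return a [HaplotypeAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' aln <- readFastaAlignment(fa)
#' nHaplotypes(aln)
#' @export
readFastaAlignment <- function(path, outgroupId = NA_character_,
                               regionOffset = 1L) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) > 1L)
    stop("sequences are not aligned (unequal lengths): ",
         paste0(ids, "=", lens, collapse = ", "))
  chars <- toupper(as.character(seqs))
  mat <- matrix(unlist(strsplit(chars, ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  bad <- which(matrix(!(mat %in% .VALID_BASES), nrow(mat)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("ambiguity code '", mat[i, j], "' in record '", ids[i],
         "' at column ", j,
         ": inputs must be phased haplotypes (resolve heterozygous ",
         "IUPAC codes with a phasing tool before import)")
  }
  haplotypeAlignment(mat, ids, outgroupId = outgroupId,
                     regionOffset = regionOffset)
}

#' Construct a HaplotypeAlignment from a character matrix
#'
#' @param mat character matrix of A/C/G/T/N/- states, one row per haplotype.
#' @param sampleIds row identifiers; defaults to rownames or h1..hn.
#' @param outgroupId optional id of the outgroup row.
#' @param regionOffset 1-based genomic coordinate of column 1.
#' @return a [HaplotypeAlignment-class].
#' @export
haplotypeAlignment <- function(mat, sampleIds = rownames(mat),
                               outgroupId = NA_character_,
                               regionOffset = 1L) {
  if (is.null(sampleIds))
    sampleIds <- paste0("h", seq_len(nrow(mat)))
  rownames(mat) <- sampleIds
  new("HaplotypeAlignment", mat = mat, sampleIds = sampleIds,
      outgroupId = as.character(outgroupId),
      regionOffset = as.integer(regionOffset))
}

#' @describeIn haplotypeAlignment number of ingroup haplotypes (the
#'   outgroup row, if any, is excluded).
#' @param x a `HaplotypeAlignment`.
#' @export
nHaplotypes <- function(x) nrow(ingroupMatrix(x))

#' @describeIn haplotypeAlignment alignment length in columns.
#' @export
alignmentLength <- function(x) ncol(x@mat)

#' @describeIn haplotypeAlignment sample identifiers (including outgroup).
#' @export
sampleIds <- function(x) x@sampleIds

#' @describeIn haplotypeAlignment id of the outgroup row (NA if unset).
#' @export
outgroupId <- function(x) x@outgroupId

#' @describeIn haplotypeAlignment ingroup rows as a character matrix.
#' @export
ingroupMatrix <- function(x) {
  m <- x@mat
  if (!is.na(x@outgroupId)) m <- m[x@sampleIds != x@outgroupId, , drop = FALSE]
  m
}

#' @describeIn haplotypeAlignment outgroup row as a character vector, or
#'   NULL when no outgroup is flagged.
#' @export
outgroupSeq <- function(x) {
  if (is.na(x@outgroupId)) return(NULL)
  x@mat[x@outgroupId, ]
}

#' @describeIn haplotypeAlignment restrict an alignment to a subset of
#'   samples (the outgroup flag is kept if the outgroup is retained).
#' @param ids sample ids to keep.
#' @export
subsetSamples <- function(x, ids) {
  stopifnot(all(ids %in% x@sampleIds))
  og <- if (!is.na(x@outgroupId) && x@outgroupId %in% ids)
    x@outgroupId else NA_character_
  haplotypeAlignment(x@mat[ids, , drop = FALSE], ids, outgroupId = og,
                     regionOffset = x@regionOffset)
}

setMethod("show", "HaplotypeAlignment", function(object) {
  cat("HaplotypeAlignment:", nrow(object@mat), "haplotypes x",
      ncol(object@mat), "columns\n")
  if (!is.na(object@outgroupId))
    cat("  outgroup:", object@outgroupId, "\n")
  cat("  region offset:", object@regionOffset, "\n")
})

#' Read gene annotations from a GFF3 subset
#'
#' Parses gene and CDS features from a GFF3 file into a
#' [GenomicRanges::GRanges] with columns `type` ("CDS"), `gene_id` and
#' `phase`.  Coordinates are 1-based inclusive, as in GFF3.  Introns are
#' not stored: they are inferred downstream as the intra-gene gaps between
#' consecutive CDS intervals.  Within each gene the CDS must not overlap
#' and their total length, after discounting the phase of the first coding
#' segment, must be divisible by 3.
#'
#' @param path path to a GFF3 file (may be empty or header-only, in which
#'   case an empty `GRanges` is returned and the region is treated as
#'   intergenic).
#' @return a `GRanges` of CDS features sorted by start.
#' @export
readAnnotation <- function(path) {
  empty <- GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(),
    strand = character(), type = character(), gene_id = character(),
    phase = integer())
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[as.character(gr$type) == "CDS"]
  if (!length(cds)) return(empty)
  parent <- if (!is.null(cds$Parent)) {
    vapply(as.list(cds$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1))
  } else rep(NA_character_, length(cds))
  id <- if (!is.null(cds$ID)) as.character(cds$ID)
        else rep(NA_character_, length(cds))
  gene_id <- ifelse(is.na(parent), id, parent)
  if (anyNA(gene_id))
    stop("CDS features must carry a Parent or ID attribute")
  cds <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(cds),
    ranges = IRanges::ranges(cds),
    strand = GenomicRanges::strand(cds),
    type = "CDS", gene_id = gene_id,
    phase = suppressWarnings(as.integer(as.character(cds$phase))))
  cds$phase[is.na(cds$phase)] <- 0L
  cds <- cds[order(GenomicRanges::start(cds))]
  for (g in unique(cds$gene_id)) {
    gi <- cds[cds$gene_id == g]
    if (length(gi) > 1L) {
      o <- order(GenomicRanges::start(gi))
      s <- GenomicRanges::start(gi)[o]; e <- GenomicRanges::end(gi)[o]
      if (any(s[-1L] <= e[-length(e)]))
        stop("overlapping CDS within gene ", g)
    }
    firstIdx <- if (as.character(GenomicRanges::strand(gi)[1L]) == "-")
      which.max(GenomicRanges::end(gi)) else which.min(GenomicRanges::start(gi))
    adj <- sum(GenomicRanges::width(gi)) - gi$phase[firstIdx]
    if (adj %% 3L != 0L)
      stop("CDS length of gene ", g,
           " is not divisible by 3 after frame adjustment (", adj, " bp)")
  }
  cds
}

#' Read a sample-to-population map
#'
#' Reads a two-column TSV with header `sample_id<TAB>population`.  Every
#' ingroup sample must be assigned exactly one population; a virtual
#' "pooled" grouping containing all samples is always available through
#' [populationSamples()].
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample_id` and `population`.
#' @export
readPopulationMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(df)))
    stop("population map must have header: sample_id<TAB>population")
  if (anyDuplicated(df$sample_id))
    stop("samples assigned to more than one population: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  df[, c("sample_id", "population")]
}

#' @describeIn readPopulationMap sample ids belonging to one population;
#'   `"pooled"` returns every mapped sample.
#' @param popmap data.frame from `readPopulationMap`.
#' @param population population label or `"pooled"`.
#' @export
populationSamples <- function(popmap, population) {
  if (identical(population, "pooled")) return(popmap$sample_id)
  ids <- popmap$sample_id[popmap$population == population]
  if (!length(ids)) stop("unknown population: ", population)
  ids
}

# genetic code lookup on coding-strand codons (standard code)
.geneticCode <- function() Biostrings::GENETIC_CODE

.pkgCache <- new.env(parent = emptyenv())

# 64 x 3 matrix of Nei-Gojobori synonymous weights, one row per codon
.synWeightTable <- function() {
  if (is.null(.pkgCache$synW)) {
    codons <- names(Biostrings::GENETIC_CODE)
    .pkgCache$synW <- t(vapply(codons, .synWeights, numeric(3)))
  }
  .pkgCache$synW
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

.revcompCodon <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  paste(.COMPLEMENT[rev(b)], collapse = "")
}

# Nei-Gojobori synonymous weights for one coding-strand codon: per codon
# position, the fraction of the 3 possible single-base changes that leave
# the amino acid unchanged.
.synWeights <- function(codon) {
  gc <- .geneticCode()
  aa <- gc[[codon]]
  b <- strsplit(codon, "")[[1]]
  vapply(1:3, function(p) {
    alts <- setdiff(c("A", "C", "G", "T"), b[p])
    mut <- vapply(alts, function(a) {
      bb <- b; bb[p] <- a
      gc[[paste(bb, collapse = "")]]
    }, character(1))
    sum(mut == aa) / 3
  }, numeric(1))
}

# majority ingroup base per column; ties broken alphabetically; NA where
# no unambiguous base is present
.majorityBase <- function(mat) {
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  maj <- bases[max.col(counts, ties.method = "first")]
  maj[rowSums(counts) == 0L] <- NA_character_
  maj
}

#' Classify alignment columns into site classes
#'
#' Assigns every alignment column exactly one of the mutually exclusive
#' classes coding, intronic or intergenic, and computes fractional
#' synonymous/nonsynonymous site weights for coding columns by Nei-Gojobori
#' counting on a reference codon built from the majority ingroup allele of
#' each column (ties broken alphabetically).  Columns with a gap or N in
#' any ingroup row are masked; a codon overlapping a masked column is
#' wholly masked, as is any codon whose reference translation is an
#' internal stop (with a warning).
#'
#' @param alignment a [HaplotypeAlignment-class].
#' @param annotations CDS `GRanges` from [readAnnotation()] (coordinates are
#'   interpreted relative to the same genome as `regionOffset`).
#' @return a [SiteClassMap-class].
#' @export
classifySites <- function(alignment, annotations) {
  L <- alignmentLength(alignment)
  off <- alignment@regionOffset
  ing <- ingroupMatrix(alignment)
  masked <- colSums(ing == "N" | ing == "-") > 0L
  cls <- factor(rep("intergenic", L),
                levels = c("coding", "intronic", "intergenic"))
  synW <- rep(NA_real_, L)
  codonGroup <- rep(NA_integer_, L)
  refCodon <- rep(NA_character_, L)
  codonPos <- rep(NA_integer_, L)
  geneId <- rep(NA_character_, L)
  strandV <- rep(NA_character_, L)
  maj <- .majorityBase(ing)

  cds <- annotations[annotations$type == "CDS"]
  nextGroup <- 1L
  genes <- unique(cds$gene_id)
  # gene extents; error on inter-gene overlap (classes must be exclusive)
  if (length(genes) > 1L) {
    ext <- t(vapply(genes, function(g) {
      gi <- cds[cds$gene_id == g]
      c(min(GenomicRanges::start(gi)), max(GenomicRanges::end(gi)))
    }, numeric(2)))
    o <- order(ext[, 1L])
    if (any(ext[o, 1L][-1L] <= ext[o, 2L][-length(genes)]))
      stop("overlapping genes: site classes must be mutually exclusive")
  }
  for (g in genes) {
    gi <- cds[cds$gene_id == g]
    str <- as.character(GenomicRanges::strand(gi)[1L])
    o <- order(GenomicRanges::start(gi))
    s <- GenomicRanges::start(gi)[o] - off + 1L
    e <- GenomicRanges::end(gi)[o] - off + 1L
    ph <- gi$phase[o]
    if (any(s < 1L) || any(e > L))
      stop("annotation of gene ", g, " extends outside the alignment")
    # intron columns: gaps between consecutive CDS
    if (length(s) > 1L)
      for (i in seq_len(length(s) - 1L)) {
        gap <- seq(e[i] + 1L, s[i + 1L] - 1L)
        if (length(gap)) {
          cls[gap] <- "intronic"
          geneId[gap] <- g; strandV[gap] <- str
        }
      }
    cols <- unlist(lapply(seq_along(s), function(i) s[i]:e[i]))
    # translation order: genomic order on +, reversed on -
    transCols <- if (str == "-") rev(cols) else cols
    firstPhase <- if (str == "-") ph[which.max(e)] else ph[1L]
    if (firstPhase > 0L)
      transCols <- transCols[-seq_len(firstPhase)]
    stopifnot(length(transCols) %% 3L == 0L)
    codIdx <- matrix(transCols, nrow = 3L)
    nCod <- ncol(codIdx)
    allC <- as.vector(codIdx)
    cls[allC] <- "coding"
    geneId[allC] <- g; strandV[allC] <- str
    codonGroup[allC] <- nextGroup + rep(seq_len(nCod) - 1L, each = 3L)
    codonPos[allC] <- rep(1:3, nCod)
    nextGroup <- nextGroup + nCod
    # whole-codon masking: any masked or base-less column masks the codon
    badCod <- colSums(matrix(masked[allC] | is.na(maj[allC]),
                             nrow = 3L)) > 0L
    masked[as.vector(codIdx[, badCod])] <- TRUE
    okCod <- which(!badCod)
    if (length(okCod)) {
      b <- matrix(maj[as.vector(codIdx[, okCod])], nrow = 3L)
      if (str == "-") b <- matrix(.COMPLEMENT[b], nrow = 3L)
      codStr <- paste0(b[1L, ], b[2L, ], b[3L, ])
      refCodon[as.vector(codIdx[, okCod])] <- rep(codStr, each = 3L)
      isStop <- .geneticCode()[codStr] == "*"
      if (any(isStop)) {
        warning("internal stop codon in reference frame of gene ", g,
                "; codon masked")
        masked[as.vector(codIdx[, okCod[isStop]])] <- TRUE
      }
      keep <- okCod[!isStop]
      if (length(keep)) {
        w <- .synWeightTable()[codStr[!isStop], , drop = FALSE]
        synW[as.vector(codIdx[, keep])] <- as.vector(t(w))
      }
    }
    # frame-skipped leading bases remain class coding but unweighted/masked
    skipped <- setdiff(cols, as.vector(codIdx))
    if (length(skipped)) {
      cls[skipped] <- "coding"
      geneId[skipped] <- g; strandV[skipped] <- str
      masked[skipped] <- TRUE
    }
  }
  new("SiteClassMap", siteClass = cls, synWeight = synW, masked = masked,
      codonGroup = codonGroup, refCodon = refCodon, codonPos = codonPos,
      geneId = geneId, strand = strandV)
}

#' @describeIn classifySites number of unmasked columns (NS, the sites
#'   analyzed excluding gap positions).
#' @param map a `SiteClassMap`.
#' @export
analyzedSiteCount <- function(map) sum(!map@masked)

#' @describeIn classifySites fractional synonymous site count.
#' @export
synonymousSiteCount <- function(map)
  sum(map@synWeight[!map@masked & map@siteClass == "coding"])

#' @describeIn classifySites fractional nonsynonymous site count.
#' @export
nonsynonymousSiteCount <- function(map)
  sum(1 - map@synWeight[!map@masked & map@siteClass == "coding"])

#' @describeIn classifySites number of unmasked intronic columns.
#' @export
intronicSiteCount <- function(map)
  sum(!map@masked & map@siteClass == "intronic")

#' @describeIn classifySites silent site count (synonymous + intronic).
#' @export
silentSiteCount <- function(map)
  synonymousSiteCount(map) + intronicSiteCount(map)

#' @describeIn classifySites per-column class labels.
#' @export
siteClasses <- function(map) map@siteClass

#' @describeIn classifySites logical mask of excluded columns.
#' @export
maskedSites <- function(map) map@masked

setMethod("show", "SiteClassMap", function(object) {
  cat("SiteClassMap:", length(object@siteClass), "columns\n")
  print(table(class = object@siteClass, masked = object@masked))
  cat(sprintf("  synonymous sites %.2f | nonsynonymous %.2f | silent %.2f\n",
              synonymousSiteCount(object), nonsynonymousSiteCount(object),
              silentSiteCount(object)))
})
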