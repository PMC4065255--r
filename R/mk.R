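#' Two-sided Fisher exact test by full support enumeration
#'
#' Exact two-sided P for a 2x2 table [[a, b], [c, d]] under the
#' hypergeometric null, using the "sum of tables at most as probable as
#' the observed one" rule.  A zero margin makes the table degenerate and
#' returns P = 1 (flagged via the `degenerate` attribute).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return P value in (0, 1].
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  pObs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' McDonald-Kreitman test
#'
#' Contrasts fixed differences against polymorphisms, split into
#' amino-acid replacement and synonymous classes, in a 2x2 exact test.
#' Under neutrality Da/Ds = Pa/Ps; an excess of replacement divergence
#' indicates recurrent adaptive protein evolution.
#'
#' @param Da fixed amino-acid replacement differences.
#' @param Ds fixed synonymous differences.
#' @param Pa nonsynonymous polymorphisms.
#' @param Ps synonymous polymorphisms.
#' @return list with `P` (two-sided Fisher exact), `DaDs`, `PaPs` (NA on
#'   zero denominators) and the input counts.
#' @export
mkTest <- function(Da, Ds, Pa, Ps) {
  if (Da + Ds + Pa + Ps == 0)
    stop("all four MK cells are zero")
  list(Da = Da, Ds = Ds, Pa = Pa, Ps = Ps,
       DaDs = if (Ds > 0) Da / Ds else NA_real_,
       PaPs = if (Ps > 0) Pa / Ps else NA_real_,
       P = as.numeric(fisherExactTwoSided(Da, Ds, Pa, Ps)))
}

# enumerate minimal mutational pathways between two codons and average
# the synonymous/nonsynonymous step classification over them; pathways
# passing through a stop codon are excluded unless all do
.codonPathDiffs <- function(codA, codB) {
  gc <- .geneticCode()
  diffPos <- which(codA != codB)
  nd <- length(diffPos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(diffPos) else {
    idx <- seq_len(nd)
    prm <- if (nd == 2L) list(c(1L, 2L), c(2L, 1L)) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(prm, function(p) diffPos[p])
  }
  evalPath <- function(ord) {
    cur <- codA
    syn <- 0; nonsyn <- 0; hitStop <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- codB[p]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") hitStop <- TRUE
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, stop = as.numeric(hitStop))
  }
  res <- vapply(perms, evalPath, numeric(3))
  keep <- res["stop", ] == 0
  if (!any(keep)) keep <- rep(TRUE, length(perms))
  c(syn = mean(res["syn", keep]), nonsyn = mean(res["nonsyn", keep]))
}

#' Counting estimator of dN and dS between two coding sequences
#'
#' Nei-Gojobori style estimates of the per-site nonsynonymous (dN) and
#' synonymous (dS) substitution rates between two codon-aligned coding
#' sequences: synonymous/nonsynonymous site counts are fractional weights
#' averaged over both sequences; differences in multi-hit codons are
#' partitioned by averaging over minimal mutational pathways (pathways
#' through stop codons excluded when avoidable); the Jukes-Cantor
#' correction d = -(3/4) log(1 - 4p/3) is applied per class.
#'
#' @param cdsA,cdsB coding-strand CDS strings or character vectors, equal
#'   length divisible by 3; codons containing gaps, N or a stop in either
#'   sequence are skipped.
#' @return list with `dN`, `dS`, `dNdS` (NA when dS = 0), the raw
#'   proportions `pN`, `pS`, site counts `nSites`, `sSites` and
#'   difference counts `nDiff`, `sDiff`.
#' @export
neiGojoboriDnds <- function(cdsA, cdsB) {
  if (length(cdsA) == 1L) cdsA <- strsplit(toupper(cdsA), "")[[1]]
  if (length(cdsB) == 1L) cdsB <- strsplit(toupper(cdsB), "")[[1]]
  stopifnot(length(cdsA) == length(cdsB),
            length(cdsA) %% 3L == 0L)
  gc <- .geneticCode()
  nCodon <- length(cdsA) %/% 3L
  sSites <- 0; nSites <- 0; sDiff <- 0; nDiff <- 0
  for (ci in seq_len(nCodon)) {
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    codA <- cdsA[idx]; codB <- cdsB[idx]
    if (any(!codA %in% c("A", "C", "G", "T")) ||
        any(!codB %in% c("A", "C", "G", "T"))) next
    sA <- paste(codA, collapse = ""); sB <- paste(codB, collapse = "")
    if (gc[[sA]] == "*" || gc[[sB]] == "*") next
    wA <- sum(.synWeights(sA)); wB <- sum(.synWeights(sB))
    sSites <- sSites + (wA + wB) / 2
    nSites <- nSites + 3 - (wA + wB) / 2
    d <- .codonPathDiffs(codA, codB)
    sDiff <- sDiff + d[["syn"]]
    nDiff <- nDiff + d[["nonsyn"]]
  }
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75)
      stop("substitution proportion p = ", format(p, digits = 4),
           " is saturated (>= 3/4); Jukes-Cantor correction undefined")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  pS <- if (sSites > 0) sDiff / sSites else NA_real_
  pN <- if (nSites > 0) nDiff / nSites else NA_real_
  dS <- jc(pS); dN <- jc(pN)
  list(dN = dN, dS = dS,
       dNdS = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
       pN = pN, pS = pS, nSites = nSites, sSites = sSites,
       nDiff = nDiff, sDiff = sDiff)
}

#' Extract a coding-strand CDS sequence from an aligned region
#'
#' Concatenates the CDS columns of one gene in translation order
#' (reverse-complemented for minus-strand genes) for a single sample or
#' for the ingroup majority consensus.
#'
#' @param alignment a [HaplotypeAlignment-class].
#' @param annotations CDS `GRanges` from [readAnnotation()].
#' @param gene gene id.
#' @param sample sample id, or NULL for the ingroup consensus.
#' @return character vector of coding-strand bases.
#' @export
cdsSequence <- function(alignment, annotations, gene, sample = NULL) {
  cds <- annotations[annotations$type == "CDS" &
                     annotations$gene_id == gene]
  if (!length(cds)) stop("no CDS annotated for gene ", gene)
  off <- alignment@regionOffset
  str <- as.character(GenomicRanges::strand(cds)[1L])
  o <- order(GenomicRanges::start(cds))
  s <- GenomicRanges::start(cds)[o] - off + 1L
  e <- GenomicRanges::end(cds)[o] - off + 1L
  cols <- unlist(lapply(seq_along(s), function(i) s[i]:e[i]))
  seqv <- if (is.null(sample)) .majorityBase(ingroupMatrix(alignment))[cols]
          else alignment@mat[sample, cols]
  seqv[is.na(seqv)] <- "N"
  if (str == "-") unname(.COMPLEMENT[rev(seqv)]) else seqv
}

#' Polymorphism and divergence counts for a McDonald-Kreitman table
#'
#' Walks the unmasked coding columns of a region and tabulates, per
#' change: fixed differences (ingroup monomorphic and different from the
#' outgroup) split into replacement (Da) and synonymous (Ds), and
#' polymorphisms (>= 2 ingroup alleles) split into replacement (Pa) and
#' synonymous (Ps).  Sites that are both polymorphic and divergent are
#' counted as polymorphic only (the standard MK convention).  By default
#' fixed differences are unpolarized interspecific differences; supplying
#' the true ancestral sequence with `polarized = TRUE` restricts Da/Ds to
#' changes fixed along the ingroup lineage.
#'
#' @param alignment a [HaplotypeAlignment-class] with an outgroup.
#' @param map a [SiteClassMap-class].
#' @param gene optional gene id to restrict counting to one locus.
#' @param polarized count fixed differences along the ingroup branch only
#'   (requires `ancestral`).
#' @param ancestral optional character vector of true ancestral bases
#'   (same length as the alignment).
#' @return list with `Da`, `Ds`, `Pa`, `Ps`.
#' @export
polarizedSubstitutionCounts <- function(alignment, map, gene = NULL,
                                        polarized = FALSE,
                                        ancestral = NULL) {
  og <- outgroupSeq(alignment)
  if (is.null(og)) stop("MK counting requires an outgroup")
  if (polarized && is.null(ancestral))
    stop("polarized counting requires the ancestral sequence")
  ing <- ingroupMatrix(alignment)
  maj <- .majorityBase(ing)
  gc <- .geneticCode()
  bases <- c("A", "C", "G", "T")
  Da <- 0L; Ds <- 0L
  use <- !map@masked & map@siteClass == "coding" & !is.na(map@refCodon)
  if (!is.null(gene)) use <- use & map@geneId %in% gene
  stats <- .columnPairStats(alignment, map)
  cp <- stats$codingPairs
  cp <- cp[use[cp$col], , drop = FALSE]
  Pa <- sum(!cp$synonymous)
  Ps <- sum(cp$synonymous)
  aaOf <- function(j, base) {
    cod <- strsplit(map@refCodon[j], "")[[1]]
    b <- if (identical(map@strand[j], "-")) .COMPLEMENT[[base]] else base
    cod[map@codonPos[j]] <- b
    gc[[paste(cod, collapse = "")]]
  }
  for (j in which(use & !stats$polymorphic)) {
    a <- maj[j]
    b <- og[j]
    if (!a %in% bases || !b %in% bases || a == b) next
    if (polarized) {
      anc <- ancestral[j]
      if (!anc %in% bases || a == anc) next  # change on the outgroup branch
      b <- anc
    }
    if (aaOf(j, a) == aaOf(j, b)) Ds <- Ds + 1L else Da <- Da + 1L
  }
  list(Da = Da, Ds = Ds, Pa = Pa, Ps = Ps)
}
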