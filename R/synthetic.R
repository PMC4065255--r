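#' Specification of a synthetic resequencing region
#'
#' Default parameters describe the study design the package targets: a
#' 16,950-bp region carrying seven genes (a focal gene and its three
#' upstream and three downstream neighbors), resequenced in three
#' population samples with a single outgroup haplotype.  Gene ids and CDS
#' lengths echo that layout; all sequence content is synthetic.  Silent
#' mutation rates default to theta = 0.01 per site, outgroup divergence
#' time to T = 11 (2N generations, giving silent divergence near
#' theta (T+1) = 0.12 per site), and a recent sweep of intensity
#' alpha = 2.3e-4 per bp is planted at the centre of the focal gene.
#'
#' @param regionLength total region length in bp.
#' @param genes data.frame with columns gene, cdsLen, nIntrons, intronLen,
#'   strand.
#' @param thetaSilent per-site scaled silent mutation rate, one value per
#'   gene (recycled).
#' @param rho per-region scaled recombination rate.
#' @param T outgroup divergence time in 2N generations.
#' @param keepNonsyn fraction of nonsynonymous mutations retained
#'   (purifying-constraint emulation).
#' @param sweep list with `enabled`, `gene` (focal gene id) and `alpha`
#'   (per-bp sweep intensity; escape probability 1 - exp(-alpha d)).
#' @param populations named integer vector: chromosomes per population.
#' @param popDiff scaled rate of additional population-private mutations
#'   (0 = one panmictic population, the default).
#' @param seed integer seed; all outputs are deterministic given it.
#' @return a list of class `RegionSpec`.
#' @export
regionSpec <- function(regionLength = 16950L,
                       genes = data.frame(
                         gene = c("CRE02131", "srh-44", "CRE02129",
                                  "age-1", "mdt-8", "CRE01736",
                                  "CRE01735"),
                         cdsLen = c(1860L, 1905L, 960L, 3564L, 2448L,
                                    510L, 3369L),
                         nIntrons = c(1L, 1L, 1L, 3L, 2L, 0L, 1L),
                         intronLen = 52L,
                         strand = c("+", "-", "+", "+", "+", "-", "+"),
                         stringsAsFactors = FALSE),
                       thetaSilent = 0.01,
                       rho = 150,
                       T = 11,
                       keepNonsyn = 0.12,
                       sweep = list(enabled = TRUE, gene = "age-1",
                                    alpha = 2.3e-4),
                       populations = c(Ohio = 48L, Germany = 48L,
                                       Ontario = 40L),
                       popDiff = 0,
                       seed = 1L) {
  stopifnot(all(genes$cdsLen %% 3L == 0L), regionLength > 0,
            rho >= 0, T >= 0, keepNonsyn >= 0, keepNonsyn <= 1,
            all(populations >= 2L))
  spec <- list(regionLength = as.integer(regionLength), genes = genes,
               thetaSilent = rep_len(thetaSilent, nrow(genes)),
               rho = rho, T = T, keepNonsyn = keepNonsyn, sweep = sweep,
               populations = populations, popDiff = popDiff,
               seed = as.integer(seed))
  class(spec) <- "RegionSpec"
  spec
}

.nonStopCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# place genes left to right with equal intergenic gaps; errors when the
# genic span does not fit
.regionLayout <- function(spec) {
  g <- spec$genes
  spans <- g$cdsLen + g$nIntrons * g$intronLen
  gapTotal <- spec$regionLength - sum(spans)
  nGaps <- nrow(g) + 1L
  if (gapTotal < nGaps)
    stop("infeasible layout: genes (", sum(spans),
         " bp) do not fit in the region (", spec$regionLength, " bp)")
  gap <- gapTotal %/% nGaps
  extra <- gapTotal - gap * nGaps
  starts <- integer(nrow(g))
  cur <- gap + extra + 1L
  for (i in seq_len(nrow(g))) {
    starts[i] <- cur
    cur <- cur + spans[i] + gap
  }
  data.frame(gene = g$gene, start = starts, end = starts + spans - 1L,
             span = spans, stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated region
#'
#' Produces the ancestral sequence and annotation of the default
#' seven-gene region: every CDS is a valid open reading frame (ATG
#' followed by non-stop codons; minus-strand genes are reverse
#' complemented into genomic orientation), introns split the CDS into
#' equal exons, and intergenic spacers fill the remainder.  Deterministic
#' given `spec$seed`.
#'
#' @param spec a [regionSpec()].
#' @return list with `sequence` (character vector of bases), `annotations`
#'   (CDS `GRanges`), `gff` (GFF3 text lines) and `layout`.
#' @export
generateRegion <- function(spec = regionSpec()) {
  set.seed(spec$seed)
  L <- spec$regionLength
  layout <- .regionLayout(spec)
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, L, replace = TRUE)
  codons <- .nonStopCodons()
  codons <- setdiff(codons, "ATG")
  gffLines <- c("##gff-version 3")
  annStart <- integer(0); annEnd <- integer(0); annGene <- character(0)
  annStrand <- character(0); annPhase <- integer(0)
  for (i in seq_len(nrow(spec$genes))) {
    g <- spec$genes[i, ]
    lay <- layout[i, ]
    cdsSeq <- c("A", "T", "G",
                unlist(strsplit(sample(codons, g$cdsLen / 3 - 1L,
                                       replace = TRUE), "")))
    # split CDS into nIntrons+1 exons of near-equal length
    nEx <- g$nIntrons + 1L
    exLen <- rep(g$cdsLen %/% nEx, nEx)
    exLen[seq_len(g$cdsLen %% nEx)] <- exLen[seq_len(g$cdsLen %% nEx)] + 1L
    exStart <- lay$start + cumsum(c(0L, exLen[-nEx] + g$intronLen))
    exEnd <- exStart + exLen - 1L
    intronCols <- setdiff(seq(lay$start, lay$end),
                          unlist(mapply(seq, exStart, exEnd,
                                        SIMPLIFY = FALSE)))
    seqv[intronCols] <- sample(bases, length(intronCols), replace = TRUE)
    cdsCols <- unlist(mapply(seq, exStart, exEnd, SIMPLIFY = FALSE))
    if (g$strand == "+") {
      seqv[cdsCols] <- cdsSeq
    } else {
      seqv[cdsCols] <- .COMPLEMENT[rev(cdsSeq)]
    }
    # per-exon phase in translation order
    exOrder <- if (g$strand == "-") rev(seq_len(nEx)) else seq_len(nEx)
    phase <- integer(nEx)
    done <- 0L
    for (k in exOrder) {
      phase[k] <- (3L - done %% 3L) %% 3L
      done <- done + exLen[k]
    }
    annStart <- c(annStart, exStart); annEnd <- c(annEnd, exEnd)
    annGene <- c(annGene, rep(g$gene, nEx))
    annStrand <- c(annStrand, rep(g$strand, nEx))
    annPhase <- c(annPhase, phase)
    gffLines <- c(gffLines,
      paste("region", "synthetic", "gene", lay$start, lay$end, ".",
            g$strand, ".", paste0("ID=", g$gene), sep = "\t"),
      paste("region", "synthetic", "CDS", exStart, exEnd, ".",
            g$strand, phase, paste0("Parent=", g$gene), sep = "\t"))
  }
  ann <- GenomicRanges::GRanges(
    seqnames = "region",
    ranges = IRanges::IRanges(annStart, annEnd),
    strand = annStrand, type = "CDS", gene_id = annGene,
    phase = annPhase)
  ann <- ann[order(GenomicRanges::start(ann))]
  list(sequence = seqv, annotations = ann, gff = gffLines,
       layout = layout)
}

# classify the single-base change anc->alt at genomic column j in the
# ancestral codon context: "silent" (non-coding or synonymous),
# "nonsyn", or "stop" (creates a premature stop; treated as lethal and
# never accepted by the generator)
.changeType <- function(j, alt, seqv, idx) {
  if (idx$colClass[j] != 1L) return("silent")   # intron or intergenic
  gcode <- .geneticCode()
  colsC <- idx$codonMat[, idx$codonOf[j]]   # translation order
  cod <- seqv[colsC]
  alt1 <- cod
  alt1[idx$posInCodon[j]] <- alt
  if (idx$strand[j] == "-") {
    cod <- .COMPLEMENT[cod]
    alt1 <- .COMPLEMENT[alt1]
  }
  aa1 <- gcode[[paste(cod, collapse = "")]]
  aa2 <- gcode[[paste(alt1, collapse = "")]]
  if (aa2 == "*") "stop" else if (aa1 == aa2) "silent" else "nonsyn"
}

# per-column lookup tables for the generator: class (1 coding, 2 intron,
# 3 intergenic), gene index, codon membership (codons may span introns)
# and strand; codonMat columns hold the 3 genomic columns of each codon in
# translation order
.generatorSiteIndex <- function(region, spec) {
  L <- spec$regionLength
  colClass <- rep(3L, L)
  colGene <- rep(NA_integer_, L)
  codonOf <- rep(NA_integer_, L)
  posInCodon <- rep(NA_integer_, L)
  strandV <- rep(NA_character_, L)
  codonCols <- list()
  ann <- region$annotations
  for (i in seq_len(nrow(spec$genes))) {
    g <- spec$genes$gene[i]
    gi <- ann[ann$gene_id == g]
    o <- order(GenomicRanges::start(gi))
    s <- GenomicRanges::start(gi)[o]; e <- GenomicRanges::end(gi)[o]
    str <- as.character(GenomicRanges::strand(gi)[1L])
    lay <- region$layout[region$layout$gene == g, ]
    geneCols <- seq(lay$start, lay$end)
    colGene[geneCols] <- i
    strandV[geneCols] <- str
    colClass[geneCols] <- 2L
    cols <- unlist(mapply(seq, s, e, SIMPLIFY = FALSE))
    colClass[cols] <- 1L
    transCols <- if (str == "-") rev(cols) else cols
    codIdx <- matrix(transCols, nrow = 3L)
    base <- length(codonCols)
    codonOf[transCols] <- base + rep(seq_len(ncol(codIdx)), each = 3L)
    posInCodon[transCols] <- rep(1:3, ncol(codIdx))
    codonCols <- c(codonCols, lapply(seq_len(ncol(codIdx)),
                                     function(ci) codIdx[, ci]))
  }
  list(colClass = colClass, colGene = colGene,
       codonMat = do.call(cbind, codonCols), codonOf = codonOf,
       posInCodon = posInCodon, strand = strandV)
}

#' Simulate a full synthetic region sample
#'
#' Draws phased haplotypes for the configured populations (one panmictic
#' coalescent sample with recombination), maps mutations onto the
#' ancestral sequence respecting site classes (silent changes accepted
#' freely; nonsynonymous changes retained with probability
#' `spec$keepNonsyn`), applies the planted sweep by collapsing each
#' haplotype onto a founder haplotype within an exponentially distributed
#' escape distance of the sweep centre (escape rate `alpha` per bp), and
#' evolves the outgroup along a branch of length T.  Returns the complete
#' input bundle for the analysis pipeline plus a truth record holding
#' every planted parameter.
#'
#' @param spec a [regionSpec()].
#' @return list with `alignment` ([HaplotypeAlignment-class] including the
#'   outgroup row), `annotations`, `popmap` (data.frame), `gff`,
#'   `ancestral` (character vector) and `truth` (list).
#' @export
simulateRegionSample <- function(spec = regionSpec()) {
  region <- generateRegion(spec)   # consumes spec$seed deterministically
  L <- spec$regionLength
  nTot <- sum(spec$populations)
  idx <- .generatorSiteIndex(region, spec)
  thetaMax <- max(spec$thetaSilent)
  thetaMean <- mean(spec$thetaSilent)
  # one panmictic ancestral recombination graph for all populations
  sim <- simulateNeutral(nTot, theta = thetaMax * L, rho = spec$rho,
                         L = L, reps = 1L)[[1L]]
  mat <- matrix(rep(region$sequence, each = nTot), nrow = nTot)
  bases <- c("A", "C", "G", "T")
  applied <- 0L
  for (s in seq_along(sim$positions)) {
    col <- ceiling(sim$positions[s])
    col <- min(max(col, 1L), L)
    gi <- idx$colGene[col]
    thetaCol <- if (is.na(gi)) thetaMean else spec$thetaSilent[gi]
    if (runif(1L) > thetaCol / thetaMax) next
    anc <- region$sequence[col]
    alt <- sample(setdiff(bases, anc), 1L)
    type <- .changeType(col, alt, region$sequence, idx)
    if (type == "stop") next
    if (type == "nonsyn" && runif(1L) > spec$keepNonsyn) next
    mat[sim$carriers[[s]], col] <- alt
    applied <- applied + 1L
  }
  # optional population-private differentiation
  popIdx <- rep(seq_along(spec$populations), spec$populations)
  if (spec$popDiff > 0) {
    for (p in seq_along(spec$populations)) {
      rows <- which(popIdx == p)
      priv <- simulateNeutral(length(rows), theta = spec$popDiff *
                                thetaMean * L, rho = 0, L = L,
                              reps = 1L)[[1L]]
      for (s in seq_along(priv$positions)) {
        col <- min(max(ceiling(priv$positions[s]), 1L), L)
        if (idx$colClass[col] == 1L) next  # keep private load silent
        anc <- region$sequence[col]
        mat[rows[priv$carriers[[s]]], col] <-
          sample(setdiff(bases, anc), 1L)
      }
    }
  }
  # planted sweep: collapse onto the founder haplotype within the escape
  # distance of the sweep centre
  truthSweep <- NULL
  if (isTRUE(spec$sweep$enabled)) {
    lay <- region$layout[region$layout$gene == spec$sweep$gene, ]
    if (!nrow(lay)) stop("sweep gene not in the region: ",
                         spec$sweep$gene)
    x0 <- (lay$start + lay$end) / 2
    founder <- 1L
    eL <- rexp(nTot, spec$sweep$alpha)
    eR <- rexp(nTot, spec$sweep$alpha)
    eL[founder] <- Inf; eR[founder] <- Inf
    posCols <- which(colSums(mat != mat[rep(founder, nTot), ,
                                        drop = FALSE]) > 0)
    for (i in seq_len(nTot)[-founder]) {
      swept <- posCols[posCols > x0 - eL[i] & posCols < x0 + eR[i]]
      if (length(swept)) mat[i, swept] <- mat[founder, swept]
    }
    truthSweep <- list(gene = spec$sweep$gene, position = x0,
                       alpha = spec$sweep$alpha, founder = founder)
  }
  # outgroup evolved along a branch of length T (plus the ingroup depth)
  og <- region$sequence
  tg <- spec$thetaSilent[idx$colGene]
  tg[is.na(tg)] <- thetaMean
  pDiv <- pmin(tg * (spec$T + 1), 0.7)
  hit <- which(runif(L) < pDiv)
  for (col in hit) {
    anc <- region$sequence[col]
    alt <- sample(setdiff(bases, anc), 1L)
    type <- .changeType(col, alt, region$sequence, idx)
    if (type == "stop") next
    if (type == "nonsyn" && runif(1L) > spec$keepNonsyn) next
    og[col] <- alt
  }
  popLabels <- rep(names(spec$populations), spec$populations)
  ids <- paste0(popLabels, "_h",
                formatC(unlist(lapply(spec$populations, seq_len)),
                        width = 3, flag = "0"))
  allMat <- rbind(mat, og)
  rownames(allMat) <- c(ids, "outgroup")
  aln <- haplotypeAlignment(allMat, c(ids, "outgroup"),
                            outgroupId = "outgroup", regionOffset = 1L)
  popmap <- data.frame(sample_id = ids, population = popLabels,
                       stringsAsFactors = FALSE)
  truth <- list(spec = spec, sweep = truthSweep,
                mutationsSimulated = length(sim$positions),
                mutationsApplied = applied,
                outgroupChanges = sum(og != region$sequence))
  list(alignment = aln, annotations = region$annotations,
       popmap = popmap, gff = region$gff, ancestral = region$sequence,
       truth = truth)
}

#' Write a simulated bundle to the pipeline input formats
#'
#' Serialises a [simulateRegionSample()] result as the exact formats the
#' readers consume: aligned FASTA, GFF3 and a population TSV, plus a JSON
#' truth record.
#'
#' @param sim result of `simulateRegionSample`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeRegionBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "region.fa"),
             gff = file.path(dir, "region.gff3"),
             popmap = file.path(dir, "popmap.tsv"),
             truth = file.path(dir, "truth.json"))
  m <- sim$alignment@mat
  fa <- unlist(lapply(seq_len(nrow(m)), function(i)
    c(paste0(">", rownames(m)[i]), paste(m[i, ], collapse = ""))))
  writeLines(fa, paths["fasta"])
  writeLines(sim$gff, paths["gff"])
  utils::write.table(sim$popmap, paths["popmap"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$spec$genes <- as.list(truth$spec$genes)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}

#' Plant an exact McDonald-Kreitman table in a synthetic gene
#'
#' Builds a single-gene coding alignment (n ingroup haplotypes plus an
#' outgroup) realizing exactly the requested counts: Da/Ds as fixed
#' replacement/synonymous differences on the outgroup branch and Pa/Ps as
#' segregating replacement/synonymous polymorphisms, one planted change
#' per codon so that counting recovers the table exactly.
#'
#' @param Da,Ds,Pa,Ps requested counts.
#' @param cdsLength coding length in bp (divisible by 3).
#' @param n ingroup haplotypes.
#' @param seed integer seed.
#' @return list with `alignment`, `annotations` and `map` (the
#'   [SiteClassMap-class]).
#' @export
plantMkTable <- function(Da, Ds, Pa, Ps, cdsLength = 3564L, n = 8L,
                         seed = 1L) {
  stopifnot(cdsLength %% 3L == 0L, n >= 4L)
  set.seed(seed)
  nCodon <- cdsLength %/% 3L
  need <- Da + Ds + Pa + Ps
  if (need > nCodon - 1L)
    stop("infeasible counts: ", need, " changes requested but only ",
         nCodon - 1L, " codons available")
  gcode <- .geneticCode()
  fourfold <- c("GCT", "GGT", "CCT", "ACT", "GTT", "CGT", "TCT")
  cds <- c("ATG", sample(fourfold, nCodon - 1L, replace = TRUE))
  anc <- unlist(strsplit(cds, ""))
  og <- anc
  mat <- matrix(rep(anc, each = n), nrow = n)
  slots <- sample(2:nCodon)  # codon indices available for planting
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- slots[seq_len(k)]
    slots <<- slots[-seq_len(k)]
    out
  }
  synAlt <- function(codon) {  # alternative 3rd base (always synonymous)
    b <- substr(codon, 3, 3)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }
  nonsynAlt <- function(codon) {  # 2nd-position change avoiding stops
    b <- strsplit(codon, "")[[1]]
    for (alt in sample(setdiff(c("A", "C", "G", "T"), b[2L]))) {
      cand <- b; cand[2L] <- alt
      if (gcode[[paste(cand, collapse = "")]] != "*" &&
          gcode[[paste(cand, collapse = "")]] != gcode[[codon]])
        return(alt)
    }
    stop("no nonsynonymous non-stop change available for ", codon)
  }
  for (ci in take(Ds)) og[3L * ci] <- synAlt(cds[ci])
  for (ci in take(Da)) og[3L * ci - 1L] <- nonsynAlt(cds[ci])
  nMinor <- max(1L, n %/% 4L)
  for (ci in take(Ps))
    mat[seq_len(nMinor), 3L * ci] <- synAlt(cds[ci])
  for (ci in take(Pa))
    mat[seq_len(nMinor), 3L * ci - 1L] <- nonsynAlt(cds[ci])
  allMat <- rbind(mat, og)
  ids <- c(paste0("h", seq_len(n)), "outgroup")
  rownames(allMat) <- ids
  aln <- haplotypeAlignment(allMat, ids, outgroupId = "outgroup")
  ann <- GenomicRanges::GRanges(
    seqnames = "gene", ranges = IRanges::IRanges(1L, cdsLength),
    strand = "+", type = "CDS", gene_id = "planted", phase = 0L)
  map <- classifySites(aln, ann)
  list(alignment = aln, annotations = ann, map = map)
}
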