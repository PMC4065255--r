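#' Restrict an alignment to a contiguous column range
#'
#' @param alignment a [HaplotypeAlignment-class].
#' @param from,to 1-based alignment columns (inclusive).
#' @return a [HaplotypeAlignment-class] with adjusted region offset.
#' @export
subsetColumns <- function(alignment, from, to) {
  stopifnot(from >= 1L, to <= alignmentLength(alignment), from <= to)
  haplotypeAlignment(alignment@mat[, from:to, drop = FALSE],
                     alignment@sampleIds,
                     outgroupId = alignment@outgroupId,
                     regionOffset = alignment@regionOffset + from - 1L)
}

# gene extents (alignment columns) from a CDS GRanges
.geneExtents <- function(annotations, regionOffset = 1L) {
  genes <- unique(annotations$gene_id)
  do.call(rbind, lapply(genes, function(g) {
    gi <- annotations[annotations$gene_id == g]
    data.frame(gene = g,
               from = min(GenomicRanges::start(gi)) - regionOffset + 1L,
               to = max(GenomicRanges::end(gi)) - regionOffset + 1L,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full sweep-detection pipeline on one region
#'
#' Executes the analysis stages in order -- per-locus diversity,
#' site-frequency-spectrum neutrality tests, pairwise and
#' maximum-likelihood HKA, the CLR and omega sweep scans, and
#' McDonald-Kreitman / dN-dS -- on a region bundle, writing tab-separated
#' tables, scan tracks and a JSON manifest to `outDir`.  Inputs may be
#' file paths or an in-memory bundle from [simulateRegionSample()].
#'
#' @param bundle list with `alignment`, `annotations`, `popmap` (e.g. from
#'   [simulateRegionSample()]); alternatively supply `fasta`, `gff`,
#'   `popmapPath` and `outgroupId` to read from files.
#' @param fasta,gff,popmapPath input file paths (ignored when `bundle`
#'   given).
#' @param outgroupId outgroup record id for file input.
#' @param focalGene focal locus for HKA and reporting (default the middle
#'   gene).
#' @param outDir output directory.
#' @param populations population labels to analyze; "pooled" is always
#'   added.
#' @param repsD,repsH,repsHka,repsCutoff replicate counts for the
#'   empirical nulls (published-scale defaults are 50000, 10000, 10000,
#'   10000; reduce them for quick runs).
#' @param scanPopulation population whose sample feeds the sweep scans
#'   (default "pooled").
#' @param seed master seed; every stochastic stage derives its seed from
#'   it and records it in the outputs.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
runPipeline <- function(bundle = NULL, fasta = NULL, gff = NULL,
                        popmapPath = NULL, outgroupId = "outgroup",
                        focalGene = NULL, outDir = tempfile("sweeprun"),
                        populations = NULL,
                        repsD = 50000L, repsH = 10000L,
                        repsHka = 10000L, repsCutoff = 10000L,
                        scanPopulation = "pooled", seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(bundle)) {
    if (is.null(fasta) || is.null(gff) || is.null(popmapPath))
      stop("provide either a bundle or fasta + gff + popmapPath")
    bundle <- list(alignment = readFastaAlignment(fasta, outgroupId),
                   annotations = readAnnotation(gff),
                   popmap = readPopulationMap(popmapPath))
  }
  aln <- bundle$alignment
  ann <- bundle$annotations
  popmap <- bundle$popmap
  if (is.null(outgroupId) || is.na(outgroupId(aln)))
    stop("the pipeline's unfolded tests require an outgroup haplotype; ",
         "flag one with outgroupId")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ext <- .geneExtents(ann, aln@regionOffset)
  if (is.null(focalGene)) focalGene <- ext$gene[(nrow(ext) + 1L) %/% 2L]
  if (is.null(populations))
    populations <- unique(popmap$population)
  populations <- c(populations, "pooled")
  stageTimes <- list()
  tick <- function(name) {
    t <- proc.time()[["elapsed"]]
    stageTimes[[name]] <<- round(t - t0, 2)
    t0 <<- t
  }

  # ---- diversity + neutrality per population x locus -------------------
  divRows <- list(); neutRows <- list()
  perPop <- list()
  for (pop in populations) {
    ids <- populationSamples(popmap, pop)
    sub <- subsetSamples(aln, c(ids, outgroupId(aln)))
    for (gi in seq_len(nrow(ext))) {
      locAln <- subsetColumns(sub, ext$from[gi], ext$to[gi])
      locAnn <- ann[ann$gene_id == ext$gene[gi]]
      map <- classifySites(locAln, locAnn)
      row <- locusSummary(ext$gene[gi], locAln, map)
      row <- cbind(sample = pop, row)
      d <- neutralityTest(locAln, map, "D", "silent", reps = repsD,
                          seed = seed + gi)
      h <- neutralityTest(locAln, map, "H", "silent", reps = repsH,
                          seed = seed + 100L + gi)
      row$D_Taj <- d$value; row$P_D <- d$P
      row$H_FW <- h$value; row$P_H <- h$P
      divRows[[paste(pop, gi)]] <- row
      perPop[[pop]][[ext$gene[gi]]] <- list(alignment = locAln, map = map)
    }
  }
  divTab <- do.call(rbind, divRows)
  utils::write.table(formatDiversityTable(divTab),
                     file.path(outDir, "diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("diversity_neutrality")

  # ---- sliding-window diversity track ---------------------------------
  poolIds <- populationSamples(popmap, "pooled")
  poolAln <- subsetSamples(aln, c(poolIds, outgroupId(aln)))
  poolMap <- classifySites(poolAln, ann)
  wt <- slidingWindowPi(poolAln, poolMap)
  utils::write.table(wt, file.path(outDir, "window_pi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("window_track")

  # ---- HKA: pairwise focal-vs-neighbor and multilocus ML --------------
  hkaRowsByPop <- lapply(setNames(populations, populations), function(pop) {
    do.call(rbind, lapply(seq_len(nrow(ext)), function(gi) {
      x <- perPop[[pop]][[ext$gene[gi]]]
      sfsSil <- .classSiteIndices(x$alignment, x$map, "silent")
      Dsil <- .silentDivergence(x$alignment, x$map) *
        silentSiteCount(x$map)
      hkaLoci(ext$gene[gi], nHaplotypes(x$alignment),
              max(silentSiteCount(x$map), 1), sfsSil$S, Dsil)
    }))
  })
  hkaOut <- list()
  for (pop in populations) {
    loci <- hkaRowsByPop[[pop]]
    pw <- lapply(setdiff(loci$locus, focalGene), function(other) {
      r <- pairwiseHka(loci[loci$locus %in% c(focalGene, other), ],
                       reps = repsHka, seed = seed + 200L)
      data.frame(sample = pop, focal = focalGene, other = other,
                 X2 = r$X2, P = r$P)
    })
    fit0 <- mlhkaFit(loci, focal = focalGene, selection = FALSE)
    fit1 <- mlhkaFit(loci, focal = focalGene, selection = TRUE)
    lrt <- mlhkaLrt(fit0, fit1)
    hkaOut[[pop]] <- list(pairwise = do.call(rbind, pw),
                          mlhka = data.frame(
                            sample = pop, k = lrt$k,
                            L0 = fit0@logLik, L1 = fit1@logLik,
                            twoDeltaL = lrt$twoDeltaL, P = lrt$P))
  }
  mlhkaTab <- do.call(rbind, lapply(hkaOut, `[[`, "mlhka"))
  utils::write.table(mlhkaTab, file.path(outDir, "mlhka.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, lapply(hkaOut, `[[`, "pairwise")),
                     file.path(outDir, "hka_pairwise.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("hka")

  # ---- sweep scans ----------------------------------------------------
  scanIds <- populationSamples(popmap, scanPopulation)
  scanAln <- subsetSamples(aln, c(scanIds, outgroupId(aln)))
  scanMap <- classifySites(scanAln, ann)
  snps <- snpMatrixFromAlignment(scanAln, scanMap)
  clr <- clrScan(snps)
  om <- omegaScan(snps)
  if (repsCutoff > 0) {   # repsCutoff = 0 skips the simulated cutoffs
    clr <- scanCutoff(clr, snps, reps = repsCutoff, seed = seed + 300L,
                      rho = 0)
    om <- scanCutoff(om, snps, reps = repsCutoff, seed = seed + 400L,
                     rho = 20)
  }
  clrDf <- data.frame(position = clr@position, CLR = clr@stat,
                      alpha_hat = clr@alphaHat)
  omDf <- data.frame(position = om@position, omega = om@stat)
  utils::write.table(clrDf, file.path(outDir, "clr_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(omDf, file.path(outDir, "omega_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("sweep_scans")

  # ---- MK and dN/dS ---------------------------------------------------
  mkRows <- lapply(seq_len(nrow(ext)), function(gi) {
    x <- perPop[["pooled"]][[ext$gene[gi]]]
    counts <- polarizedSubstitutionCounts(x$alignment, x$map)
    mk <- mkTest(counts$Da, counts$Ds, counts$Pa, counts$Ps)
    cons <- cdsSequence(x$alignment, ann, ext$gene[gi])
    ogc <- cdsSequence(x$alignment, ann, ext$gene[gi],
                       sample = outgroupId(aln))
    dn <- neiGojoboriDnds(cons, ogc)
    data.frame(locus = ext$gene[gi], dN = dn$dN, dS = dn$dS,
               dNdS = dn$dNdS, Da = mk$Da, Ds = mk$Ds, DaDs = mk$DaDs,
               Pa = mk$Pa, Ps = mk$Ps, PaPs = mk$PaPs, P = mk$P)
  })
  mkTab <- do.call(rbind, mkRows)
  utils::write.table(mkTab, file.path(outDir, "mk.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("mk_dnds")

  manifest <- list(
    package = "sweepsig",
    version = as.character(utils::packageVersion("sweepsig")),
    seed = seed,
    replicates = list(D = repsD, H = repsH, hka = repsHka,
                      cutoffs = repsCutoff),
    focalGene = focalGene,
    stages = names(stageTimes),
    stageSeconds = as.list(stageTimes),
    outputs = list.files(outDir))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(diversity = divTab, windows = wt, hka = hkaOut,
                 mlhka = mlhkaTab, clr = clr, omega = om, mk = mkTab,
                 manifest = manifest, outDir = outDir))
}
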