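test_that("region generation is deterministic with valid ORFs", {
  spec <- regionSpec(seed = 7)
  r1 <- generateRegion(spec)
  r2 <- generateRegion(spec)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$gff, r2$gff)
  expect_equal(nrow(r1$layout), 7L)
  expect_lte(max(r1$layout$end), spec$regionLength)
  expect_true(all(diff(r1$layout$start) > 0))
  # every CDS translates without internal stops
  aln1 <- haplotypeAlignment(matrix(r1$sequence, nrow = 1),
                             "anc")
  gcode <- Biostrings::GENETIC_CODE
  for (g in spec$genes$gene) {
    cds <- cdsSequence(
      haplotypeAlignment(rbind(r1$sequence, r1$sequence),
                         c("a", "b")), r1$annotations, g)
    codons <- apply(matrix(cds, nrow = 3), 2, paste, collapse = "")
    expect_false(any(gcode[codons] == "*"), info = g)
    expect_equal(paste(cds[1:3], collapse = ""), "ATG", info = g)
  }
})

test_that("infeasible gene layouts are rejected", {
  genes <- data.frame(gene = "big", cdsLen = 3000L, nIntrons = 0L,
                      intronLen = 0L, strand = "+")
  expect_error(generateRegion(regionSpec(regionLength = 2000L,
                                         genes = genes,
                                         sweep = list(enabled = FALSE))),
               "infeasible layout")
})

test_that("simulated samples pass input validation with zero warnings", {
  spec <- regionSpec(seed = 23, populations = c(Ohio = 12L, Germany = 10L))
  sim <- simulateRegionSample(spec)
  expect_warning(map <- classifySites(sim$alignment, sim$annotations),
                 NA)
  expect_equal(nHaplotypes(sim$alignment), 22L)
  expect_equal(nrow(sim$popmap), 22L)
  # bundle round-trips through the on-disk formats
  dir <- tempfile("bundle")
  paths <- writeRegionBundle(sim, dir)
  aln <- readFastaAlignment(paths[["fasta"]], outgroupId = "outgroup")
  expect_identical(aln@mat, sim$alignment@mat)
  ann <- readAnnotation(paths[["gff"]])
  expect_equal(length(ann), length(sim$annotations))
  pm <- readPopulationMap(paths[["popmap"]])
  expect_equal(pm, sim$popmap)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$spec$seed, 23L)
  expect_equal(truth$sweep$gene, "age-1")
})

test_that("same seed gives byte-identical simulated bundles", {
  spec <- regionSpec(seed = 31, populations = c(Ohio = 8L))
  s1 <- simulateRegionSample(spec)
  s2 <- simulateRegionSample(spec)
  expect_identical(s1$alignment@mat, s2$alignment@mat)
  expect_identical(s1$truth, s2$truth)
})

test_that("outgroup silent divergence sits near theta (T+1)", {
  divs <- vapply(41:44, function(s) {
    spec <- regionSpec(seed = s, populations = c(Ohio = 8L),
                       sweep = list(enabled = FALSE))
    sim <- simulateRegionSample(spec)
    map <- classifySites(sim$alignment, sim$annotations)
    sweepsig:::.silentDivergence(sim$alignment, map)
  }, numeric(1))
  expected <- 0.01 * 12   # thetaSilent * (T + 1)
  expect_equal(mean(divs), expected, tolerance = 0.15)
})

test_that("planted sweeps depress diversity at the focal gene", {
  # strong-sweep parameters: alpha = 2e-5 per bp
  ratios <- vapply(1:20, function(s) {
    spec <- regionSpec(seed = 100 + s, populations = c(Ohio = 24L))
    spec$sweep$alpha <- 2e-5
    sim <- simulateRegionSample(spec)
    ext <- sweepsig:::.geneExtents(sim$annotations, 1L)
    piSi <- vapply(seq_len(nrow(ext)), function(i) {
      sub <- subsetColumns(sim$alignment, ext$from[i], ext$to[i])
      m <- classifySites(sub,
                         sim$annotations[sim$annotations$gene_id ==
                                         ext$gene[i]])
      pairwisePi(sub, m, "silent")
    }, numeric(1))
    names(piSi) <- ext$gene
    piSi[["age-1"]] / mean(c(piSi[["CRE02131"]], piSi[["CRE01735"]]))
  }, numeric(1))
  # 0/0 replicates (everything monomorphic) have no defined ratio
  expect_lte(median(ratios, na.rm = TRUE), 0.2)
})

test_that("the swept gene shows the negative D and H signature", {
  hits <- 0L
  for (s in 1:5) {
    spec <- regionSpec(seed = 300 + s, populations = c(Ohio = 24L))
    spec$sweep$alpha <- 1e-4
    sim <- simulateRegionSample(spec)
    ext <- sweepsig:::.geneExtents(sim$annotations, 1L)
    i <- which(ext$gene == "age-1")
    sub <- subsetColumns(sim$alignment, ext$from[i], ext$to[i])
    map <- classifySites(sub, sim$annotations[
      sim$annotations$gene_id == "age-1"])
    seg <- segregatingSites(sub, map)
    if (seg$Ssil < 2) next
    piHat <- meanPairwiseDifferences(sub, map, "silent")
    d <- tajimasD(piHat, seg$Ssil, nHaplotypes(sub))
    sfs <- buildSfs(sub, map = map)
    h <- fayWuHNorm(unfoldedCounts(sfs), nHaplotypes(sub))
    if (!is.na(d) && !is.na(h) && d < 0 && h < 0) hits <- hits + 1L
  }
  expect_gte(hits, 3L)  # majority of strong-sweep replicates
})

test_that("neutral control keeps the focal/outer diversity ratio near 1", {
  ratios <- vapply(1:20, function(s) {
    spec <- regionSpec(seed = 200 + s, populations = c(Ohio = 24L),
                       sweep = list(enabled = FALSE))
    sim <- simulateRegionSample(spec)
    ext <- sweepsig:::.geneExtents(sim$annotations, 1L)
    piSi <- vapply(seq_len(nrow(ext)), function(i) {
      sub <- subsetColumns(sim$alignment, ext$from[i], ext$to[i])
      m <- classifySites(sub,
                         sim$annotations[sim$annotations$gene_id ==
                                         ext$gene[i]])
      pairwisePi(sub, m, "silent")
    }, numeric(1))
    names(piSi) <- ext$gene
    piSi[["age-1"]] / mean(c(piSi[["CRE02131"]], piSi[["CRE01735"]]))
  }, numeric(1))
  expect_gte(median(ratios), 0.5)
  expect_lte(median(ratios), 2)
})
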