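test_that("aligned FASTA reads back and malformed inputs are rejected", {
  set.seed(1)
  seqs <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
          collapse = ""), character(1))
  aln <- readFastaAlignment(writeFasta(seqs))
  expect_s4_class(aln, "HaplotypeAlignment")
  expect_equal(nHaplotypes(aln), 4L)
  expect_equal(alignmentLength(aln), 100L)
  expect_equal(unname(aln@mat[2, 1:5]),
               strsplit(seqs[2], "")[[1]][1:5])

  short <- c(seqs[1:3], substr(seqs[4], 1, 99))
  expect_error(readFastaAlignment(writeFasta(short)), "unequal length")

  amb <- seqs
  substr(amb[3], 17, 17) <- "R"
  err <- tryCatch(readFastaAlignment(writeFasta(amb)),
                  error = conditionMessage)
  expect_match(err, "s3")
  expect_match(err, "17")
  expect_match(err, "phas")

  expect_error(readFastaAlignment(writeFasta(c(seqs[1], seqs[2]),
                                             ids = c("a", "a"))),
               "duplicate")
})

test_that("GFF3 subset parses, infers introns and enforces frame", {
  gff <- c("##gff-version 3",
           "region\tsyn\tgene\t10\t400\t.\t+\t.\tID=g1",
           "region\tsyn\tCDS\t10\t159\t.\t+\t0\tParent=g1",
           "region\tsyn\tCDS\t210\t362\t.\t+\t0\tParent=g1")
  f <- tempfile(fileext = ".gff3"); writeLines(gff, f)
  ann <- readAnnotation(f)
  expect_equal(length(ann), 2L)
  expect_equal(sum(GenomicRanges::width(ann)), 303L)
  # intron = intra-gene gap, recovered by classification
  aln <- randomAlignment(3, 400, seed = 2)
  map <- suppressWarnings(classifySites(aln, ann))
  expect_equal(sum(siteClasses(map) == "intronic"), 50L)

  f2 <- tempfile(); writeLines("##gff-version 3", f2)
  expect_equal(length(readAnnotation(f2)), 0L)

  bad <- c("##gff-version 3",
           "region\tsyn\tCDS\t10\t310\t.\t+\t0\tParent=g1")
  f3 <- tempfile(fileext = ".gff3"); writeLines(bad, f3)
  expect_error(readAnnotation(f3), "divisible by 3")

  over <- c("##gff-version 3",
            "region\tsyn\tCDS\t10\t60\t.\t+\t0\tParent=g1",
            "region\tsyn\tCDS\t50\t100\t.\t+\t0\tParent=g1")
  f4 <- tempfile(fileext = ".gff3"); writeLines(over, f4)
  expect_error(readAnnotation(f4), "overlapping CDS")
})

test_that("population map enforces one population per sample", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation", "a\tOhio", "b\tGermany"), f)
  pm <- readPopulationMap(f)
  expect_equal(populationSamples(pm, "Ohio"), "a")
  expect_setequal(populationSamples(pm, "pooled"), c("a", "b"))
  expect_error(populationSamples(pm, "nowhere"), "unknown population")
  writeLines(c("sample_id\tpopulation", "a\tOhio", "a\tGermany"), f)
  expect_error(readPopulationMap(f), "more than one population")
})

test_that("codon synonymous weights follow single-base-change enumeration", {
  # independent oracle: enumerate the 9 single-base mutants of a codon
  # against the standard genetic code
  gc <- Biostrings::GENETIC_CODE
  oracle <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    vapply(1:3, function(p) {
      muts <- vapply(setdiff(c("A", "C", "G", "T"), b[p]), function(x) {
        bb <- b; bb[p] <- x; gc[[paste(bb, collapse = "")]]
      }, character(1))
      sum(muts == gc[[codon]]) / 3
    }, numeric(1))
  }
  expect_equal(oracle("TTT"), c(0, 0, 1 / 3))
  expect_equal(oracle("ATG"), c(0, 0, 0))
  for (codon in c("TTT", "ATG", "CTG", "GCA", "TGG", "ATA", "AGG")) {
    fx <- codingAlignment(codon)
    expect_equal(synonymousSiteCount(fx$map), sum(oracle(codon)),
                 info = codon)
  }
})

test_that("site classes are exclusive, exhaustive and silent = syn + intronic", {
  set.seed(3)
  aln <- randomAlignment(6, 120, seed = 3)
  ann <- cdsAnnotation(c(11, 61), c(40, 90))  # 60-bp CDS, 20-bp intron
  map <- classifySites(aln, ann)
  cls <- siteClasses(map)
  expect_equal(length(cls), 120L)
  expect_false(anyNA(cls))  # exactly one class per column
  expect_equal(sum(cls == "coding"), 60L)
  expect_equal(sum(cls == "intronic"), 20L)
  expect_equal(sum(cls == "intergenic"), 40L)
  expect_equal(silentSiteCount(map),
               synonymousSiteCount(map) + intronicSiteCount(map))
  # per-codon weights sum: syn + nonsyn = unmasked coding columns
  expect_equal(synonymousSiteCount(map) + nonsynonymousSiteCount(map),
               sum(cls == "coding" & !maskedSites(map)))
})

test_that("classification is strand-consistent under reverse complement", {
  set.seed(4)
  L <- 90L
  # 4:2 row weighting avoids majority ties, which are broken
  # alphabetically and thus not strand-symmetric
  a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  aln <- haplotypeAlignment(rbind(a, a, a, a, b, b),
                            paste0("h", 1:6))
  ann <- cdsAnnotation(16, 75, strand = "+")
  mapF <- classifySites(aln, ann)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcMat <- matrix(comp[aln@mat[, L:1]], nrow = nrow(aln@mat))
  alnR <- haplotypeAlignment(rcMat, sampleIds(aln))
  annR <- cdsAnnotation(L - 75 + 1, L - 16 + 1, strand = "-")
  mapR <- classifySites(alnR, annR)
  expect_equal(synonymousSiteCount(mapR), synonymousSiteCount(mapF))
  expect_equal(nonsynonymousSiteCount(mapR), nonsynonymousSiteCount(mapF))
  expect_equal(analyzedSiteCount(mapR), analyzedSiteCount(mapF))
})

test_that("gap/N columns mask whole codons and drop out of NS", {
  fx <- codingAlignment("ATGCTGAAA", n = 3)
  expect_equal(analyzedSiteCount(fx$map), 9L)
  m <- fx$aln@mat
  m[2, 5] <- "-"
  aln2 <- haplotypeAlignment(m, sampleIds(fx$aln))
  map2 <- classifySites(aln2, fx$ann)
  # the gap column masks its whole codon, removing 3 sites from NS
  expect_equal(analyzedSiteCount(map2), 6L)
  expect_true(all(maskedSites(map2)[4:6]))
  expect_equal(synonymousSiteCount(map2),
               synonymousSiteCount(classifySites(
                 codingAlignment("ATGAAA", n = 3)$aln,
                 cdsAnnotation(1, 6))) + 0)
})

test_that("internal reference stop codons are masked with a warning", {
  expect_warning(codingAlignment("ATGTAAAAA", n = 3), "stop codon")
})
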