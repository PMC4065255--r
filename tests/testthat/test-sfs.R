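test_that("outgroup polarization follows the exact-match rule", {
  # n=4, one site {A:3, G:1}; outgroup A => derived G at count 1
  aln <- alnFromStrings("A", "A", "A", "G", outgroup = "A")
  sfs <- buildSfs(aln)
  expect_equal(unfoldedCounts(sfs), c(1, 0, 0))
  expect_equal(sfs@nPolarized, 1L)

  # outgroup C (third allele) => unpolarizable, folded only
  aln2 <- alnFromStrings("A", "A", "A", "G", outgroup = "C")
  sfs2 <- buildSfs(aln2)
  expect_equal(sum(unfoldedCounts(sfs2)), 0)
  expect_equal(foldedCounts(sfs2), c(1, 0))
  expect_equal(sfs2@nUnpolarizable, 1L)

  noOut <- alnFromStrings("A", "A", "A", "G")
  expect_error(buildSfs(noOut), "outgroup")
  expect_s4_class(buildSfs(noOut, folded = TRUE), "SiteFrequencySpectrum")
})

test_that("folding identity holds on random alignments", {
  # independent fold-by-definition oracle on minor allele counts
  for (seed in c(21, 22, 23)) {
    aln <- randomAlignment(10, 200, seed = seed, outgroup = TRUE)
    sfs <- buildSfs(aln)
    oracleEta <- numeric(5)
    ing <- ingroupMatrix(aln)
    for (j in seq_len(ncol(ing))) {
      tab <- table(ing[, j])
      if (length(tab) != 2L) next
      mc <- min(tab)
      oracleEta[mc] <- oracleEta[mc] + 1
    }
    expect_equal(foldedCounts(sfs), oracleEta)
    # eta_i = xi_i + xi_(n-i) restricted to polarized sites
    polAln <- sfs@nUnpolarizable == 0
    if (polAln) expect_equal(foldSpectrum(sfs), foldedCounts(sfs))
    expect_equal(sum(unfoldedCounts(sfs)) + sfs@nUnpolarizable,
                 sum(foldedCounts(sfs)))
  }
})

test_that("Tajima's D matches its defining constants", {
  n <- 10
  a1 <- sum(1 / (1:9))
  expect_equal(tajimasD(5 / a1, 5, n), 0)   # numerator exactly zero
  expect_true(is.na(tajimasD(0, 0, n)))     # undefined at S = 0

  # all-singleton spectrum forces D < 0
  countsSingle <- rep(1L, 8)
  piHat <- sum(2 * countsSingle * (n - countsSingle)) / (n * (n - 1))
  expect_lt(tajimasD(piHat, 8, n), 0)

  # independent textbook-constant reimplementation
  oracleD <- function(piHat, S, n) {
    a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (piHat - S / a1) / sqrt(c1 / a1 * S +
                            c2 / (a1^2 + a2) * S * (S - 1))
  }
  reps <- simulateFixedS(12, 15, reps = 20, seed = 31)
  for (rp in reps) {
    ph <- sum(2 * rp$counts * (12 - rp$counts)) / (12 * 11)
    expect_equal(tajimasD(ph, 15, 12), oracleD(ph, 15, 12),
                 tolerance = 1e-12)
  }
})

test_that("normalized H has the forced signs and direct-formula value", {
  n <- 10
  # all derived at count n-1: strong high-frequency excess => H << 0
  xiHigh <- c(rep(0, n - 2), 6)
  expect_lt(fayWuHNorm(xiHigh, n), -1)

  # all singletons: theta_L < theta_pi => H > 0 (direct evaluation)
  xiLow <- c(6, rep(0, n - 2))
  S <- 6
  an <- sum(1 / seq_len(n - 1)); bn <- sum(1 / seq_len(n - 1)^2)
  bn1 <- sum(1 / seq_len(n)^2)
  thetaPi <- 1 * (n - 1) * 6 * 2 / (n * (n - 1))
  thetaL <- 6 / (n - 1)
  thetaW <- S / an
  theta2 <- S * (S - 1) / (an^2 + bn)
  varH <- thetaW * (n - 2) / (6 * (n - 1)) +
    theta2 * (18 * n^2 * (3 * n + 2) * bn1 -
              (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  expected <- (thetaPi - thetaL) / sqrt(varH)
  expect_gt(expected, 0)
  expect_equal(fayWuHNorm(xiLow, n), expected, tolerance = 1e-12)

  expect_true(is.na(fayWuHNorm(rep(0, n - 1), n)))
})

test_that("H ignores monomorphic sites and D ignores column order", {
  aln <- randomAlignment(8, 120, seed = 41, outgroup = TRUE)
  map <- classifySites(aln, emptyAnnotation())
  sfs <- buildSfs(aln, map = map)
  h0 <- fayWuHNorm(unfoldedCounts(sfs), 8)
  # append monomorphic columns
  extra <- matrix("A", nrow(aln@mat), 30)
  aln2 <- haplotypeAlignment(cbind(aln@mat, extra), sampleIds(aln),
                             outgroupId = "og")
  sfs2 <- buildSfs(aln2, map = classifySites(aln2, emptyAnnotation()))
  expect_equal(fayWuHNorm(unfoldedCounts(sfs2), 8), h0)

  set.seed(5)
  perm <- sample(ncol(aln@mat))
  aln3 <- haplotypeAlignment(aln@mat[, perm], sampleIds(aln),
                             outgroupId = "og")
  map3 <- classifySites(aln3, emptyAnnotation())
  expect_equal(meanPairwiseDifferences(aln3, map3, "total"),
               meanPairwiseDifferences(aln, map, "total"))
})

test_that("neutrality tests attach fixed-S empirical P values", {
  set.seed(6)
  aln <- randomAlignment(10, 300, seed = 51, outgroup = TRUE)
  map <- classifySites(aln, emptyAnnotation())
  d <- neutralityTest(aln, map, "D", "total", reps = 300, seed = 3)
  expect_true(is.finite(d$value))
  expect_gt(d$P, 0); expect_lte(d$P, 1)
  expect_equal(d$reps, 300L)
  # determinism under seed
  d2 <- neutralityTest(aln, map, "D", "total", reps = 300, seed = 3)
  expect_equal(d$P, d2$P)
  h <- neutralityTest(aln, map, "H", "total", reps = 200, seed = 4)
  expect_true(is.finite(h$value))
})

test_that("misorientation probability follows the JC-style formula", {
  # d = 0 -> 0
  s <- paste(rep("ATGAAACCTGGG", 3), collapse = "")
  fx <- codingAlignment(s, n = 3, outgroup = s)
  mis0 <- misorientationProbability(fx$aln, fx$map)
  expect_equal(mis0$pMis, 0)
  # direct formula check at d = 0.03 and the order-of-magnitude case
  expect_equal((0.03 / 3) / (1 - 2 * 0.03 / 3), 0.01 / 0.98)
  pm <- function(d) (d / 3) / (1 - 2 * d / 3)
  expect_equal(pm(0.03), 0.0102, tolerance = 1e-3)
  expect_true(abs(pm(0.003) - 0.001) < 2e-4)  # ~0.1%, sweep-study order
})

test_that("empirical rank reports ties and midrank percentiles", {
  r <- empiricalRank(-2.08, c(-1.9, -1.2, 0.3, 1.1))
  expect_equal(r$rank, 0L)  # most negative of all
  expect_equal(r$percentile, 0)

  r2 <- empiricalRank(-2, c(-2, -1, 0))
  expect_equal(r2$ties, 1L)
  expect_equal(r2$rank, 1L)

  vals <- sort(rnorm(11))
  r3 <- empiricalRank(vals[6], vals)
  expect_equal(r3$percentile, 50)
  expect_error(empiricalRank(1, numeric(0)), "non-empty")
})
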