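# independent enumeration oracle for the sweep-transformed spectrum:
# loops over escape counts, ordered hypergeometric draws and the collapse
# choice, coded separately from the vectorized implementation
sweepSfsOracle <- function(q, pe, n) {
  r <- numeric(n + 1)
  for (B in 0:n) {
    wB <- choose(n, B) * pe^B * (1 - pe)^(n - B)
    if (wB == 0) next
    if (B == n) { r[2:n] <- r[2:n] + wB * q; next }
    m <- B + 1
    for (j in seq_len(n - 1)) {
      for (k in 0:min(m, j)) {
        if (m - k > n - j) next
        h <- choose(j, k) * choose(n - j, m - k) / choose(n, m)
        # collapsed lineage is one of the m draws, uniformly
        pDerived <- k / m
        if (k > 0)
          r[(k - 1) + (n - B) + 1] <- r[(k - 1) + (n - B) + 1] +
            wB * q[j] * h * pDerived
        r[k + 1] <- r[k + 1] + wB * q[j] * h * (1 - pDerived)
      }
    }
  }
  poly <- r[2:n]
  poly / sum(poly)
}

test_that("sweep-transformed spectrum matches outcome enumeration at n=4", {
  q <- rep(1 / 3, 3)
  for (pe in c(0.1, 0.3, 0.5, 0.8)) {
    expect_equal(as.numeric(sweepTransformedSfs(q, pe = pe, alpha = NA,
                                                d = NA, n = 4)),
                 sweepSfsOracle(q, pe, 4), tolerance = 1e-12,
                 info = paste("pe", pe))
  }
  skewed <- c(0.6, 0.3, 0.1)
  expect_equal(as.numeric(sweepTransformedSfs(skewed, pe = 0.4,
                                              alpha = NA, d = NA, n = 4)),
               sweepSfsOracle(skewed, 0.4, 4), tolerance = 1e-12)
})

test_that("sweep transform limits: full escape and complete hitchhiking", {
  n <- 10
  q <- (1 / (1:(n - 1))); q <- q / sum(q)
  expect_equal(as.numeric(sweepTransformedSfs(q, pe = 1, alpha = NA,
                                              d = NA, n = n)),
               as.numeric(q))
  p0 <- sweepTransformedSfs(q, pe = 0, alpha = NA, d = NA, n = n)
  expect_equal(attr(p0, "polymorphicMass"), 0)
  # alpha*d -> large behaves like the background
  far <- sweepTransformedSfs(q, alpha = 1, d = 50, n = n)
  expect_equal(as.numeric(far), as.numeric(q), tolerance = 1e-6)
})

test_that("transformed spectra renormalize to 1 over (alpha, d) grids", {
  n <- 12
  set.seed(7)
  q <- runif(n - 1); q <- q / sum(q)
  for (alpha in c(1e-4, 1e-3, 1e-2)) {
    for (d in c(10, 300, 5000)) {
      p <- sweepTransformedSfs(q, alpha = alpha, d = d, n = n)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
})

test_that("r-squared matches direct haplotype-frequency counting", {
  a <- c(1, 1, 0, 0, 1, 0, 1, 0)
  expect_equal(rSquared(a, a), 1)
  expect_equal(rSquared(a, 1 - a), 1)   # complementary columns
  b <- c(1, 0, 0, 1, 1, 0, 0, 0)
  # direct counting oracle
  pA <- sum(a) / 8; pB <- sum(b) / 8; pAB <- sum(a & b) / 8
  expect_equal(rSquared(a, b),
               (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB)))
  expect_true(is.na(rSquared(rep(1, 8), b)))
  # allele-relabeling invariance
  expect_equal(rSquared(1 - a, b), rSquared(a, b))
})

test_that("omega equals exhaustive split enumeration on a 12-SNP instance", {
  set.seed(8)
  n <- 16
  mat <- matrix(rbinom(n * 12, 1, 0.5), nrow = n)
  keep <- colSums(mat) > 0 & colSums(mat) < n
  mat[, !keep] <- 1 - rbind(matrix(0, n - 1, sum(!keep)),
                            matrix(1, 1, sum(!keep)))
  pos <- sort(sample(100:3900, 12))
  snps <- new("SnpMatrix", positions = as.numeric(pos), mat = mat,
              polarized = rep(TRUE, 12))
  x <- 2000
  minwin <- 1000; maxwin <- 2000
  # brute force: every admissible (left extension, right extension) pair
  r2 <- suppressWarnings(stats::cor(mat))^2
  left <- which(pos < x & pos >= x - maxwin)
  right <- which(pos >= x & pos <= x + maxwin)
  left <- left[order(x - pos[left])]
  right <- right[order(pos[right] - x)]
  iMin <- max(2, sum(x - pos[left] <= minwin))
  kMin <- max(2, sum(pos[right] - x <= minwin))
  best <- -Inf
  for (i in iMin:length(left)) {
    for (k in kMin:length(right)) {
      Ls <- left[1:i]; Rs <- right[1:k]
      wl <- sum(r2[Ls, Ls][upper.tri(diag(i))])
      wr <- sum(r2[Rs, Rs][upper.tri(diag(k))])
      cross <- sum(r2[Ls, Rs])
      om <- ((wl + wr) / (choose(i, 2) + choose(k, 2))) /
        (cross / (i * k))
      if (is.finite(om) && om > best) best <- om
    }
  }
  expect_equal(omegaAt(x, snps, minwin, maxwin)$omega, best,
               tolerance = 1e-12)
})

test_that("omega toy patterns: equal correlations and decoupled blocks", {
  n <- 12
  set.seed(2)
  h <- rbinom(n, 1, 0.5)
  pos <- as.numeric(c(seq(100, 900, 200), seq(1100, 1900, 200)))
  same <- matrix(rep(h, 10), ncol = 10)
  snpsSame <- new("SnpMatrix", positions = pos, mat = same,
                  polarized = rep(TRUE, 10))
  expect_equal(omegaAt(1000, snpsSame, 1000, 2000)$omega, 1)

  h2 <- rbinom(n, 1, 0.5)
  while (identical(h2, h) || identical(h2, 1 - h)) h2 <- rbinom(n, 1, 0.5)
  blocks <- cbind(matrix(rep(h, 5), ncol = 5), matrix(rep(h2, 5), ncol = 5))
  snpsBlk <- new("SnpMatrix", positions = pos, mat = blocks,
                 polarized = rep(TRUE, 10))
  omBlk <- omegaAt(1000, snpsBlk, 1000, 2000)$omega
  expect_gt(omBlk, 1)  # within-flank LD perfect, cross-flank lower
  # perfectly uncorrelated blocks hit the +Inf sentinel
  h3 <- c(rep(1, n / 2), rep(0, n / 2))
  h4 <- rep(c(1, 0), n / 2)  # r2(h3, h4) == 0
  dec <- cbind(matrix(rep(h3, 5), ncol = 5), matrix(rep(h4, 5), ncol = 5))
  snpsDec <- new("SnpMatrix", positions = pos, mat = dec,
                 polarized = rep(TRUE, 10))
  expect_true(is.infinite(omegaAt(1000, snpsDec, 1000, 2000)$omega))
})

test_that("omega scan grid spans the SNP range with NA where undefined", {
  set.seed(9)
  n <- 10
  mat <- matrix(rbinom(n * 30, 1, 0.4), nrow = n)
  ok <- colSums(mat) > 0 & colSums(mat) < n
  mat <- mat[, ok]
  pos <- sort(sample(1:8000, ncol(mat)))
  snps <- new("SnpMatrix", positions = as.numeric(pos), mat = mat,
              polarized = rep(TRUE, ncol(mat)))
  tr <- omegaScan(snps, grid = 40)
  expect_equal(length(tr@position), 40L)
  expect_equal(tr@position[1], min(pos))
  expect_equal(tr@position[40], max(pos))
  expect_true(is.na(tr@stat[1]))  # no left flank at the first grid point
})

test_that("CLR collapses to zero when only the neutral alpha is available", {
  set.seed(10)
  n <- 10
  bg <- rep(1 / (n - 1), n - 1)
  S <- 40
  counts <- sample(1:(n - 1), S, replace = TRUE)
  mat <- sapply(seq_len(S), function(s) {
    v <- integer(n); v[sample(n, counts[s])] <- 1L; v })
  snps <- new("SnpMatrix", positions = sort(runif(S, 1, 1e4)), mat = mat,
              polarized = rep(TRUE, S))
  # at alpha*d effectively infinite the sweep model IS the background:
  # the lookup tables map such values to the background row exactly
  tabs <- sweepsig:::.sweepTables(bg, n)
  bins <- sweepsig:::.binOf(c(1e6, 1e9), tabs$x)
  expect_true(all(bins == length(tabs$x) + 1L))
  expect_equal(tabs$logTab[length(tabs$x) + 1L, seq_len(n - 1)],
               log(bg))
  # hence the neutral sentinel in the alpha grid keeps CLR >= 0
  tr2 <- clrScan(snps, background = bg, grid = 20)
  expect_true(all(tr2@stat >= 0))
  expect_error(clrScan(new("SnpMatrix",
                           positions = 1, mat = matrix(c(0L, 1L), 2, 1),
                           polarized = TRUE)),
               "at least 2 SNPs")
})

test_that("CLR localizes a sweep simulated from its own model", {
  set.seed(11)
  n <- 20; S <- 200; L <- 17000; x0 <- 6500; alphaTrue <- 8e-4
  bg <- 1 / (1:(n - 1)); bg <- bg / sum(bg)
  hits <- 0
  for (rep in 1:5) {
    pos <- sort(runif(S, 1, L))
    counts <- vapply(pos, function(p) {
      pr <- sweepTransformedSfs(bg, alpha = alphaTrue, d = abs(p - x0),
                                n = n)
      sample(1:(n - 1), 1, prob = pr)
    }, numeric(1))
    mat <- sapply(seq_len(S), function(s) {
      v <- integer(n); v[sample(n, counts[s])] <- 1L; v })
    snps <- new("SnpMatrix", positions = pos, mat = mat,
                polarized = rep(TRUE, S))
    mx <- scanMax(clrScan(snps, background = bg))
    if (abs(mx$position - x0) <= 2000) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("background spectrum estimation splits folded SNPs evenly", {
  n <- 6
  mat <- cbind(c(1, 0, 0, 0, 0, 0),   # polarized singleton
               c(1, 1, 0, 0, 0, 0),   # folded doubleton
               c(1, 1, 1, 1, 0, 0))   # polarized count 4
  snps <- new("SnpMatrix", positions = c(10, 20, 30), mat = mat,
              polarized = c(TRUE, FALSE, TRUE))
  q <- backgroundSfs(snps)
  expect_equal(as.numeric(q), c(1, 0.5, 0, 1.5, 0) / 3)
  expect_equal(sum(q), 1)
})

test_that("scan cutoffs are reproducible and attached to the track", {
  set.seed(12)
  rep1 <- simulateFixedS(10, 60, reps = 1, seed = 3, matrices = TRUE)[[1]]
  snps <- snpMatrixFromReplicate(rep1, 10000)
  tr <- clrScan(snps, grid = 30)
  tr <- scanCutoff(tr, snps, reps = 120, seed = 5, grid = 25)
  expect_true(is.finite(tr@cutoff))
  expect_equal(tr@replicates, 120L)
  tr2 <- scanCutoff(clrScan(snps, grid = 30), snps, reps = 120, seed = 5,
                    grid = 25)
  expect_identical(tr@cutoff, tr2@cutoff)
})
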