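#' Build a site frequency spectrum with outgroup polarization
#'
#' Tabulates biallelic ingroup sites into the unfolded spectrum (derived
#' allele counts, polarized by the outgroup haplotype) and the folded
#' spectrum (minor allele counts).  A site is polarized if and only if the
#' outgroup carries a valid base matching exactly one of the two ingroup
#' alleles; sites where the outgroup is missing, gapped or carries a third
#' allele enter the folded spectrum only, mirroring a per-site mixed
#' folded/unfolded scheme.  Sites with more than two ingroup alleles are
#' excluded (infinite-sites filter) and reported in `nExcluded`.
#'
#' @param alignment a [HaplotypeAlignment-class]; must carry an outgroup
#'   unless `folded = TRUE`.
#' @param sites optional integer vector of column indices to use (e.g. the
#'   silent columns of a [SiteClassMap-class]); defaults to all columns.
#' @param map optional [SiteClassMap-class] used to drop masked columns.
#' @param folded set TRUE to build a purely folded spectrum without an
#'   outgroup.
#' @return a [SiteFrequencySpectrum-class].
#' @export
buildSfs <- function(alignment, sites = NULL, map = NULL, folded = FALSE) {
  ing <- ingroupMatrix(alignment)
  n <- nrow(ing)
  og <- outgroupSeq(alignment)
  if (is.null(og) && !folded)
    stop("unfolded spectrum requested but the alignment has no outgroup; ",
         "set folded = TRUE or provide outgroupId")
  L <- ncol(ing)
  use <- rep(TRUE, L)
  if (!is.null(map)) use <- use & !map@masked
  if (!is.null(sites)) use <- use & seq_len(L) %in% sites
  xi <- numeric(n - 1L)
  eta <- numeric(n %/% 2L)
  nPol <- 0L; nUnpol <- 0L; nExcl <- 0L
  bases <- c("A", "C", "G", "T")
  for (j in which(use)) {
    col <- ing[, j]
    if (any(!col %in% bases)) next
    tab <- table(col)
    if (length(tab) < 2L) next
    if (length(tab) > 2L) { nExcl <- nExcl + 1L; next }
    alleles <- names(tab)
    cnt <- as.integer(tab)
    ogb <- if (is.null(og) || folded) NA_character_ else og[j]
    if (!is.na(ogb) && ogb %in% bases && ogb %in% alleles) {
      derived <- alleles[alleles != ogb]
      d <- cnt[alleles == derived]
      xi[d] <- xi[d] + 1
      nPol <- nPol + 1L
    } else {
      nUnpol <- nUnpol + 1L
    }
    m <- min(cnt)
    eta[m] <- eta[m] + 1
  }
  new("SiteFrequencySpectrum", n = as.integer(n), xi = xi, eta = eta,
      nPolarized = nPol, nUnpolarizable = nUnpol, nExcluded = nExcl)
}

#' @describeIn buildSfs unfolded counts xi_i, i = 1..n-1.
#' @param sfs a `SiteFrequencySpectrum`.
#' @export
unfoldedCounts <- function(sfs) sfs@xi

#' @describeIn buildSfs folded counts eta_i, i = 1..floor(n/2).
#' @export
foldedCounts <- function(sfs) sfs@eta

#' @describeIn buildSfs fold the unfolded counts by the identity
#'   eta_i = xi_i + xi_(n-i) (i < n/2), eta_(n/2) = xi_(n/2).
#' @export
foldSpectrum <- function(sfs) {
  n <- sfs@n
  vapply(seq_len(n %/% 2L), function(i)
    if (i < n - i) sfs@xi[i] + sfs@xi[n - i] else sfs@xi[i], numeric(1))
}

setMethod("show", "SiteFrequencySpectrum", function(object) {
  cat("SiteFrequencySpectrum: n =", object@n, "\n")
  cat("  polarized:", object@nPolarized,
      "| unpolarizable:", object@nUnpolarizable,
      "| excluded (>2 alleles):", object@nExcluded, "\n")
})

#' Tajima's D
#'
#' D = (pi_hat - S/a1) / sqrt(e1 S + e2 S (S-1)) with pi_hat the mean
#' number of pairwise differences (in counts, over the same sites as S)
#' and the usual coefficients a1 = sum(1/i), a2 = sum(1/i^2) for i < n,
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#' Undefined (NA) at S = 0.
#'
#' @param piHat mean pairwise differences in counts.
#' @param S number of segregating sites.
#' @param n sample size.
#' @return Tajima's D (NA when S = 0).
#' @export
tajimasD <- function(piHat, S, n) {
  stopifnot(n >= 2)
  if (S < 1) return(NA_real_)
  a1 <- .harmonic(n - 1)
  a2 <- .harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Normalized Fay-Wu H
#'
#' H = (theta_pi - theta_L) / sqrt(Var), contrasting pairwise diversity
#' against the high-frequency-weighted estimator theta_L, normalized so
#' that the statistic has approximately zero mean and unit variance under
#' neutrality.  With unfolded counts xi_i over polarized sites:
#' theta_pi = sum i (n-i) xi_i * 2/(n(n-1)), theta_L = sum i xi_i / (n-1),
#' theta_W = S/a_n, theta2 = S(S-1)/(a_n^2 + b_n), and
#' Var = theta_W (n-2)/(6(n-1)) +
#'       theta2 (18 n^2 (3n+2) b_(n+1) - (88 n^3 + 9 n^2 - 13 n + 6)) /
#'       (9 n (n-1)^2),
#' where a_n = sum(1/i, i < n), b_n = sum(1/i^2, i < n) and
#' b_(n+1) = sum(1/i^2, i <= n).  Negative H indicates an excess of
#' high-frequency derived variants, a sweep signature.
#'
#' @param xi unfolded counts (length n-1) over polarized sites.
#' @param n sample size.
#' @return normalized H (NA when no polarized segregating sites).
#' @export
fayWuHNorm <- function(xi, n) {
  stopifnot(length(xi) == n - 1L)
  S <- sum(xi)
  if (S < 1) return(NA_real_)
  i <- seq_len(n - 1L)
  an <- .harmonic(n - 1)
  bn <- .harmonic2(n - 1)
  bn1 <- .harmonic2(n)
  thetaPi <- sum(i * (n - i) * xi) * 2 / (n * (n - 1))
  thetaL <- sum(i * xi) / (n - 1)
  thetaW <- S / an
  theta2 <- S * (S - 1) / (an^2 + bn)
  varH <- thetaW * (n - 2) / (6 * (n - 1)) +
    theta2 * (18 * n^2 * (3 * n + 2) * bn1 -
              (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  (thetaPi - thetaL) / sqrt(varH)
}

#' @describeIn fayWuHNorm convenience wrapper taking a vector of per-site
#'   derived allele counts (1..n-1) instead of tabulated xi.
#' @param counts derived allele counts, one entry per polarized site.
#' @export
fayWuHFromCounts <- function(counts, n) {
  xi <- tabulate(counts, nbins = n - 1L)
  fayWuHNorm(xi, n)
}

#' Neutrality test with a fixed-S coalescent null
#'
#' Computes Tajima's D or normalized Fay-Wu H on one site class of an
#' alignment and attaches a two-tailed empirical P value from neutral
#' coalescent simulations conditioning on the observed number of
#' segregating sites (no intragenic recombination -- the conservative
#' choice).  The empirical P uses the +1 correction (r+1)/(reps+1).
#'
#' @param alignment a [HaplotypeAlignment-class].
#' @param map a [SiteClassMap-class].
#' @param stat "D" (Tajima) or "H" (normalized Fay-Wu).
#' @param class site class for the statistic ("silent" is the table
#'   default; "synonymous" reproduces coding-only usage).
#' @param reps coalescent replicates (published-scale defaults are 50000
#'   for D and 10000 for H; pass smaller values for quick exploration).
#' @param seed integer seed for the null simulation.
#' @return list with `statistic`, `value`, `P`, `reps`, `seed`, `S`, `n`.
#' @export
neutralityTest <- function(alignment, map, stat = c("D", "H"),
                           class = c("silent", "synonymous", "total"),
                           reps = NULL, seed = 1L) {
  stat <- match.arg(stat)
  class <- match.arg(class)
  if (is.null(reps)) reps <- if (stat == "D") 50000L else 10000L
  n <- nHaplotypes(alignment)
  sel <- .classSiteIndices(alignment, map, class)
  if (stat == "D") {
    piHat <- meanPairwiseDifferences(alignment, map, class)
    S <- sel$S
    value <- tajimasD(piHat, S, n)
  } else {
    sfs <- buildSfs(alignment, sites = sel$sites, map = map)
    S <- as.integer(sfs@nPolarized)
    value <- fayWuHNorm(sfs@xi, n)
  }
  if (is.na(value) || S < 1)
    return(list(statistic = stat, value = NA_real_, P = NA_real_,
                reps = 0L, seed = seed, S = S, n = n))
  sims <- simulateFixedS(n, S, reps = reps, seed = seed)
  nullVals <- vapply(sims, function(rp) {
    if (stat == "D") {
      ph <- sum(2 * rp$counts * (n - rp$counts)) / (n * (n - 1))
      tajimasD(ph, S, n)
    } else fayWuHFromCounts(rp$counts, n)
  }, numeric(1))
  r <- sum(abs(nullVals) >= abs(value), na.rm = TRUE)
  list(statistic = stat, value = value, P = empiricalP(r, reps),
       reps = as.integer(reps), seed = as.integer(seed), S = S, n = n)
}

# column indices belonging to one site class, and the matching segregating
# site count used for fixed-S conditioning
.classSiteIndices <- function(alignment, map, class) {
  unmasked <- !map@masked
  seg <- segregatingSites(alignment, map)
  switch(class,
    total = list(sites = which(unmasked), S = seg$P),
    silent = {
      s <- .columnPairStats(alignment, map)
      cp <- s$codingPairs
      synCols <- as.integer(names(which(vapply(
        split(cp$synonymous, cp$col), all, logical(1)))))
      intronCols <- which(unmasked & map@siteClass == "intronic")
      monoCoding <- which(unmasked & map@siteClass == "coding" &
                          !s$polymorphic)
      list(sites = sort(c(synCols, intronCols, monoCoding)), S = seg$Ssil)
    },
    synonymous = {
      s <- .columnPairStats(alignment, map)
      cp <- s$codingPairs
      synCols <- as.integer(names(which(vapply(
        split(cp$synonymous, cp$col), all, logical(1)))))
      monoCoding <- which(unmasked & map@siteClass == "coding" &
                          !s$polymorphic)
      list(sites = sort(c(synCols, monoCoding)), S = seg$Ssyn)
    })
}

#' Probability of ancestral-state misorientation
#'
#' Under a Jukes-Cantor-style argument, the probability that the outgroup
#' base at a polymorphic site has itself been substituted so that it
#' coincides with the derived ingroup allele is p = (d/3) / (1 - 2d/3),
#' where d is the per-site silent divergence between the ingroup consensus
#' and the outgroup.  High-frequency-derived tests are sensitive to such
#' misorientation, so this quantifies how much of an observed skew could
#' be artifactual.
#'
#' @param alignment a [HaplotypeAlignment-class] with an outgroup.
#' @param map a [SiteClassMap-class].
#' @return list with `d` (silent divergence) and `pMis`.
#' @export
misorientationProbability <- function(alignment, map) {
  og <- outgroupSeq(alignment)
  if (is.null(og)) stop("misorientation probability requires an outgroup")
  d <- .silentDivergence(alignment, map)
  if (is.na(d)) stop("silent divergence is not computable")
  if (d >= 0.75)
    stop("silent divergence is saturated (d >= 3/4); misorientation ",
         "probability undefined")
  list(d = d, pMis = (d / 3) / (1 - 2 * d / 3))
}

# per-site silent divergence between ingroup consensus and outgroup:
# differences at intronic columns plus synonymous-classified differences
# at coding columns, over the silent site count
.silentDivergence <- function(alignment, map) {
  og <- outgroupSeq(alignment)
  ing <- ingroupMatrix(alignment)
  maj <- .majorityBase(ing)
  bases <- c("A", "C", "G", "T")
  ok <- !map@masked & og %in% bases & maj %in% bases
  diffs <- 0
  intron <- ok & map@siteClass == "intronic"
  diffs <- diffs + sum(maj[intron] != og[intron])
  gc <- .geneticCode()
  coding <- which(ok & map@siteClass == "coding" & !is.na(map@refCodon) &
                  maj != og)
  for (j in coding) {
    cp <- map@codonPos[j]
    codon <- strsplit(map@refCodon[j], "")[[1]]
    minus <- identical(map@strand[j], "-")
    b1 <- if (minus) .COMPLEMENT[[maj[j]]] else maj[j]
    b2 <- if (minus) .COMPLEMENT[[og[j]]] else og[j]
    c1 <- codon; c1[cp] <- b1
    c2 <- codon; c2[cp] <- b2
    if (gc[[paste(c1, collapse = "")]] == gc[[paste(c2, collapse = "")]])
      diffs <- diffs + 1
  }
  den <- silentSiteCount(map)
  if (den <= 0) return(NA_real_)
  diffs / den
}

#' Rank a focal statistic against an empirical background
#'
#' Reports how a focal value sits within an empirical background
#' distribution (e.g. a focal gene's Tajima's D against a panel of
#' reference genes): the count of background values at or below the focal
#' value, the number of exact ties, and the midrank percentile.
#'
#' @param focal focal value.
#' @param background non-empty numeric vector of background values.
#' @return list with `rank` (count of background <= focal), `ties`,
#'   `percentile` (midrank, in percent) and `nBackground`.
#' @export
empiricalRank <- function(focal, background) {
  if (!length(background)) stop("background must be non-empty")
  below <- sum(background < focal)
  ties <- sum(background == focal)
  list(rank = below + ties,
       ties = ties,
       percentile = 100 * (below + 0.5 * ties) / length(background),
       nBackground = length(background))
}
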