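#' @importFrom stats setNames
NULL

# Shared per-column polymorphism bookkeeping for an alignment + site map.
# Returns base counts, per-column pairwise difference counts, and a table
# of observed allele pairs at polymorphic coding columns classified as
# synonymous or nonsynonymous in the reference codon context.
.columnPairStats <- function(alignment, map) {
  ing <- ingroupMatrix(alignment)
  n <- nrow(ing)
  L <- ncol(ing)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(ing == b), numeric(L))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  counts <- t(counts)  # 4 x L
  nPairs <- n * (n - 1) / 2
  pairDiff <- nPairs - colSums(choose(counts, 2))
  pairDiff[map@masked] <- NA_real_
  poly <- !map@masked & colSums(counts > 0) > 1L
  gc <- .geneticCode()
  codingPoly <- which(poly & map@siteClass == "coding" & !is.na(map@refCodon))
  pairRows <- lapply(codingPoly, function(j) {
    present <- bases[counts[, j] > 0]
    cp <- map@codonPos[j]
    codon <- strsplit(map@refCodon[j], "")[[1]]
    minus <- identical(map@strand[j], "-")
    aa <- vapply(present, function(b) {
      cb <- if (minus) .COMPLEMENT[[b]] else b
      cod <- codon; cod[cp] <- cb
      gc[[paste(cod, collapse = "")]]
    }, character(1))
    cmb <- utils::combn(seq_along(present), 2)
    data.frame(
      col = j,
      npairs = counts[match(present, bases)[cmb[1L, ]], j] *
               counts[match(present, bases)[cmb[2L, ]], j],
      synonymous = aa[cmb[1L, ]] == aa[cmb[2L, ]]
    )
  })
  codingPairs <- if (length(pairRows)) do.call(rbind, pairRows) else
    data.frame(col = integer(), npairs = numeric(), synonymous = logical())
  list(n = n, nPairs = nPairs, counts = counts, pairDiff = pairDiff,
       polymorphic = poly, codingPairs = codingPairs)
}

# numerator (mean pairwise differences, in counts) and usable-site
# denominator for one site class
.classPi <- function(stats, map, class) {
  unmasked <- !map@masked
  cp <- stats$codingPairs
  switch(class,
    total = list(
      num = sum(stats$pairDiff[unmasked]) / stats$nPairs,
      den = sum(unmasked)),
    synonymous = list(
      num = sum(cp$npairs[cp$synonymous]) / stats$nPairs,
      den = synonymousSiteCount(map)),
    nonsynonymous = list(
      num = sum(cp$npairs[!cp$synonymous]) / stats$nPairs,
      den = nonsynonymousSiteCount(map)),
    silent = list(
      num = (sum(cp$npairs[cp$synonymous]) +
             sum(stats$pairDiff[unmasked & map@siteClass == "intronic"])) /
            stats$nPairs,
      den = silentSiteCount(map)),
    stop("unknown site class: ", class)
  )
}

#' Nucleotide diversity (pi) by site class
#'
#' Average pairwise difference per site (Nei's pi, uncorrected for multiple
#' hits) over the unmasked columns of one site class.  For the coding
#' classes the denominator is the fractional synonymous or nonsynonymous
#' site count; "silent" pools synonymous and intronic sites.  Returns `NA`
#' (an explicit undefined result) when the class contains no usable sites.
#'
#' @param alignment a [HaplotypeAlignment-class] with >= 2 ingroup rows.
#' @param map the [SiteClassMap-class] from [classifySites()].
#' @param class one of "total", "synonymous", "nonsynonymous", "silent".
#' @return per-site diversity (plain scale; multiply by 1e3 for table
#'   display).
#' @export
pairwisePi <- function(alignment, map,
                       class = c("total", "synonymous", "nonsynonymous",
                                 "silent")) {
  class <- match.arg(class)
  if (nHaplotypes(alignment) < 2L)
    stop("pi requires at least 2 ingroup haplotypes")
  s <- .columnPairStats(alignment, map)
  p <- .classPi(s, map, class)
  if (p$den <= 0) return(NA_real_)
  p$num / p$den
}

#' Mean pairwise differences in counts over a site class
#'
#' The unscaled numerator of pi: the average number of pairwise
#' differences over the columns of a class (needed by Tajima's D, which is
#' defined on counts, not per-site values).
#'
#' @inheritParams pairwisePi
#' @return mean number of pairwise differences.
#' @export
meanPairwiseDifferences <- function(alignment, map,
                                    class = c("total", "synonymous",
                                              "nonsynonymous", "silent")) {
  class <- match.arg(class)
  s <- .columnPairStats(alignment, map)
  .classPi(s, map, class)$num
}

#' Segregating-site and change counts by class
#'
#' Counts polymorphic columns and classifies observed changes at coding
#' columns as synonymous or amino-acid replacements.  A coding column is a
#' silent segregating site when every observed allele pair at it is
#' synonymous; columns with both kinds of change are counted in the
#' replacement and synonymous change totals but not as silent sites.
#'
#' @inheritParams pairwisePi
#' @return list with `P` (polymorphic unmasked columns), `A` (replacement
#'   changes), `Syn` (synonymous changes), `Ssil` (segregating silent
#'   sites) and `Ssyn` (segregating all-synonymous coding sites).
#' @export
segregatingSites <- function(alignment, map) {
  s <- .columnPairStats(alignment, map)
  cp <- s$codingPairs
  perCol <- split(cp$synonymous, cp$col)
  allSyn <- vapply(perCol, all, logical(1))
  P <- sum(s$polymorphic)
  Ssyn <- sum(allSyn)
  intronPoly <- sum(s$polymorphic & map@siteClass == "intronic")
  list(P = P,
       A = sum(!cp$synonymous),
       Syn = sum(cp$synonymous),
       Ssil = Ssyn + intronPoly,
       Ssyn = Ssyn)
}

#' Watterson's theta per site
#'
#' theta_W = S / (a_n * L) with a_n the harmonic number sum(1/i, i < n).
#'
#' @param S number of segregating sites.
#' @param n number of chromosomes (>= 2).
#' @param L number of sites.
#' @return per-site Watterson estimate.
#' @export
wattersonTheta <- function(S, n, L) {
  if (n < 2) stop("watterson theta requires n >= 2")
  stopifnot(S >= 0, L > 0)
  S / (.harmonic(n - 1) * L)
}

.harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))
.harmonic2 <- function(k) if (k < 1) 0 else sum(1 / seq_len(k)^2)

#' Sliding-window nucleotide diversity
#'
#' Computes pi in fixed-length windows advanced by a fixed step across the
#' alignment.  Windows are defined on alignment coordinates including
#' masked columns; masked columns drop out of both the numerator and the
#' denominator, which keeps tracks positionally stable.  The window count
#' is floor((L - window) / step) + 1.
#'
#' @param alignment a [HaplotypeAlignment-class].
#' @param map optional [SiteClassMap-class]; when omitted all columns are
#'   treated as unmasked intergenic sites except those with gaps/N.
#' @param window window length in bp (default 150).
#' @param step step size in bp (default 25).
#' @return data.frame with columns start, end, midpoint, pi (per site; NA
#'   where a window has no usable sites).
#' @export
slidingWindowPi <- function(alignment, map = NULL, window = 150L,
                            step = 25L) {
  L <- alignmentLength(alignment)
  if (L < window)
    stop("alignment (", L, " bp) shorter than one window (", window,
         " bp); no truncated windows are produced")
  ing <- ingroupMatrix(alignment)
  n <- nrow(ing)
  masked <- if (is.null(map)) colSums(ing == "N" | ing == "-") > 0L
            else map@masked
  bases <- c("A", "C", "G", "T")
  counts <- t(vapply(bases, function(b) colSums(ing == b), numeric(L)))
  nPairs <- n * (n - 1) / 2
  pd <- (nPairs - colSums(choose(counts, 2))) / nPairs
  pd[masked] <- 0
  use <- as.numeric(!masked)
  starts <- seq(1L, L - window + 1L, by = step)
  cumPd <- c(0, cumsum(pd))
  cumUse <- c(0, cumsum(use))
  ends <- starts + window - 1L
  num <- cumPd[ends + 1L] - cumPd[starts]
  den <- cumUse[ends + 1L] - cumUse[starts]
  pi <- ifelse(den > 0, num / den, NA_real_)
  off <- alignment@regionOffset
  data.frame(start = starts + off - 1L, end = ends + off - 1L,
             midpoint = (starts + ends) / 2 + off - 1L, pi = pi)
}

#' Per-locus diversity summary (one table row)
#'
#' Summarises one locus in one sample: sample size, sites analyzed,
#' polymorphism counts and diversity by site class -- the shape of a
#' standard polymorphism table row.
#'
#' @param locus locus identifier.
#' @param alignment a [HaplotypeAlignment-class] restricted to the locus.
#' @param map matching [SiteClassMap-class].
#' @return one-row data.frame with columns locus, n, NS, P, A, S, pi, piA,
#'   piS, piSi (diversity on the raw per-site scale).
#' @export
locusSummary <- function(locus, alignment, map) {
  seg <- segregatingSites(alignment, map)
  data.frame(
    locus = locus,
    n = nHaplotypes(alignment),
    NS = analyzedSiteCount(map),
    P = seg$P, A = seg$A, S = seg$Syn,
    pi = pairwisePi(alignment, map, "total"),
    piA = pairwisePi(alignment, map, "nonsynonymous"),
    piS = pairwisePi(alignment, map, "synonymous"),
    piSi = pairwisePi(alignment, map, "silent"),
    stringsAsFactors = FALSE)
}

#' Format a diversity table for display
#'
#' Scales the per-site diversity columns of [locusSummary()] output by
#' 1e3, mirroring the usual published presentation; machine-readable
#' output should keep the raw scale.
#'
#' @param df data.frame of `locusSummary` rows.
#' @param digits rounding for the scaled columns.
#' @return data.frame with pi columns multiplied by 1000.
#' @export
formatDiversityTable <- function(df, digits = 2) {
  for (cl in intersect(c("pi", "piA", "piS", "piSi"), names(df)))
    df[[cl]] <- round(df[[cl]] * 1e3, digits)
  df
}
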