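#' Extract biallelic SNPs from a haplotype alignment
#'
#' Builds a [SnpMatrix-class] from the ingroup rows of an alignment:
#' masked columns and sites with more than two ingroup alleles are
#' dropped; each retained SNP is polarized against the outgroup where
#' possible (1 = derived allele) and kept as a folded site otherwise
#' (1 = minor allele).
#'
#' @param alignment a [HaplotypeAlignment-class].
#' @param map optional [SiteClassMap-class] supplying the column mask.
#' @return a [SnpMatrix-class] with positions in genomic bp.
#' @export
snpMatrixFromAlignment <- function(alignment, map = NULL) {
  ing <- ingroupMatrix(alignment)
  og <- outgroupSeq(alignment)
  n <- nrow(ing)
  L <- ncol(ing)
  masked <- if (is.null(map)) colSums(ing == "N" | ing == "-") > 0L
            else map@masked
  bases <- c("A", "C", "G", "T")
  pos <- integer(0); cols <- list(); polarized <- logical(0)
  for (j in which(!masked)) {
    col <- ing[, j]
    if (any(!col %in% bases)) next
    al <- unique(col)
    if (length(al) != 2L) next
    cnt <- c(sum(col == al[1L]), sum(col == al[2L]))
    ogb <- if (is.null(og)) NA_character_ else og[j]
    if (!is.na(ogb) && ogb %in% al) {
      derived <- al[al != ogb]
      v <- as.integer(col == derived)
      pol <- TRUE
    } else {
      minor <- al[which.min(cnt)]
      v <- as.integer(col == minor)
      pol <- FALSE
    }
    pos <- c(pos, j)
    cols <- c(cols, list(v))
    polarized <- c(polarized, pol)
  }
  mat <- if (length(cols)) do.call(cbind, cols) else matrix(0L, n, 0L)
  new("SnpMatrix",
      positions = as.numeric(pos + alignment@regionOffset - 1L),
      mat = mat, polarized = polarized)
}

#' @describeIn snpMatrixFromAlignment build a SnpMatrix from a coalescent
#'   replicate (simulated with `matrices = TRUE`); all SNPs are polarized
#'   since the simulation knows the ancestral state.
#' @param rep a replicate from [simulateNeutral()] or [simulateFixedS()].
#' @param L region length in bp used to scale replicate positions.
#' @export
snpMatrixFromReplicate <- function(rep, L) {
  pos <- rep$positions
  if (max(pos, 1) <= 1) pos <- pos * L
  keep <- which(!duplicated(pos))
  keep <- keep[order(pos[keep])]
  cs <- colSums(rep$mat)
  keep <- keep[cs[keep] > 0 & cs[keep] < nrow(rep$mat)]
  new("SnpMatrix", positions = pos[keep],
      mat = rep$mat[, keep, drop = FALSE],
      polarized = rep(TRUE, length(keep)))
}

setMethod("show", "SnpMatrix", function(object) {
  cat("SnpMatrix:", nrow(object@mat), "haplotypes x",
      length(object@positions), "SNPs (",
      sum(object@polarized), "polarized )\n")
})

#' Background site frequency spectrum of a SNP set
#'
#' Estimates the probability vector over derived-allele classes 1..n-1
#' from all scanned SNPs (the composite null model of the CLR scan).
#' Polarized SNPs contribute to their derived class; folded SNPs split
#' their weight equally between the two complementary classes.
#'
#' @param snps a [SnpMatrix-class].
#' @param includeFixed reserved flag for an extra fixed-derived class
#'   (excluded by default).
#' @return numeric probability vector of length n-1 (sums to 1), with
#'   attribute `n`.
#' @export
backgroundSfs <- function(snps, includeFixed = FALSE) {
  n <- nrow(snps@mat)
  counts <- colSums(snps@mat)
  q <- numeric(n - 1L)
  for (s in seq_along(counts)) {
    j <- counts[s]
    if (snps@polarized[s]) {
      q[j] <- q[j] + 1
    } else {
      q[j] <- q[j] + 0.5
      q[n - j] <- q[n - j] + 0.5
    }
  }
  if (sum(q) == 0) stop("no SNPs to estimate a background spectrum from")
  q <- q / sum(q)
  attr(q, "n") <- n
  q
}

#' Sweep-transformed site frequency spectrum
#'
#' Distorts a background spectrum by a selective sweep at distance `d`
#' from the scanned site with intensity `alpha`: each of the n sampled
#' lineages escapes the sweep independently with probability
#' p_e = 1 - exp(-alpha d); the B escapees plus one lineage representing
#' the common swept ancestor form an effective sample of B+1 drawn from
#' the background spectrum (hypergeometric downsampling from n to B+1),
#' and the ancestor's allele is replicated across the n-B swept lineages.
#' The result is renormalized over the observable polymorphic classes
#' 1..n-1 (its attribute `polymorphicMass` retains the pre-normalization
#' polymorphic probability).
#'
#' @param background probability vector over classes 1..n-1 (e.g. from
#'   [backgroundSfs()]).
#' @param alpha sweep intensity (per bp; `Inf` gives the background back).
#' @param d distance from the proposed sweep site in bp.
#' @param n sample size.
#' @param pe optionally supply the escape probability directly (overrides
#'   `alpha`/`d`).
#' @return probability vector over classes 1..n-1.
#' @export
sweepTransformedSfs <- function(background, alpha, d, n, pe = NULL) {
  stopifnot(length(background) == n - 1L)
  if (is.null(pe)) {
    stopifnot(alpha >= 0, d >= 0)
    pe <- 1 - exp(-alpha * d)
  }
  stopifnot(pe >= 0, pe <= 1)
  r <- numeric(n + 1L)  # counts 0..n
  wB <- dbinom(0:n, n, pe)
  for (B in 0:n) {
    w <- wB[B + 1L]
    if (w == 0) next
    if (B == n) {  # every lineage escaped: spectrum unchanged
      r[2:n] <- r[2:n] + w * background
      next
    }
    m <- B + 1L
    for (j in seq_len(n - 1L)) {
      qj <- background[j]
      if (qj == 0) next
      k <- 0:m
      h <- dhyper(k, j, n - j, m)
      pd <- k / m  # probability the collapsed lineage carries the derived allele
      derivedFinal <- (k - 1L) + (n - B)
      ancestralFinal <- k
      add <- w * qj * h
      sel <- h > 0 & k > 0
      r[derivedFinal[sel] + 1L] <- r[derivedFinal[sel] + 1L] +
        add[sel] * pd[sel]
      r[ancestralFinal + 1L] <- r[ancestralFinal + 1L] + add * (1 - pd)
    }
  }
  poly <- r[2:n]
  mass <- sum(poly)
  out <- if (mass > 0) poly / mass else poly
  attr(out, "polymorphicMass") <- mass
  out
}

# Precompute log sweep-spectrum lookup tables over a grid of alpha*d
# values: rows = bins of x = alpha*d (log-spaced, last row = x -> Inf,
# i.e. the background itself), columns = unfolded classes 1..n-1 followed
# by folded classes 1..floor(n/2).
.sweepTables <- function(background, n, nBins = 96L,
                         xRange = c(1e-6, 25)) {
  xs <- exp(seq(log(xRange[1L]), log(xRange[2L]), length.out = nBins))
  nf <- n %/% 2L
  tab <- matrix(NA_real_, nBins + 1L, (n - 1L) + nf)
  for (b in seq_len(nBins)) {
    p <- sweepTransformedSfs(background, alpha = 1, d = xs[b], n = n)
    fold <- vapply(seq_len(nf), function(i)
      if (i < n - i) p[i] + p[n - i] else p[i], numeric(1))
    tab[b, ] <- c(p, fold)
  }
  bg <- as.numeric(background)
  foldBg <- vapply(seq_len(nf), function(i)
    if (i < n - i) bg[i] + bg[n - i] else bg[i], numeric(1))
  tab[nBins + 1L, ] <- c(bg, foldBg)
  list(x = xs, logTab = log(pmax(tab, 1e-300)), n = n, nFold = nf)
}

.binOf <- function(x, xs) {
  # nearest log-spaced bin; values beyond the last bin map to background
  nb <- length(xs)
  b <- findInterval(x, c(-Inf, sqrt(xs[-nb] * xs[-1L]), Inf))
  b[x > xs[nb]] <- nb + 1L
  b
}

#' Composite-likelihood-ratio sweep scan
#'
#' At each of `grid` evenly spaced positions x spanning the SNP range,
#' computes CLR(x) = 2 (max over alpha of the summed log sweep-model SNP
#' probabilities at distance |pos_s - x|, minus the summed log background
#' probabilities), where the sweep model comes from
#' [sweepTransformedSfs()] and folded SNPs contribute the summed
#' probability of the two complementary classes.  alpha is maximized over
#' a fixed logarithmic grid that includes an effectively neutral value, so
#' CLR >= 0 everywhere up to lookup resolution.
#'
#' @param snps a [SnpMatrix-class] with at least 2 SNPs.
#' @param background optional background spectrum; estimated from `snps`
#'   (including the focal region -- the composite approach) when omitted.
#' @param grid number of grid points (default 125).
#' @param nAlpha number of finite alpha grid values (default 40).
#' @param peRange escape-probability range at the region half-width that
#'   anchors the alpha grid.
#' @return a [ScanTrack-class] with per-position CLR and fitted alpha.
#' @export
clrScan <- function(snps, background = NULL, grid = 125L, nAlpha = 40L,
                    peRange = c(1e-4, 0.9999)) {
  S <- length(snps@positions)
  if (S < 2L) stop("CLR scan requires at least 2 SNPs")
  n <- nrow(snps@mat)
  if (is.null(background)) background <- backgroundSfs(snps)
  halfw <- max((max(snps@positions) - min(snps@positions)) / 2, 1)
  alphas <- c(-log(1 - exp(seq(log(peRange[1L]), log(peRange[2L]),
                               length.out = nAlpha)) *
                     (1 - 1e-12)) / halfw, Inf)
  tabs <- .sweepTables(background, n)
  counts <- colSums(snps@mat)
  classIdx <- ifelse(snps@polarized, counts,
                     (n - 1L) + pmin(counts, n - counts))
  gpos <- seq(min(snps@positions), max(snps@positions), length.out = grid)
  nb <- length(tabs$x)
  bgLog <- sum(tabs$logTab[nb + 1L, classIdx])
  clr <- numeric(grid)
  aHat <- numeric(grid)
  nA <- length(alphas)
  for (g in seq_len(grid)) {
    dsnp <- abs(snps@positions - gpos[g])
    ll <- vapply(seq_len(nA), function(ai) {
      a <- alphas[ai]
      bins <- if (is.finite(a)) .binOf(a * dsnp, tabs$x)
              else rep(nb + 1L, S)
      sum(tabs$logTab[cbind(bins, classIdx)])
    }, numeric(1))
    bestA <- which.max(ll)
    clr[g] <- 2 * (ll[bestA] - bgLog)
    aHat[g] <- alphas[bestA]
  }
  new("ScanTrack", statName = "CLR", position = gpos, stat = clr,
      alphaHat = aHat, cutoff = NA_real_, cutoffQuantile = NA_real_,
      replicates = NA_integer_, seed = NA_integer_)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' r^2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B)) from haplotype
#' counts; invariant to allele relabeling at either SNP.  Undefined (NA)
#' when either SNP is monomorphic.
#'
#' @param a,b 0/1 vectors over the same haplotype set.
#' @return r-squared in [0, 1].
#' @export
rSquared <- function(a, b) {
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  pAB <- mean(a * b)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

.r2Matrix <- function(mat) {
  r <- suppressWarnings(stats::cor(mat))^2
  r[is.na(r)] <- 0
  r
}

#' The omega linkage-disequilibrium statistic at one position
#'
#' Splits the SNPs flanking `position` into a left set of l SNPs and a
#' right set of r SNPs and computes
#' omega = [ (C(l,2)+C(r,2))^-1 (sum r^2 within left + within right) ] /
#'         [ (l r)^-1 sum r^2 across ],
#' maximized over admissible window extents: every SNP within `minwin` of
#' the position is always included and each flank may extend SNP by SNP up
#' to `maxwin`; at least 2 SNPs are required per flank.  A zero
#' cross-flank denominator yields +Inf (reported as a sentinel); ties take
#' the leftmost (smallest) split.
#'
#' @param position focal position in bp.
#' @param snps a [SnpMatrix-class].
#' @param minwin minimum window extent per flank in bp (default 1000).
#' @param maxwin maximum window extent per flank in bp (default 2000).
#' @param r2 optional precomputed full r-squared matrix of `snps`.
#' @return list with `omega` (NA when a flank has < 2 SNPs in `maxwin`),
#'   `nLeft`, `nRight`.
#' @export
omegaAt <- function(position, snps, minwin = 1000, maxwin = 2000,
                    r2 = NULL) {
  pos <- snps@positions
  leftIdx <- which(pos < position & pos >= position - maxwin)
  rightIdx <- which(pos >= position & pos <= position + maxwin)
  if (length(leftIdx) < 2L || length(rightIdx) < 2L)
    return(list(omega = NA_real_, nLeft = NA_integer_,
                nRight = NA_integer_))
  leftIdx <- leftIdx[order(position - pos[leftIdx])]   # nearest first
  rightIdx <- rightIdx[order(pos[rightIdx] - position)]
  if (is.null(r2)) r2 <- .r2Matrix(snps@mat)
  RL <- r2[leftIdx, leftIdx, drop = FALSE]
  RR <- r2[rightIdx, rightIdx, drop = FALSE]
  RX <- r2[leftIdx, rightIdx, drop = FALSE]
  nl <- length(leftIdx); nr <- length(rightIdx)
  WL <- cumsum(vapply(seq_len(nl), function(i)
    if (i == 1L) 0 else sum(RL[i, seq_len(i - 1L)]), numeric(1)))
  WR <- cumsum(vapply(seq_len(nr), function(i)
    if (i == 1L) 0 else sum(RR[i, seq_len(i - 1L)]), numeric(1)))
  PX <- apply(RX, 2L, cumsum)
  if (is.null(dim(PX))) PX <- matrix(PX, nrow = nl)
  PX <- t(apply(PX, 1L, cumsum))
  if (is.null(dim(PX))) PX <- matrix(PX, ncol = nr)
  iMin <- max(2L, sum(position - pos[leftIdx] <= minwin))
  kMin <- max(2L, sum(pos[rightIdx] - position <= minwin))
  best <- -Inf; bi <- NA_integer_; bk <- NA_integer_
  for (i in iMin:nl) {
    for (k in kMin:nr) {
      within <- (WL[i] + WR[k]) / (choose(i, 2) + choose(k, 2))
      cross <- PX[i, k] / (i * k)
      om <- if (cross == 0) {
        if (within > 0) Inf else NA_real_
      } else within / cross
      if (!is.na(om) && om > best) { best <- om; bi <- i; bk <- k }
    }
  }
  if (!is.finite(best) && is.na(bi))
    return(list(omega = NA_real_, nLeft = NA_integer_,
                nRight = NA_integer_))
  list(omega = best, nLeft = bi, nRight = bk)
}

#' Omega sweep scan over a positional grid
#'
#' Evaluates [omegaAt()] on `grid` evenly spaced positions spanning the
#' SNP range.  Grid points with insufficient flanking SNPs are recorded
#' as NA rather than failing.
#'
#' @inheritParams omegaAt
#' @param grid number of grid points (default 125).
#' @return a [ScanTrack-class].
#' @export
omegaScan <- function(snps, grid = 125L, minwin = 1000, maxwin = 2000) {
  S <- length(snps@positions)
  if (S < 4L) stop("omega scan requires at least 4 SNPs")
  r2 <- .r2Matrix(snps@mat)
  gpos <- seq(min(snps@positions), max(snps@positions), length.out = grid)
  om <- vapply(gpos, function(x)
    omegaAt(x, snps, minwin, maxwin, r2 = r2)$omega, numeric(1))
  new("ScanTrack", statName = "omega", position = gpos, stat = om,
      alphaHat = numeric(0), cutoff = NA_real_,
      cutoffQuantile = NA_real_, replicates = NA_integer_,
      seed = NA_integer_)
}

#' @describeIn omegaScan maximum of a scan track and its position.
#' @param track a `ScanTrack`.
#' @export
scanMax <- function(track) {
  ok <- which(is.finite(track@stat) | is.infinite(track@stat))
  vals <- track@stat
  vals[is.na(vals)] <- -Inf
  i <- which.max(vals)
  list(position = track@position[i], value = track@stat[i])
}

#' Attach a simulated significance cutoff to a scan track
#'
#' Simulates neutral replicate regions (fixed-S genealogies without
#' recombination, or the standard coalescent with recombination when
#' `rho > 0`), applies the matching scan to each, and stores the empirical
#' quantile of the scan maximum in the track.
#'
#' @param track a [ScanTrack-class] from [clrScan()] or [omegaScan()].
#' @param snps the observed [SnpMatrix-class] (supplies n, S and the span).
#' @param reps null replicates (>= 100 recommended for a 1% cutoff).
#' @param seed integer seed.
#' @param rho per-region scaled recombination rate for the null.
#' @param quantile cutoff quantile (default 0.99, the upper 1% point).
#' @param background background spectrum reused for null CLR scans
#'   (defaults to the observed background, the composite null model).
#' @param grid grid size for null scans (smaller than the data scan is
#'   acceptable for a maximum statistic; default 50 to bound runtime).
#' @param minwin,maxwin omega window parameters.
#' @return the track with `cutoff`, `cutoffQuantile`, `replicates`,
#'   `seed` filled in.
#' @export
scanCutoff <- function(track, snps, reps = 10000L, seed = 1L, rho = 0,
                       quantile = 0.99, background = NULL, grid = 50L,
                       minwin = 1000, maxwin = 2000) {
  n <- nrow(snps@mat)
  S <- length(snps@positions)
  L <- max(snps@positions) - min(snps@positions)
  if (is.null(background) && track@statName == "CLR")
    background <- backgroundSfs(snps)
  statFn <- function(rep) {
    sm <- snpMatrixFromReplicate(rep, L)
    if (length(sm@positions) < 4L) return(NA_real_)
    tr <- if (track@statName == "CLR")
      clrScan(sm, background = background, grid = grid)
    else omegaScan(sm, grid = grid, minwin = minwin, maxwin = maxwin)
    v <- scanMax(tr)$value
    if (is.infinite(v)) .Machine$double.xmax else v
  }
  simFn <- if (rho > 0) {
    theta <- S / .harmonic(n - 1)  # Watterson-matched mutation rate
    function(i) simulateNeutral(n, theta, rho = rho, L = L, reps = 1L,
                                matrices = TRUE)[[1L]]
  } else {
    function(i) simulateFixedS(n, S, reps = 1L, matrices = TRUE)[[1L]]
  }
  nc <- nullCutoff(statFn, simFn, reps = reps, quantile = quantile,
                   seed = seed)
  track@cutoff <- as.numeric(nc$cutoff)
  track@cutoffQuantile <- quantile
  track@replicates <- as.integer(reps)
  track@seed <- as.integer(seed)
  track
}

setMethod("show", "ScanTrack", function(object) {
  cat("ScanTrack [", object@statName, "]: ", length(object@position),
      " grid points\n", sep = "")
  mx <- scanMax(object)
  cat("  max =", format(mx$value, digits = 4), "at position",
      format(mx$position, digits = 8), "\n")
  if (!is.na(object@cutoff))
    cat("  simulated ", 100 * (1 - object@cutoffQuantile),
        "% cutoff = ", format(object@cutoff, digits = 4),
        " (", object@replicates, " replicates, seed ", object@seed,
        ")\n", sep = "")
})
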