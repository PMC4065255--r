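#' @importFrom stats rexp rpois runif rbinom quantile optim uniroot pchisq
#'   rmultinom dbinom dhyper phyper
NULL

# One Kingman genealogy for n samples: returns the 2n-2 non-root branches
# as (subtended leaf count, branch length), plus the leaf sets when
# `sets = TRUE`.  Time is scaled in units of 2N generations, so the
# coalescence rate with k lineages is k(k-1)/2.
.kingmanBranches <- function(n, sets = FALSE) {
  sizes <- rep(1L, n)
  birth <- rep(0, n)
  leafSets <- if (sets) as.list(seq_len(n)) else NULL
  bSize <- integer(2L * n - 2L)
  bLen <- numeric(2L * n - 2L)
  bSets <- if (sets) vector("list", 2L * n - 2L) else NULL
  t <- 0
  out <- 0L
  for (k in n:2) {
    t <- t + rexp(1L, k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    i <- pair[1L]; j <- pair[2L]
    for (idx in c(i, j)) {
      out <- out + 1L
      bSize[out] <- sizes[idx]
      bLen[out] <- t - birth[idx]
      if (sets) bSets[[out]] <- leafSets[[idx]]
    }
    sizes[i] <- sizes[i] + sizes[j]
    birth[i] <- t
    if (sets) leafSets[[i]] <- c(leafSets[[i]], leafSets[[j]])
    sizes <- sizes[-j]
    birth <- birth[-j]
    if (sets) leafSets[[j]] <- NULL
  }
  list(size = bSize, length = bLen, sets = bSets,
       totalLength = sum(bLen))
}

#' Simulate neutral samples conditioning on the number of segregating sites
#'
#' Draws neutral Kingman genealogies (no recombination) and places exactly
#' S mutations on branches with probability proportional to branch length.
#' This is the engine behind the empirical null distributions of Tajima's D
#' and normalized Fay-Wu H ("fixed-S" conditioning).
#'
#' @param n sample size (chromosomes, >= 2).
#' @param S number of segregating sites to place per replicate.
#' @param reps number of replicates.
#' @param seed optional integer seed (set before simulation when given).
#' @param matrices if TRUE, also return the n x S binary haplotype matrix
#'   for every replicate (slower; derived allele = 1).
#' @return list of replicates; each has `counts` (derived allele count per
#'   mutation, length S), `positions` (uniform on (0, 1]) and, when
#'   requested, `mat`.
#' @export
simulateFixedS <- function(n, S, reps = 1L, seed = NULL, matrices = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 2, S >= 0, reps >= 1)
  lapply(seq_len(reps), function(r) {
    g <- .kingmanBranches(n, sets = matrices)
    if (S == 0L) {
      rep <- list(counts = integer(0), positions = numeric(0))
      if (matrices) rep$mat <- matrix(0L, n, 0L)
      return(rep)
    }
    hit <- sample.int(length(g$length), S, replace = TRUE, prob = g$length)
    rep <- list(counts = g$size[hit], positions = sort(runif(S)))
    if (matrices) {
      mat <- matrix(0L, n, S)
      for (s in seq_len(S)) mat[g$sets[[hit[s]]], s] <- 1L
      rep$mat <- mat
    }
    rep
  })
}

#' Simulate neutral samples under the standard coalescent
#'
#' Standard neutral equilibrium coalescent with per-locus scaled mutation
#' rate theta = 4N mu (mutation number Poisson on total branch length) and
#' optional population recombination rate rho = 4Nr across the locus
#' (Hudson's ancestral recombination graph).  Each replicate reports the
#' segregating mutations as derived-allele carrier sets with positions
#' uniform on (0, L].
#'
#' @param n sample size.
#' @param theta per-locus scaled mutation rate.
#' @param rho per-locus scaled recombination rate (0 = single genealogy).
#' @param L locus length in bp (positions are reported on (0, L]).
#' @param reps replicates.
#' @param seed optional integer seed.
#' @param matrices if TRUE attach the n x S binary matrix per replicate.
#' @return list of replicates with `positions`, `counts`, `carriers` (list
#'   of integer vectors) and optionally `mat`.
#' @export
simulateNeutral <- function(n, theta, rho = 0, L = 1L, reps = 1L,
                            seed = NULL, matrices = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 2, theta >= 0, rho >= 0, reps >= 1)
  lapply(seq_len(reps), function(r) {
    muts <- if (rho == 0) {
      g <- .kingmanBranches(n, sets = TRUE)
      S <- rpois(1L, theta * g$totalLength / 2)
      if (S > 0L) {
        hit <- sample.int(length(g$length), S, replace = TRUE,
                          prob = g$length)
        list(pos = runif(S), carriers = g$sets[hit])
      } else list(pos = numeric(0), carriers = list())
    } else {
      .argMutations(n, theta, rho)
    }
    o <- order(muts$pos)
    pos <- muts$pos[o] * L
    carriers <- muts$carriers[o]
    rep <- list(positions = pos,
                counts = lengths(carriers),
                carriers = carriers)
    if (matrices) {
      mat <- matrix(0L, n, length(pos))
      for (s in seq_along(pos)) mat[carriers[[s]], s] <- 1L
      rep$mat <- mat
    }
    rep
  })
}

# Hudson-style ancestral recombination graph over the unit interval,
# emitting mutations directly as competing exponential events.  Each
# lineage carries a set of ancestral segments, each tagged with the sample
# set it subtends; segments that reach the full sample size are pruned
# (their mutations would be invisible).  Rates: coalescence k(k-1)/2,
# recombination (rho/2) * breakable span, mutation (theta/2) * ancestral
# measure.
.argMutations <- function(n, theta, rho) {
  lineages <- lapply(seq_len(n), function(i)
    list(l = 0, r = 1, sets = list(i)))
  mutPos <- numeric(0)
  mutCar <- list()
  .measure <- function(lin) sum(lin$r - lin$l)
  .span <- function(lin) if (length(lin$l)) max(lin$r) - min(lin$l) else 0
  repeat {
    k <- length(lineages)
    if (k == 0L) break
    meas <- vapply(lineages, .measure, numeric(1))
    spans <- vapply(lineages, .span, numeric(1))
    rateC <- if (k >= 2L) k * (k - 1) / 2 else 0
    rateR <- rho / 2 * sum(spans)
    rateM <- theta / 2 * sum(meas)
    total <- rateC + rateR + rateM
    if (total == 0) break
    ev <- runif(1L) * total
    if (ev < rateM) {
      li <- sample.int(k, 1L, prob = meas)
      lin <- lineages[[li]]
      segLen <- lin$r - lin$l
      si <- sample.int(length(segLen), 1L, prob = segLen)
      mutPos <- c(mutPos, runif(1L, lin$l[si], lin$r[si]))
      mutCar <- c(mutCar, list(lin$sets[[si]]))
    } else if (ev < rateM + rateR) {
      li <- sample.int(k, 1L, prob = spans)
      lin <- lineages[[li]]
      bp <- runif(1L, min(lin$l), max(lin$r))
      left <- .clipLineage(lin, -Inf, bp)
      right <- .clipLineage(lin, bp, Inf)
      lineages[[li]] <- left
      lineages[[length(lineages) + 1L]] <- right
    } else {
      pair <- sample.int(k, 2L)
      merged <- .mergeLineages(lineages[[pair[1L]]], lineages[[pair[2L]]], n)
      lineages[[pair[1L]]] <- merged
      lineages[[pair[2L]]] <- NULL
    }
    lineages <- Filter(function(x) length(x$l) > 0L, lineages)
  }
  list(pos = mutPos, carriers = mutCar)
}

.clipLineage <- function(lin, lo, hi) {
  keep <- lin$r > lo & lin$l < hi
  l <- pmax(lin$l[keep], lo)
  r <- pmin(lin$r[keep], hi)
  list(l = l, r = r, sets = lin$sets[keep])
}

.mergeLineages <- function(a, b, n) {
  pts <- sort(unique(c(a$l, a$r, b$l, b$r)))
  if (length(pts) < 2L) return(list(l = numeric(0), r = numeric(0),
                                    sets = list()))
  lo <- pts[-length(pts)]
  hi <- pts[-1L]
  outL <- numeric(0); outR <- numeric(0); outS <- list()
  for (i in seq_along(lo)) {
    ia <- which(a$l < hi[i] & a$r > lo[i])
    ib <- which(b$l < hi[i] & b$r > lo[i])
    set <- NULL
    if (length(ia)) set <- a$sets[[ia[1L]]]
    if (length(ib)) set <- union(set, b$sets[[ib[1L]]])
    if (is.null(set) || length(set) == n) next  # gap or MRCA reached
    m <- length(outL)
    if (m > 0L && outR[m] == lo[i] && setequal(outS[[m]], set)) {
      outR[m] <- hi[i]  # compact identical adjacent segments
    } else {
      outL <- c(outL, lo[i]); outR <- c(outR, hi[i])
      outS <- c(outS, list(set))
    }
  }
  list(l = outL, r = outR, sets = outS)
}

#' Empirical null cutoff for a scan or test statistic
#'
#' Runs a replicate generator, applies a statistic to each replicate, and
#' returns the empirical quantile -- the machinery behind simulated 1%
#' cutoffs and empirical P values.  Fully deterministic given `seed`.
#'
#' @param statFn function mapping one replicate to a scalar.
#' @param simFn function(i) producing replicate i.
#' @param reps number of replicates.
#' @param quantile quantile to report (e.g. 0.99 for an upper 1% cutoff).
#' @param seed optional integer seed set before simulation.
#' @return list with `cutoff`, `quantile`, `reps`, `seed` and the sorted
#'   null `values`.
#' @export
nullCutoff <- function(statFn, simFn, reps, quantile = 0.99, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (reps < 100 && (quantile <= 0.01 || quantile >= 0.99))
    warning("fewer than 100 replicates for a 1% cutoff; the estimate ",
            "will be unstable")
  vals <- vapply(seq_len(reps), function(i) statFn(simFn(i)), numeric(1))
  list(cutoff = unname(stats::quantile(vals, quantile, type = 1,
                                       na.rm = TRUE)),
       quantile = quantile, reps = as.integer(reps),
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
       values = sort(vals))
}

#' Empirical P value with the +1 correction
#'
#' P = (r + 1) / (reps + 1) where r is the number of null replicates at
#' least as extreme as the observation, so simulated P values are never 0.
#'
#' @param r number of replicates at least as extreme as observed.
#' @param reps total replicates.
#' @return empirical P in (0, 1].
#' @export
empiricalP <- function(r, reps) (r + 1) / (reps + 1)

#' Write replicates in ms-compatible text format
#'
#' Serialises replicates from [simulateFixedS()] or [simulateNeutral()]
#' (run with `matrices = TRUE`) in the text layout of Hudson's ms:
#' `//`, `segsites:`, `positions:` and one 0/1 haplotype string per
#' sample, for interoperability with external tools.
#'
#' @param replicates list of replicates carrying `mat` and `positions`.
#' @param n sample size.
#' @param header command-line style header string.
#' @return character vector of output lines.
#' @export
msFormat <- function(replicates, n, header = "ms") {
  out <- c(header, paste(sample.int(2^15, 3L), collapse = " "))
  for (rep in replicates) {
    if (is.null(rep$mat))
      stop("msFormat needs replicates simulated with matrices = TRUE")
    S <- ncol(rep$mat)
    out <- c(out, "", "//", paste("segsites:", S))
    if (S > 0L) {
      posLine <- paste("positions:",
                       paste(sprintf("%.6f", rep$positions /
                                       max(rep$positions, 1)), collapse = " "))
      out <- c(out, posLine,
               apply(rep$mat, 1L, paste, collapse = ""))
    }
  }
  out
}
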