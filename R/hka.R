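#' Assemble per-locus HKA input data
#'
#' The HKA framework consumes, for every locus, the sample size, the
#' number of silent sites surveyed, the silent segregating-site count and
#' the mean pairwise silent divergence to the outgroup (in counts).
#'
#' @param locus character vector of locus ids.
#' @param n integer vector, chromosomes sampled per locus.
#' @param L numeric vector, silent sites per locus (> 0).
#' @param S numeric vector, silent segregating sites (>= 0).
#' @param D numeric vector, mean pairwise silent divergence counts (>= 0).
#' @return data.frame with one row per locus.
#' @export
hkaLoci <- function(locus, n, L, S, D) {
  stopifnot(all(L > 0), all(S >= 0), all(D >= 0), all(n >= 2))
  data.frame(locus = as.character(locus), n = as.integer(n),
             L = as.numeric(L), S = as.numeric(S), D = as.numeric(D),
             stringsAsFactors = FALSE)
}

#' @describeIn hkaLoci read a TSV of HKA locus rows (columns locus, n, L,
#'   S, D).
#' @param path path to the TSV file.
#' @export
readHkaTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "n", "L", "S", "D")
  if (!all(need %in% names(df)))
    stop("HKA table must have columns: ", paste(need, collapse = ", "))
  hkaLoci(df$locus, df$n, df$L, df$S, df$D)
}

# moment fit of the neutral HKA model: theta_i(T) profiles out exactly,
# and T solves sum(S) = sum(theta_i L_i a_i)
.hkaMomentFit <- function(loci) {
  a <- vapply(loci$n, function(n) .harmonic(n - 1), numeric(1))
  if (sum(loci$S) + sum(loci$D) == 0)
    stop("degenerate HKA system: all polymorphism and divergence zero")
  thetaOf <- function(T) (loci$S + loci$D) / (loci$L * (a + T + 1))
  f <- function(T) sum(thetaOf(T) * loci$L * a) - sum(loci$S)
  if (sum(loci$S) == 0) {
    T <- 1e6  # no polymorphism anywhere: T unbounded, use sentinel
  } else if (f(1e-9) <= 0) {
    T <- 1e-9
  } else {
    T <- uniroot(f, c(1e-9, 1e9), tol = 1e-10)$root
  }
  list(T = T, theta = thetaOf(T), a = a)
}

# HKA goodness-of-fit statistic at fitted (theta, T)
.hkaX2 <- function(loci, fit) {
  a <- fit$a
  b <- vapply(loci$n, function(n) .harmonic2(n - 1), numeric(1))
  tl <- fit$theta * loci$L
  eS <- tl * a
  vS <- tl * a + tl^2 * b
  eD <- tl * (fit$T + 1)
  vD <- tl * (fit$T + 1) + tl^2
  sum((loci$S - eS)^2 / vS + (loci$D - eD)^2 / vD)
}

#' Pairwise (or multilocus) HKA test
#'
#' Tests proportionality of within-species polymorphism to between-species
#' divergence across loci.  Moment estimators of the per-locus mutation
#' parameters and the divergence time solve sum(S_i) = sum(theta_i L_i
#' a_i) and D_i = theta_i L_i (T+1); the goodness-of-fit statistic is
#' X^2 = sum_i (S_i - E S_i)^2 / Var S_i + (D_i - E D_i)^2 / Var D_i with
#' Var S_i = theta L a_i + (theta L)^2 b_i and Var D_i = theta L (T+1) +
#' (theta L)^2.  Significance comes from neutral coalescent simulation
#' under the fitted null (each replicate re-fitted before computing its
#' X^2), with the +1 empirical-P correction.
#'
#' @param loci data.frame from [hkaLoci()] (two rows for the classic
#'   pairwise test; more are accepted).
#' @param reps simulation replicates (published-scale default 10000).
#' @param seed integer seed.
#' @return list with `X2`, `P`, the fitted `T` and per-locus `theta`,
#'   `reps` and `seed`.
#' @export
pairwiseHka <- function(loci, reps = 10000L, seed = 1L) {
  stopifnot(nrow(loci) >= 2L)
  fit <- .hkaMomentFit(loci)
  obs <- .hkaX2(loci, fit)
  set.seed(seed)
  tl <- fit$theta * loci$L
  nulls <- vapply(seq_len(reps), function(r) {
    Ssim <- vapply(seq_len(nrow(loci)), function(i) {
      k <- loci$n[i]:2
      ttot <- sum(k * rexp(length(k), k * (k - 1) / 2))
      rpois(1L, tl[i] * ttot / 2)
    }, numeric(1))
    Dsim <- rpois(nrow(loci), tl * (fit$T + rexp(nrow(loci))))
    sim <- loci
    sim$S <- Ssim; sim$D <- Dsim
    if (sum(Ssim) + sum(Dsim) == 0) return(0)
    .hkaX2(sim, .hkaMomentFit(sim))
  }, numeric(1))
  r <- sum(nulls >= obs)
  list(X2 = obs, P = empiricalP(r, reps), T = fit$T, theta = fit$theta,
       reps = as.integer(reps), seed = as.integer(seed))
}

# Poisson log-likelihood of the ML-HKA model at (T, k) with theta profiled
# out exactly: theta_i = (S_i + D_i) / (L_i (k_i a_i + T + 1))
.mlhkaLogLik <- function(loci, T, k, focalFlag) {
  a <- vapply(loci$n, function(n) .harmonic(n - 1), numeric(1))
  ki <- ifelse(focalFlag, k, 1)
  theta <- (loci$S + loci$D) / (loci$L * (ki * a + T + 1))
  lamS <- pmax(ki * theta * loci$L * a, 1e-300)
  lamD <- pmax(theta * loci$L * (T + 1), 1e-300)
  # continuous Poisson log-density so fractional (weighted) counts work
  lp <- function(x, lam) x * log(lam) - lam - lgamma(x + 1)
  ll <- sum(lp(loci$S, lamS) + lp(loci$D, lamD))
  attr(ll, "theta") <- theta
  ll
}

#' Maximum-likelihood HKA fit
#'
#' Fits the multilocus polymorphism/divergence model by maximizing the
#' Poisson likelihood L = sum_i log Pois(S_i; k_i theta_i L_i a_i) +
#' log Pois(D_i; theta_i L_i (T+1)), where k_i = 1 except at focal loci
#' under the selection model, which share one free selection parameter k
#' (bounded to [1e-4, 1e2]).  Per-locus theta is profiled out in closed
#' form; the remaining 1- or 2-dimensional problem is solved by bounded
#' numerical search from multiple independent starting points, which must
#' agree within tolerance.
#'
#' @param loci data.frame from [hkaLoci()] (>= 2 loci).
#' @param focal character vector of focal locus ids (required when
#'   `selection = TRUE`).
#' @param selection logical; free the selection parameter at focal loci.
#' @param restarts number of independent optimizer starts (default 3).
#' @param tol agreement tolerance between restart optima (log-likelihood
#'   units).
#' @return a [MlHkaResult-class].
#' @export
mlhkaFit <- function(loci, focal = character(), selection = FALSE,
                     restarts = 3L, tol = 1e-4) {
  stopifnot(nrow(loci) >= 2L)
  if (selection && !length(focal))
    stop("selection model requires a non-empty focal locus set")
  if (length(focal) && !all(focal %in% loci$locus))
    stop("unknown focal loci: ",
         paste(setdiff(focal, loci$locus), collapse = ", "))
  stopifnot(restarts >= 1L, restarts <= 5L)
  focalFlag <- loci$locus %in% focal
  mom <- .hkaMomentFit(loci)
  Tstarts <- pmax(mom$T, 1e-3) * c(1, 0.5, 2, 0.1, 10)[seq_len(restarts)]
  optima <- lapply(seq_len(restarts), function(j) {
    if (!selection) {
      o <- stats::optimize(function(lt)
        -.mlhkaLogLik(loci, exp(lt), 1, focalFlag),
        interval = log(c(1e-6, 1e7)), tol = 1e-10)
      list(T = exp(o$minimum), k = 1, value = -o$objective)
    } else {
      st <- c(log(Tstarts[j]), log(c(1, 0.3, 3, 0.05, 20)[j]))
      o <- stats::optim(st, function(p)
        -.mlhkaLogLik(loci, exp(p[1L]), exp(p[2L]), focalFlag),
        method = "L-BFGS-B",
        lower = c(log(1e-6), log(1e-4)),
        upper = c(log(1e7), log(1e2)),
        control = list(factr = 1e4))
      list(T = exp(o$par[1L]), k = exp(o$par[2L]), value = -o$value)
    }
  })
  vals <- vapply(optima, `[[`, numeric(1), "value")
  best <- optima[[which.max(vals)]]
  agreeTol <- max(tol, 1e-6 * abs(max(vals)))
  if (selection && restarts >= 2L &&
      sum(max(vals) - vals <= agreeTol) < 2L)
    stop("ML-HKA restarts did not converge to a common optimum; ",
         "log-likelihoods: ", paste(round(vals, 4), collapse = ", "))
  ll <- .mlhkaLogLik(loci, best$T, best$k, focalFlag)
  new("MlHkaResult",
      model = if (selection) "selection" else "no-selection",
      theta = stats::setNames(attr(ll, "theta"), loci$locus),
      T = best$T, k = best$k, focal = as.character(focal),
      logLik = as.numeric(ll), convergence = optima)
}

setMethod("show", "MlHkaResult", function(object) {
  cat("MlHkaResult [", object@model, "]\n", sep = "")
  cat("  logLik:", format(object@logLik, digits = 6),
      "| T:", format(object@T, digits = 4))
  if (object@model == "selection")
    cat(" | k(", paste(object@focal, collapse = ","), "): ",
        format(object@k, digits = 4), sep = "")
  cat("\n")
})

#' Likelihood-ratio test between nested ML-HKA fits
#'
#' 2*DeltaL = 2 (logLik_selection - logLik_null) compared with the
#' chi-squared distribution with 1 degree of freedom (one freed selection
#' parameter).
#'
#' @param fitNull no-selection [MlHkaResult-class].
#' @param fitAlt selection [MlHkaResult-class].
#' @param tol numerical tolerance for a negative likelihood ratio before
#'   it is treated as an optimization failure.
#' @return list with `twoDeltaL`, `df`, `P` and the focal `k`.
#' @export
mlhkaLrt <- function(fitNull, fitAlt, tol = 1e-6) {
  stopifnot(is(fitNull, "MlHkaResult"), is(fitAlt, "MlHkaResult"))
  dl <- 2 * (fitAlt@logLik - fitNull@logLik)
  if (dl < -tol)
    stop("selection model likelihood below null model likelihood (",
         format(dl, digits = 4), "): optimization failure")
  dl <- max(dl, 0)
  list(twoDeltaL = dl, df = 1L, P = lrtPvalue(dl, df = 1L), k = fitAlt@k)
}

#' Chi-squared upper-tail P for a likelihood ratio statistic
#'
#' @param twoDeltaL likelihood ratio statistic 2*DeltaL (>= 0).
#' @param df degrees of freedom.
#' @return upper-tail chi-squared probability.
#' @export
lrtPvalue <- function(twoDeltaL, df = 1L) {
  stopifnot(twoDeltaL >= 0)
  pchisq(twoDeltaL, df = df, lower.tail = FALSE)
}
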