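---
title: "Detecting selective sweeps in a multigene region: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps in a multigene region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sweepsig` implements the full inference chain used to demonstrate a
recent selective sweep in a small, densely annotated genomic region
resequenced in several population samples with a single close outgroup:

1. site classification and nucleotide diversity by site class,
2. site-frequency-spectrum (SFS) neutrality tests with coalescent nulls,
3. pairwise and maximum-likelihood HKA tests,
4. a composite-likelihood-ratio (CLR) sweep scan and the omega linkage
   disequilibrium (LD) scan, and
5. McDonald-Kreitman (MK) tests with a counting dN/dS estimator,

together with a neutral coalescent simulator that powers every empirical
null distribution and a synthetic-data generator that emulates the whole
study design, so that the complete pipeline is testable without any
external data.

# Data model and site classes

Input haplotypes are phased, aligned sequences over \{A, C, G, T, N, -\};
IUPAC ambiguity codes are rejected at import because every statistic here
assumes resolved haplotypes.  Coordinates are 1-based inclusive in all
files and reports (GFF3 convention); columns carrying a gap or N in any
ingroup row are masked, and a codon overlapping a masked column is masked
wholly, so fractional codons never arise.  The analyzed-site count NS
therefore excludes gap columns *and* the remainder of any codon they
intersect.

Each alignment column receives exactly one class: coding, intronic or
intergenic.  For coding columns a *reference codon* is built from the
majority ingroup allele per column (ties broken alphabetically); this is
reproducible and close to classifying on a reference sequence.  Fractional
synonymous weights follow Nei-Gojobori counting: the weight of a codon
position is the fraction of its three possible single-base changes that
leave the amino acid unchanged.  Silent sites are synonymous plus intronic
sites.  Because majority ties are broken alphabetically, strand symmetry
of the classification is exact only in the absence of ties; the test suite
uses tie-free fixtures for the strand-consistency property.

Nucleotide diversity is Nei's pi, uncorrected for multiple hits (the
default of the standard polymorphism software this mirrors).  For the
coding classes, the numerator counts only pairwise allele differences that
are synonymous (respectively nonsynonymous) in the reference codon
context, and the denominator is the fractional site count of that class.
A column polymorphic for both kinds of change contributes to both
numerators but is not counted as a silent segregating site.  Sliding
windows (150 bp, 25-bp step; 673 windows on the default 16,950-bp region)
are defined on alignment coordinates including masked columns, which drop
out of numerator and denominator alike, keeping tracks positionally
stable.

# SFS tests

The unfolded spectrum is polarized by a single outgroup haplotype: a site
is polarized if and only if the outgroup carries a valid base matching
exactly one of the two ingroup alleles; otherwise the site contributes to
the folded spectrum only.  Sites with more than two ingroup alleles are
excluded from SFS statistics (infinite-sites filter) and reported.

Tajima's D uses the classic coefficients and, for table output, silent
sites (synonymous-only by option).  Normalized Fay-Wu H contrasts
pairwise diversity with the high-frequency-weighted estimator
$\theta_L = \sum_i i\,\xi_i/(n-1)$ and divides by the standard variance
estimate, so H has approximately zero mean and unit variance under
neutrality; the test suite verifies the mean to within 0.1 under 10,000
fixed-S replicates.

Significance is empirical: neutral genealogies conditioned on the
observed number of segregating sites (no intragenic recombination, the
conservative choice), two-tailed on $|D|$ or $|H|$, with the
(r+1)/(reps+1) correction so P is never zero.  Published-scale defaults
are 50,000 replicates for D and 10,000 for H; the examples and tests use
smaller, stated counts.

Because the H test is sensitive to ancestral-state misidentification, the
package reports a misorientation probability
$p_{mis} = (d/3)/(1 - 2d/3)$, a Jukes-Cantor-style estimate of the chance
that the outgroup base at a polymorphic site has itself been substituted
to coincide with the derived allele, with $d$ the silent
consensus-to-outgroup divergence.  This formula is our interpretation of
the cited method; treat it as an order-of-magnitude diagnostic rather
than a reproducible quantity.

# HKA and ML-HKA

The pairwise HKA test uses the standard moment system: per-locus
$E[S_i] = \theta_i L_i a_{n_i}$ and $E[D_i] = \theta_i L_i (T+1)$ with a
shared divergence time $T$ (in units of $2N$ generations).  $\theta_i$ is
profiled in closed form and $T$ solved by root finding; the
goodness-of-fit $X^2$ sums the standardized squared deviations of every
$S_i$ and $D_i$ with $\mathrm{Var}(S_i)=\theta L a + (\theta L)^2 b$ and
$\mathrm{Var}(D_i)=\theta L(T+1)+(\theta L)^2$.  Significance comes from
simulating the fitted null (coalescent $S$, Poisson-mixture $D$ whose
variance matches the above) and *re-fitting each replicate* before
computing its $X^2$.

The maximum-likelihood variant models $S_i \sim
\mathrm{Pois}(k_i\,\theta_i L_i a_{n_i})$ and $D_i \sim
\mathrm{Pois}(\theta_i L_i (T+1))$, with $k_i = 1$ everywhere except at
focal loci under the selection model, which share one free selection
parameter $k$ ($k<1$ = diversity deficit).  The original implementation
of this model samples by MCMC; here $\theta_i$ is profiled out exactly
and the remaining one- or two-parameter problem is maximized by bounded
quasi-Newton search from several independent starts, which must agree
(mirroring the practice of repeating the fit to check stability).  Only
the MLEs and the likelihood-ratio statistic are consumed, so the model
content is identical.  $k$ is bounded to $[10^{-4}, 10^2]$; the
log-likelihood uses the continuous Poisson density so fractionally
weighted site counts are acceptable.  $2\Delta L$ is referred to
$\chi^2_1$.  Sample-size corrections to the divergence expectation are
omitted; significance rests on the chi-square or simulation, not on the
moment approximation.

# Sweep scans

**CLR.**  The scan follows the composite-likelihood scheme in which the
null per-SNP probability is the *background* SFS estimated from all
scanned SNPs (including the focal region), and the sweep model distorts
that background at distance $d$ from a proposed sweep site via the escape
probability $p_e = 1 - e^{-\alpha d}$: each of the $n$ lineages escapes
independently with probability $p_e$; the $B$ escapees plus one lineage
for the swept ancestor form an effective sample of $B+1$ drawn from the
background (hypergeometric downsampling), and the ancestor's allele is
copied onto the $n-B$ swept lineages.  The resulting class probabilities
are renormalized over the observable polymorphic classes 1..n-1; fixed
derived sites are excluded by default.  Folded SNPs contribute the summed
probability of the two complementary classes.  CLR(x) maximizes the
summed log-likelihood ratio over a fixed 40-point logarithmic grid of
$\alpha$ anchored at escape probabilities $10^{-4}$..0.9999 at the
region's half-width, plus an exact neutral sentinel ($\alpha = \infty$),
so CLR is never negative.  For speed the transform is precomputed on 96
logarithmic bins of $\alpha d$ (nearest-bin lookup); `sweepTransformedSfs`
itself is exact and is what the enumeration oracle checks.

**Omega.**  For a grid position, the flanking SNPs within `maxwin`
(default 2000 bp) are split into left and right sets; every SNP within
`minwin` (default 1000 bp) is always included and each flank may extend
SNP by SNP outward.  $\omega$ is the ratio of the average within-flank
$r^2$ to the average cross-flank $r^2$, maximized over admissible
extents, requiring at least two SNPs per flank; a zero cross-flank sum
yields a +Inf sentinel, ties take the leftmost split, and grid points
with insufficient flanking SNPs are recorded as NA rather than failing.
$r^2$ is the squared allelic correlation, invariant to allele
relabeling.  Singletons are not excluded.

**Cutoffs.**  Both scans take their 1% significance cutoffs from neutral
coalescent simulation: fixed-S genealogies without recombination for the
CLR (conservative), and the standard coalescent with recombination at the
run's $\rho$ and a Watterson-matched $\theta$ for omega.  Null scan
maxima may use a coarser grid (default 50 points) than the 125-point data
scan; the published-scale replicate default is 10,000 and every cutoff
records its seed, replicate count and quantile.  The parameters behind
the original study's cutoff simulations are not published, so cutoffs
here are calibrated properties, not value targets.

# MK tests and dN/dS

The MK table contrasts fixed differences (ingroup monomorphic, different
from the outgroup) with polymorphisms, each split into replacement and
synonymous changes classified in the reference codon context.  Sites both
polymorphic and divergent count as polymorphic only.  Fixed differences
are unpolarized interspecific differences by default; with the true
ancestral sequence (available for synthetic data) they can be restricted
to the ingroup branch.  The two-sided Fisher exact P sums the
hypergeometric probabilities of all tables at most as probable as the
observed one; a zero margin returns P = 1 and is flagged.

dN/dS uses Nei-Gojobori counting with pathway averaging for multi-hit
codons (pathways through stop codons are excluded when avoidable) and
per-class Jukes-Cantor correction, which errors explicitly at
saturation ($p \ge 3/4$).  This replaces likelihood codon models: it is
deterministic, dependency-free, and adequate at the divergence scale the
package targets (silent divergence ~0.1/site).

# The synthetic-data generator

The generator emulates the study design end to end: a 16,950-bp region
carrying seven genes (CDS lengths 1860, 1905, 960, 3564, 2448, 510 and
3369 bp, mixed strands, short introns, ~11% intergenic), three population
samples (48 + 48 + 40 chromosomes) drawn from one panmictic coalescent
with recombination, and one outgroup haplotype.  Defaults, fixed once
when the generator was designed:

* `thetaSilent = 0.01`/site — silent diversity within the 0.002-0.02
  range of the study's polymorphism tables;
* `T = 11` (2N generations) — outgroup silent divergence near
  $\theta(T+1) = 0.12$/site, inside the published dS range;
* `rho = 150`/region (~0.009/bp) — LD decaying over a few hundred bp, as
  described for this highly outcrossing nematode;
* `keepNonsyn = 0.12` — the fraction of nonsynonymous mutations retained,
  giving pi_a/pi_s ratios like the published tables; mutations creating
  premature stops are always rejected (treated as lethal);
* sweep `alpha = 2.3e-4`/bp at the centre of the focal gene — an
  escape-probability valley about 6 kb wide, matching the observed span
  of reduced diversity.

The sweep is applied by *haplotype collapse*: every haplotype draws
independent left and right escape distances from an exponential with rate
`alpha` and is overwritten with a founder haplotype inside them.  The
marginal per-site escape probability is exactly $1-e^{-\alpha d}$ — the
same law the CLR model assumes — while escape points are perfectly
correlated along each haplotype, which preserves the LD block structure
the omega statistic needs.  Reality lies between this and per-site
independent escape; the generator deliberately sits at the correlated end.

Consequences worth knowing:

* Pair diversity at distance $d$ recovers like $(2p_e - p_e^2)\,\pi_0$,
  because an escaped-vs-swept pair already differs at the background
  rate.  Under the exponential law the focal-to-outer diversity ratio is
  therefore bounded below by roughly the ratio of mean distances to the
  sweep centre (~0.14 for this layout).  The deep (<= 0.2) valley of the
  acceptance experiment uses the strong-sweep setting `alpha = 2e-5`;
  the default alpha gives a shallower, wider valley.
* Omega power experiments use `alpha = 1e-4` ("strong sweep"), where the
  partial-sweep partition structure inside the 1-2 kb windows is
  strongest.
* The generator does not model: post-sweep recovery mutations, gene
  conversion, demography (growth/structure/migration), base-composition
  or mutation-rate heterogeneity, or sequencing error.  Passing tests on
  synthetic data show the estimators and scans behave correctly under
  the stated coalescent model — not that real data meet that model.

Population structure is off by default (the study found the sweep to be
global); a `popDiff` knob adds population-private silent mutations for
robustness exercises.

# Numerical choices

* Empirical P values always use (r+1)/(reps+1).
* Quantile cutoffs use order statistics (type 1), never interpolation.
* The CLR lookup tables floor probabilities at 1e-300 before logs.
* Optimization: ML-HKA restarts are deterministic (fixed start ladder);
  a likelihood ratio below -1e-6 is an error, small negatives are
  clamped to zero.
* Degenerate inputs return explicit NA results (pi with no usable sites,
  D at S = 0, H without polarized sites, omega without two SNPs per
  flank) rather than zeros.
* Seeds: every stochastic routine takes an explicit seed and records it
  in its output; identical seeds give byte-identical results.

# Problem sizes in the tests

The test suite and the acceptance script run entirely on synthetic data
at these scales, chosen as the package's own desk scale: moment checks at
5,000 replicates; fixed-S calibration at 10,000 + 2,000 replicates
(n = 20, S = 30); CLR localization on 50 sweep-model replicates of 200
SNPs (n = 20) and calibration on 500 neutral replicates; omega power on
15-20 strong-sweep regions (n = 48) against a 1% cutoff from 80-100
matched neutral regions; ML-HKA recovery on 20 loci; valley and SFS
signature checks on 5-8 full region samples.  Published-scale replicate
counts (50,000 / 10,000) remain the defaults of the user-facing
functions.

# Known limitations

* Under fixed-S conditioning the normalized Fay-Wu H retains a small
  positive mean (about +0.1 at n = 20, S = 30): the variance constants
  are derived under the unconditional model.  Empirical P values are
  unaffected because the null is simulated under the same conditioning.
* The reference-codon (majority consensus) classification can differ
  from classification on a designated reference sequence at sites where
  the derived allele is the majority — expected inside a sweep.
* The Poisson divergence model of ML-HKA ignores the shared coalescent
  variance between polymorphism and divergence at the same locus; the
  pairwise HKA X^2 handles it through its variance terms.
* The omega null distribution is heavy-tailed at low SNP density, so 1%
  cutoffs from fewer than ~100 replicates are unstable (the package
  warns).
* dN/dS by counting underestimates rates at high divergence relative to
  codon models; the package targets the low-divergence regime.
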