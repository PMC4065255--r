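#' @import methods
#' @importFrom S4Vectors isSingleString isSingleNumber
NULL

.VALID_BASES <- c("A", "C", "G", "T", "N", "-")

#' HaplotypeAlignment: phased haplotypes over one genomic region
#'
#' Holds an aligned set of phased haplotype sequences as an n x L character
#' matrix over \{A, C, G, T, N, -\}, with optional designation of one row as
#' the outgroup.  All ingroup statistics exclude the outgroup row, and
#' columns carrying a gap or N in any ingroup row are treated as maskable.
#'
#' @slot mat character matrix, one row per haplotype, one column per
#'   alignment position.
#' @slot sampleIds character vector of row identifiers (unique).
#' @slot regionOffset 1-based genomic coordinate of alignment column 1.
#' @slot outgroupId identifier of the outgroup row, or `NA_character_`.
#' @export
setClass("HaplotypeAlignment",
  representation(
    mat = "matrix",
    sampleIds = "character",
    regionOffset = "integer",
    outgroupId = "character"
  )
)

setValidity("HaplotypeAlignment", function(object) {
  msg <- NULL
  m <- object@mat
  if (!is.character(m)) msg <- c(msg, "matrix must be character")
  if (nrow(m) != length(object@sampleIds))
    msg <- c(msg, "sampleIds length must equal number of rows")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sample ids")
  bad <- setdiff(unique(as.vector(m)), .VALID_BASES)
  if (length(bad))
    msg <- c(msg, paste0("invalid characters in alignment: ",
                         paste(bad, collapse = ", ")))
  if (!is.na(object@outgroupId) &&
      !object@outgroupId %in% object@sampleIds)
    msg <- c(msg, "outgroupId not among sampleIds")
  if (length(object@regionOffset) != 1L || is.na(object@regionOffset) ||
      object@regionOffset < 1L)
    msg <- c(msg, "regionOffset must be a positive integer")
  if (is.null(msg)) TRUE else msg
})

#' SiteClassMap: per-column functional classification of an alignment
#'
#' Every alignment column receives exactly one class label (coding,
#' intronic or intergenic), a mask flag, and -- for coding columns -- a
#' fractional synonymous site weight in [0, 1] obtained by Nei-Gojobori
#' counting on the reference (majority ingroup) codon: the weight is the
#' number of the three possible single-base changes at that position that
#' are synonymous, divided by 3.  Silent sites are synonymous plus intronic
#' sites.
#'
#' @slot siteClass factor with levels coding/intronic/intergenic, length L.
#' @slot synWeight numeric length L; fractional synonymous weight for
#'   unmasked coding columns, NA elsewhere.
#' @slot masked logical length L; TRUE for columns excluded from analysis.
#' @slot codonGroup integer length L; shared id for the three columns of one
#'   reference codon, NA outside CDS.
#' @slot refCodon character length L; reference codon (coding strand) for
#'   coding columns, NA elsewhere.
#' @slot codonPos integer length L; position (1-3) within the reference
#'   codon reading frame, on the coding strand.
#' @slot geneId character length L; gene identifier for genic columns.
#' @slot strand character length L; "+"/"-" for genic columns.
#' @export
setClass("SiteClassMap",
  representation(
    siteClass = "factor",
    synWeight = "numeric",
    masked = "logical",
    codonGroup = "integer",
    refCodon = "character",
    codonPos = "integer",
    geneId = "character",
    strand = "character"
  )
)

setValidity("SiteClassMap", function(object) {
  L <- length(object@siteClass)
  lens <- c(length(object@synWeight), length(object@masked),
            length(object@codonGroup), length(object@refCodon),
            length(object@codonPos), length(object@geneId),
            length(object@strand))
  if (any(lens != L)) return("all slots must have equal length")
  if (!identical(levels(object@siteClass),
                 c("coding", "intronic", "intergenic")))
    return("class levels must be coding/intronic/intergenic")
  w <- object@synWeight
  if (any(!is.na(w) & (w < 0 | w > 1)))
    return("synonymous weights must lie in [0, 1]")
  TRUE
})

#' SiteFrequencySpectrum: unfolded and folded variant counts
#'
#' Site frequency spectrum for a sample of n chromosomes.  Sites where the
#' outgroup resolves the ancestral state contribute to the unfolded counts
#' xi (derived allele count 1..n-1); sites that cannot be polarized
#' (outgroup missing, gapped, or carrying a third allele) contribute to the
#' folded counts only.  `eta` always holds the fold of all biallelic sites,
#' so the folding identity eta_i = xi_i + xi_(n-i) holds whenever every
#' site is polarizable.
#'
#' @slot n integer, number of ingroup chromosomes.
#' @slot xi numeric length n-1; unfolded counts over polarized sites.
#' @slot eta numeric length floor(n/2); folded counts over all biallelic
#'   sites (polarized and unpolarizable).
#' @slot nPolarized integer, number of polarized segregating sites.
#' @slot nUnpolarizable integer, number of biallelic segregating sites that
#'   could not be polarized.
#' @slot nExcluded integer, segregating sites dropped (>2 ingroup alleles).
#' @export
setClass("SiteFrequencySpectrum",
  representation(
    n = "integer",
    xi = "numeric",
    eta = "numeric",
    nPolarized = "integer",
    nUnpolarizable = "integer",
    nExcluded = "integer"
  )
)

setValidity("SiteFrequencySpectrum", function(object) {
  n <- object@n
  if (length(object@xi) != n - 1L) return("xi must have length n-1")
  if (length(object@eta) != n %/% 2L)
    return("eta must have length floor(n/2)")
  if (sum(object@xi) != object@nPolarized)
    return("sum(xi) must equal nPolarized")
  if (abs(sum(object@eta) -
          (object@nPolarized + object@nUnpolarizable)) > 1e-8)
    return("sum(eta) must equal polarized + unpolarizable sites")
  TRUE
})

#' SnpMatrix: biallelic SNPs as a binary haplotype matrix
#'
#' Biallelic segregating sites extracted from a haplotype alignment (or a
#' coalescent replicate): strictly increasing positions in bp, an n x S
#' 0/1 matrix, and a per-SNP polarization flag.  At polarized SNPs 1 is
#' the derived allele; at unpolarizable SNPs 1 is the minor allele and
#' only the folded class is meaningful.
#'
#' @slot positions numeric, strictly increasing bp positions.
#' @slot mat n x S integer 0/1 matrix.
#' @slot polarized logical length S.
#' @export
setClass("SnpMatrix",
  representation(
    positions = "numeric",
    mat = "matrix",
    polarized = "logical"
  )
)

setValidity("SnpMatrix", function(object) {
  S <- length(object@positions)
  if (ncol(object@mat) != S) return("matrix must have one column per SNP")
  if (length(object@polarized) != S)
    return("polarized flag must have one entry per SNP")
  if (S > 1L && any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  if (S > 0L) {
    cs <- colSums(object@mat)
    if (any(cs == 0L | cs == nrow(object@mat)))
      return("each SNP must have 2 observed alleles")
  }
  TRUE
})

#' ScanTrack: a statistic evaluated on a positional grid
#'
#' Result container for the composite-likelihood-ratio and omega sweep
#' scans: a set of evenly spaced grid positions with the scan statistic at
#' each, the argmax, and (optionally) a simulated significance cutoff with
#' the seed and replicate count that produced it.
#'
#' @slot statName "CLR" or "omega".
#' @slot position numeric grid positions (bp).
#' @slot stat numeric statistic values (NA where undefined).
#' @slot alphaHat numeric; fitted sweep intensity per grid point (CLR only).
#' @slot cutoff numeric(1); simulated null cutoff, NA if not computed.
#' @slot cutoffQuantile numeric(1); quantile the cutoff corresponds to.
#' @slot replicates integer(1); null replicates behind the cutoff.
#' @slot seed integer(1); seed used for the null simulation.
#' @export
setClass("ScanTrack",
  representation(
    statName = "character",
    position = "numeric",
    stat = "numeric",
    alphaHat = "numeric",
    cutoff = "numeric",
    cutoffQuantile = "numeric",
    replicates = "integer",
    seed = "integer"
  )
)

setValidity("ScanTrack", function(object) {
  if (length(object@position) != length(object@stat))
    return("position and stat must have equal length")
  TRUE
})

#' MlHkaResult: a fitted maximum-likelihood HKA model
#'
#' Maximum-likelihood fit of the multilocus polymorphism/divergence model
#' in which locus i contributes independent Poisson counts
#' S_i ~ Pois(k_i theta_i L_i a_{n_i}) and D_i ~ Pois(theta_i L_i (T+1)),
#' with k_i = 1 at non-focal loci.  Under the selection model the focal
#' loci share a free selection parameter k; k < 1 indicates a diversity
#' deficit relative to divergence.
#'
#' @slot model "no-selection" or "selection".
#' @slot theta numeric; per-locus mutation parameter estimates (per locus,
#'   i.e. theta_i * L_i is the expected locus-wide heterozygosity scale).
#' @slot T numeric(1); divergence time estimate in 2N generations.
#' @slot k numeric(1); selection parameter at the focal loci (1 when the
#'   selection flag is off).
#' @slot focal character; focal locus ids.
#' @slot logLik numeric(1); maximized log-likelihood.
#' @slot convergence list; per-restart optima for diagnostics.
#' @export
setClass("MlHkaResult",
  representation(
    model = "character",
    theta = "numeric",
    T = "numeric",
    k = "numeric",
    focal = "character",
    logLik = "numeric",
    convergence = "list"
  )
)
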