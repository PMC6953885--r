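#' @import methods
NULL

#' Simulation configuration for synthetic admixed haplotype data
#'
#' A validated container for every knob of the haplotype-mosaic simulator:
#' ancestral pool composition and divergence, the truncated 1/f site-frequency
#' spectrum, mosaic switch rates, fresh-mutation rate, panel/target sample
#' sizes, and the genotyping-array masking rule (MAF cutoff plus uniform
#' thinning). All randomness downstream of a config flows from its \code{seed},
#' so identical configs yield bit-identical datasets.
#'
#' @slot nPools number of ancestral founder pools.
#' @slot poolProportions per-pool fraction of reference-panel haplotypes;
#'   sums to 1.
#' @slot foundersPerPool founder haplotypes simulated per pool.
#' @slot fstLikeDivergence dimensionless in [0,1]; scales the variance of the
#'   logit-normal perturbation applied to pool allele frequencies.
#' @slot nSites polymorphic sites per region.
#' @slot regionLengthBp region length in base pairs.
#' @slot regionStartBp 1-based offset of the region start.
#' @slot chrom chromosome name used in site keys and VCF output.
#' @slot founderSwitchRate expected donor-founder switches per Mb.
#' @slot ancestrySwitchRate expected ancestry-segment switches per Mb.
#' @slot freshMutationRate per-site per-haplotype allele flip probability.
#' @slot freqSpectrum length-2 numeric, lower/upper bound of the 1/f draw.
#' @slot targetCohorts named list; each element is \code{list(n = <diploid
#'   individuals>, admixture = <per-pool fractions summing to 1>)}.
#' @slot nPanelHaplotypes haplotypes in the reference panel.
#' @slot arrayMafThreshold minimum target MAF for a site to be typable.
#' @slot arrayDensity fraction of eligible sites retained on the array.
#' @slot seed integer RNG seed.
#'
#' @seealso [SimConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig", representation(
  nPools = "integer",
  poolProportions = "numeric",
  foundersPerPool = "integer",
  fstLikeDivergence = "numeric",
  nSites = "integer",
  regionLengthBp = "numeric",
  regionStartBp = "numeric",
  chrom = "character",
  founderSwitchRate = "numeric",
  ancestrySwitchRate = "numeric",
  freshMutationRate = "numeric",
  freqSpectrum = "numeric",
  targetCohorts = "list",
  nPanelHaplotypes = "integer",
  arrayMafThreshold = "numeric",
  arrayDensity = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  tol <- 1e-12
  p <- object@poolProportions
  if (length(p) != object@nPools) msg <- c(msg, "poolProportions length must equal nPools")
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > tol)
    msg <- c(msg, "poolProportions must lie in [0,1] and sum to 1")
  if (object@nSites < 2L) msg <- c(msg, "nSites must be >= 2")
  if (object@foundersPerPool < 1L) msg <- c(msg, "foundersPerPool must be >= 1")
  if (object@fstLikeDivergence < 0 || object@fstLikeDivergence > 1)
    msg <- c(msg, "fstLikeDivergence must lie in [0,1]")
  rates <- c(object@founderSwitchRate, object@ancestrySwitchRate, object@freshMutationRate)
  if (any(rates < 0)) msg <- c(msg, "switch/mutation rates must be >= 0")
  fs <- object@freqSpectrum
  if (length(fs) != 2L || fs[1] <= 0 || fs[1] >= fs[2] || fs[2] > 0.5)
    msg <- c(msg, "freqSpectrum must satisfy 0 < lower < upper <= 0.5")
  for (nm in names(object@targetCohorts)) {
    co <- object@targetCohorts[[nm]]
    if (!is.list(co) || is.null(co$n) || is.null(co$admixture)) {
      msg <- c(msg, sprintf("target cohort '%s' needs fields n and admixture", nm))
      next
    }
    if (co$n < 1) msg <- c(msg, sprintf("target cohort '%s' must have n >= 1", nm))
    a <- co$admixture
    if (length(a) != object@nPools || any(a < 0) || abs(sum(a) - 1) > tol)
      msg <- c(msg, sprintf("admixture of cohort '%s' must have nPools entries in [0,1] summing to 1", nm))
  }
  if (length(object@targetCohorts) < 1L) msg <- c(msg, "at least one target cohort is required")
  if (object@nPanelHaplotypes < 2L) msg <- c(msg, "nPanelHaplotypes must be >= 2")
  if (object@arrayMafThreshold < 0 || object@arrayMafThreshold > 0.5)
    msg <- c(msg, "arrayMafThreshold must lie in [0,0.5]")
  if (object@arrayDensity <= 0 || object@arrayDensity > 1)
    msg <- c(msg, "arrayDensity must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Phased binary haplotype panel
#'
#' The central container shared by the simulator, the imputation engine and the
#' evaluation framework: a haplotype-by-site matrix of 0/1 alleles with 1-based
#' strictly increasing positions, chrom/pos/ref/alt site keys, per-haplotype
#' sample and pool labels, and (optionally) a per-haplotype per-site local
#' ancestry track. The same class represents a reference panel, a truth set, or
#' an array-masked target.
#'
#' @slot alleles integer matrix of 0/1, haplotypes in rows, sites in columns.
#' @slot positions integer vector of 1-based base-pair coordinates, strictly
#'   increasing.
#' @slot chrom single chromosome name.
#' @slot ref,alt reference/alternate alleles per site.
#' @slot siteIds chrom:pos:ref:alt keys.
#' @slot haplotypeLabels per-haplotype label (sample id plus haplotype index).
#' @slot sampleIds per-haplotype sample id (each diploid sample appears twice,
#'   on adjacent rows).
#' @slot poolLabels per-haplotype ancestral-pool or population label.
#' @slot localAncestry integer matrix of per-haplotype per-site pool indices,
#'   or a 0-row matrix when no ancestry track is available.
#' @export
setClass("HaplotypePanel", representation(
  alleles = "matrix",
  positions = "integer",
  chrom = "character",
  ref = "character",
  alt = "character",
  siteIds = "character",
  haplotypeLabels = "character",
  sampleIds = "character",
  poolLabels = "character",
  localAncestry = "matrix"
))

setValidity("HaplotypePanel", function(object) {
  msg <- character(0)
  a <- object@alleles
  if (!is.numeric(a) && !is.integer(a)) msg <- c(msg, "alleles must be numeric")
  if (length(a) && !all(a == 0L | a == 1L)) msg <- c(msg, "alleles must be binary 0/1")
  S <- ncol(a); H <- nrow(a)
  if (length(object@positions) != S) msg <- c(msg, "positions length must match site count")
  if (S > 1L && any(diff(object@positions) <= 0L)) msg <- c(msg, "positions must be strictly increasing")
  if (length(object@ref) != S || length(object@alt) != S) msg <- c(msg, "ref/alt length must match site count")
  if (length(object@siteIds) != S) msg <- c(msg, "siteIds length must match site count")
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be a single string")
  for (sl in c("haplotypeLabels", "sampleIds", "poolLabels"))
    if (length(slot(object, sl)) != H) msg <- c(msg, sprintf("%s length must match haplotype count", sl))
  la <- object@localAncestry
  if (nrow(la) > 0L && (nrow(la) != H || ncol(la) != S))
    msg <- c(msg, "localAncestry dimensions must match alleles")
  if (length(msg)) msg else TRUE
})

#' Li-Stephens copying-model parameters
#'
#' @slot recombScale expected template switches per Mb of the copying process.
#' @slot copyError emission mismatch probability (epsilon), in (0, 0.5).
#' @slot minSwitch floor on the per-interval switch probability, in [0, 1).
#' @seealso [HmmParams()]
#' @export
setClass("HmmParams", representation(
  recombScale = "numeric",
  copyError = "numeric",
  minSwitch = "numeric"
))

setValidity("HmmParams", function(object) {
  msg <- character(0)
  if (object@copyError <= 0 || object@copyError >= 0.5)
    msg <- c(msg, "copyError must lie in (0, 0.5)")
  if (object@recombScale < 0) msg <- c(msg, "recombScale must be >= 0")
  if (object@minSwitch < 0 || object@minSwitch >= 1)
    msg <- c(msg, "minSwitch must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Imputation dosages and per-site estimated R-squared
#'
#' Output of the imputation engine: per-haplotype alternate-allele dosages in
#' [0,1], per-individual genotype dosages in [0,2] (exactly the sum of the two
#' haplotype dosages), the per-site variance-ratio estimated R-squared, and a
#' typed/imputed flag per site.
#'
#' @slot haplotypeDosage numeric matrix (target haplotype x site) in [0,1].
#' @slot genotypeDosage numeric matrix (individual x site) in [0,2].
#' @slot estR2 per-site estimated R-squared (ratio of observed dosage variance
#'   to the binomial variance expected from the allele frequency); >= 0, not
#'   capped at 1.
#' @slot typed logical per site: genotyped on the array scaffold vs imputed.
#' @slot positions,chrom,ref,alt,siteIds site annotation as in
#'   \linkS4class{HaplotypePanel}.
#' @slot sampleIds one id per diploid individual.
#' @export
setClass("DosageResult", representation(
  haplotypeDosage = "matrix",
  genotypeDosage = "matrix",
  estR2 = "numeric",
  typed = "logical",
  positions = "integer",
  chrom = "character",
  ref = "character",
  alt = "character",
  siteIds = "character",
  sampleIds = "character"
))

setValidity("DosageResult", function(object) {
  msg <- character(0)
  hd <- object@haplotypeDosage
  gd <- object@genotypeDosage
  S <- ncol(hd)
  if (min(hd) < -1e-12 || max(hd) > 1 + 1e-12)
    msg <- c(msg, "haplotype dosages must lie in [0,1]")
  if (nrow(hd) %% 2L != 0L) msg <- c(msg, "haplotype count must be even")
  if (nrow(gd) != nrow(hd) / 2L || ncol(gd) != S)
    msg <- c(msg, "genotypeDosage must be (individuals x sites)")
  odd <- seq(1L, nrow(hd), by = 2L)
  if (nrow(gd) && !identical(unname(gd), unname(hd[odd, , drop = FALSE] + hd[odd + 1L, , drop = FALSE])))
    msg <- c(msg, "genotypeDosage must equal the sum of each individual's two haplotype dosages")
  if (length(object@estR2) != S || any(object@estR2 < 0))
    msg <- c(msg, "estR2 must be per-site and >= 0")
  if (length(object@typed) != S) msg <- c(msg, "typed flag must be per-site")
  if (length(object@positions) != S || length(object@siteIds) != S)
    msg <- c(msg, "site annotation must match site count")
  if (length(object@sampleIds) != nrow(gd)) msg <- c(msg, "sampleIds must be per-individual")
  if (length(msg)) msg else TRUE
})

#' Per-MAF-bin estimated R-squared QC thresholds
#'
#' Thresholds chosen per MAF bin so that variants at or above the threshold
#' have a mean quality metric of at least \code{targetMean} (0.8 by default).
#' \code{NA} in a bin is the "none-pass" sentinel: either no variant reaches
#' the target even at the largest observed value, or the bin was empty.
#'
#' @slot thresholds numeric vector, one entry per MAF bin (NA = none-pass).
#' @slot targetMean the mean-quality target enforced among passing variants.
#' @slot metric which metric the thresholds were computed on, "estimated" or
#'   "true".
#' @slot binSummary data.frame with per-bin counts, pass counts and achieved
#'   means.
#' @export
setClass("QCThresholds", representation(
  thresholds = "numeric",
  targetMean = "numeric",
  metric = "character",
  binSummary = "data.frame"
))

setValidity("QCThresholds", function(object) {
  msg <- character(0)
  if (!object@metric %in% c("estimated", "true"))
    msg <- c(msg, "metric must be 'estimated' or 'true'")
  if (object@targetMean < 0 || object@targetMean > 1)
    msg <- c(msg, "targetMean must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
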