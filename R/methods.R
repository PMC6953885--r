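#' Ancestry admixture presets for target cohorts
#'
#' Two presets parallel the study designs commonly used for admixed U.S.
#' cohorts on a five-pool panel (EUR/AFR/AMR/EAS/OTH): an "AA"-like two-way
#' 20/80 European/African mixture and an "HL"-like three-way 45/20/35
#' European/African/Amerindian mixture.
#'
#' @param name "AA" or "HL".
#' @param nPools number of pools in the configuration (>= 3).
#' @return numeric vector of per-pool admixture fractions summing to 1.
#' @export
admixturePreset <- function(name = c("AA", "HL"), nPools = 5L) {
  name <- match.arg(name)
  if (nPools < 3L) stop("admixture presets require at least 3 pools")
  a <- numeric(nPools)
  if (name == "AA") a[1:2] <- c(0.2, 0.8) else a[1:3] <- c(0.45, 0.2, 0.35)
  names(a) <- poolNames(nPools)
  a
}

poolNames <- function(n) {
  base <- c("EUR", "AFR", "AMR", "EAS", "OTH")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("P%02d", seq_len(n - length(base))))
}

#' Construct a simulation configuration
#'
#' Defaults describe the benchmarking conditions used throughout the package:
#' a five-pool reference panel mixed 54/26/10/7/3 (emulating a large
#' multi-ethnic sequencing panel dominated by European-ancestry samples with
#' substantial African-ancestry and Hispanic/Latino representation), 150 founders per pool, a 1/f site-frequency spectrum truncated to
#' [1/(2 x 750), 0.5], a 5 Mb region carrying 1,000 polymorphic sites, a
#' 2,000-haplotype panel, and one "AA"-like target cohort of 200 diploid
#' individuals typed on a sparse array (MAF >= 5%, 80% of eligible sites).
#'
#' @param nPools,poolProportions,foundersPerPool,fstLikeDivergence,nSites
#'   see \linkS4class{SimConfig}.
#' @param regionLengthBp,regionStartBp,chrom region geometry.
#' @param founderSwitchRate,ancestrySwitchRate,freshMutationRate mosaic rates.
#' @param freqSpectrum lower/upper MAF bounds of the 1/f draw; defaults to
#'   c(1/(2*nPools*foundersPerPool), 0.5).
#' @param targetCohorts named list of \code{list(n=, admixture=)}; default one
#'   "AA"-like cohort of 200 individuals.
#' @param nPanelHaplotypes,arrayMafThreshold,arrayDensity,seed see
#'   \linkS4class{SimConfig}.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(nSites = 50L, nPanelHaplotypes = 40L,
#'                  targetCohorts = list(AA = list(n = 5, admixture = admixturePreset("AA"))))
#' cfg
#' @export
SimConfig <- function(nPools = 5L,
                      poolProportions = c(EUR = 0.54, AFR = 0.26, AMR = 0.10, EAS = 0.07, OTH = 0.03),
                      foundersPerPool = 150L,
                      fstLikeDivergence = 0.1,
                      nSites = 1000L,
                      regionLengthBp = 5e6,
                      regionStartBp = 0,
                      chrom = "chr1",
                      founderSwitchRate = 0.5,
                      ancestrySwitchRate = 0.1,
                      freshMutationRate = 5e-4,
                      freqSpectrum = NULL,
                      targetCohorts = list(AA = list(n = 200L, admixture = admixturePreset("AA", nPools))),
                      nPanelHaplotypes = 2000L,
                      arrayMafThreshold = 0.05,
                      arrayDensity = 0.8,
                      seed = 1L) {
  if (is.null(freqSpectrum))
    freqSpectrum <- c(1 / (2 * nPools * foundersPerPool), 0.5)
  new("SimConfig",
      nPools = as.integer(nPools), poolProportions = poolProportions,
      foundersPerPool = as.integer(foundersPerPool),
      fstLikeDivergence = fstLikeDivergence, nSites = as.integer(nSites),
      regionLengthBp = regionLengthBp, regionStartBp = regionStartBp,
      chrom = chrom, founderSwitchRate = founderSwitchRate,
      ancestrySwitchRate = ancestrySwitchRate,
      freshMutationRate = freshMutationRate, freqSpectrum = freqSpectrum,
      targetCohorts = targetCohorts,
      nPanelHaplotypes = as.integer(nPanelHaplotypes),
      arrayMafThreshold = arrayMafThreshold, arrayDensity = arrayDensity,
      seed = as.integer(seed))
}

#' Construct Li-Stephens copying parameters
#'
#' @param recombScale expected template switches per Mb (default 1).
#' @param copyError emission mismatch probability epsilon (default 0.001).
#' @param minSwitch floor on the per-interval switch probability.
#' @return a validated \linkS4class{HmmParams}.
#' @export
HmmParams <- function(recombScale = 1, copyError = 0.001, minSwitch = 1e-5) {
  new("HmmParams", recombScale = recombScale, copyError = copyError,
      minSwitch = minSwitch)
}

#' Construct a HaplotypePanel
#'
#' @param alleles haplotype-by-site 0/1 matrix.
#' @param positions strictly increasing 1-based positions.
#' @param chrom chromosome name.
#' @param ref,alt per-site alleles (defaults "A"/"C").
#' @param haplotypeLabels,sampleIds,poolLabels per-haplotype annotation.
#' @param localAncestry optional per-haplotype per-site pool index matrix.
#' @return a validated \linkS4class{HaplotypePanel}.
#' @export
HaplotypePanel <- function(alleles, positions, chrom = "chr1",
                           ref = rep("A", ncol(alleles)),
                           alt = rep("C", ncol(alleles)),
                           haplotypeLabels = sprintf("hap%04d", seq_len(nrow(alleles))),
                           sampleIds = haplotypeLabels,
                           poolLabels = rep(NA_character_, nrow(alleles)),
                           localAncestry = matrix(integer(0), 0, 0)) {
  storage.mode(alleles) <- "integer"
  new("HaplotypePanel", alleles = alleles, positions = as.integer(positions),
      chrom = chrom, ref = ref, alt = alt,
      siteIds = sprintf("%s:%d:%s:%s", chrom, as.integer(positions), ref, alt),
      haplotypeLabels = haplotypeLabels, sampleIds = sampleIds,
      poolLabels = poolLabels, localAncestry = localAncestry)
}

## ---- accessors ------------------------------------------------------------

#' @rdname HaplotypePanel-class
#' @export
setMethod("alleleMatrix", "HaplotypePanel", function(x) x@alleles)

#' @rdname HaplotypePanel-class
#' @export
setMethod("sitePositions", "HaplotypePanel", function(x) x@positions)

#' @rdname HaplotypePanel-class
#' @export
setMethod("siteIds", "HaplotypePanel", function(x) x@siteIds)

#' @rdname HaplotypePanel-class
#' @export
setMethod("sampleIds", "HaplotypePanel", function(x) x@sampleIds)

#' @rdname HaplotypePanel-class
#' @export
setMethod("poolLabels", "HaplotypePanel", function(x) x@poolLabels)

#' @rdname HaplotypePanel-class
#' @export
setMethod("localAncestry", "HaplotypePanel", function(x) x@localAncestry)

#' @rdname HaplotypePanel-class
#' @export
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@alleles))

#' @rdname HaplotypePanel-class
#' @export
setMethod("nSites", "HaplotypePanel", function(x) ncol(x@alleles))

#' @rdname HaplotypePanel-class
#' @details \code{genotypeMatrix} collapses adjacent haplotype pairs into
#'   per-individual genotype counts in \{0,1,2\}; the panel must contain an
#'   even number of haplotypes with paired sample ids on adjacent rows.
#' @export
setMethod("genotypeMatrix", "HaplotypePanel", function(x) {
  H <- nHaplotypes(x)
  if (H %% 2L != 0L) stop("genotypeMatrix requires an even number of haplotypes")
  odd <- seq(1L, H, by = 2L)
  g <- x@alleles[odd, , drop = FALSE] + x@alleles[odd + 1L, , drop = FALSE]
  rownames(g) <- x@sampleIds[odd]
  g
})

#' @rdname HaplotypePanel-class
#' @param i haplotype (row) indices.
#' @param j site (column) indices.
#' @param ... ignored.
#' @param drop ignored; subsetting always returns a HaplotypePanel.
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nHaplotypes(x))
  if (missing(j)) j <- seq_len(nSites(x))
  la <- x@localAncestry
  if (nrow(la) > 0L) la <- la[i, j, drop = FALSE]
  initialize(x,
             alleles = x@alleles[i, j, drop = FALSE],
             positions = x@positions[j], ref = x@ref[j], alt = x@alt[j],
             siteIds = x@siteIds[j],
             haplotypeLabels = x@haplotypeLabels[i],
             sampleIds = x@sampleIds[i], poolLabels = x@poolLabels[i],
             localAncestry = la)
})

#' @rdname DosageResult-class
#' @export
setMethod("haplotypeDosage", "DosageResult", function(x) x@haplotypeDosage)

#' @rdname DosageResult-class
#' @export
setMethod("genotypeDosage", "DosageResult", function(x) x@genotypeDosage)

#' @rdname DosageResult-class
#' @export
setMethod("estR2", "DosageResult", function(x) x@estR2)

#' @rdname DosageResult-class
#' @export
setMethod("typedSites", "DosageResult", function(x) x@typed)

#' @rdname DosageResult-class
#' @export
setMethod("siteIds", "DosageResult", function(x) x@siteIds)

#' @rdname DosageResult-class
#' @export
setMethod("sitePositions", "DosageResult", function(x) x@positions)

#' @rdname DosageResult-class
#' @export
setMethod("sampleIds", "DosageResult", function(x) x@sampleIds)

#' @rdname DosageResult-class
#' @export
setMethod("nSites", "DosageResult", function(x) length(x@positions))

#' @rdname QCThresholds-class
#' @export
setMethod("qcThresholds", "QCThresholds", function(x) x@thresholds)

## ---- show methods ---------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  co <- vapply(object@targetCohorts, function(x) sprintf("%d ind", x$n), character(1))
  cat(sprintf("SimConfig: %d pools, %d founders/pool, %d sites over %.1f Mb\n",
              object@nPools, object@foundersPerPool, object@nSites,
              object@regionLengthBp / 1e6))
  cat(sprintf("  panel: %d haplotypes; cohorts: %s\n", object@nPanelHaplotypes,
              paste(sprintf("%s (%s)", names(co), co), collapse = ", ")))
  cat(sprintf("  spectrum ~1/f on [%.4g, %.3g]; array MAF >= %.3g, density %.2f; seed %d\n",
              object@freqSpectrum[1], object@freqSpectrum[2],
              object@arrayMafThreshold, object@arrayDensity, object@seed))
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes x %d sites on %s [%d-%d]\n",
              nHaplotypes(object), nSites(object), object@chrom,
              min(object@positions), max(object@positions)))
  pools <- unique(stats::na.omit(object@poolLabels))
  if (length(pools)) cat("  pools:", paste(pools, collapse = ", "), "\n")
  if (nrow(object@localAncestry)) cat("  local-ancestry track present\n")
})

setMethod("show", "HmmParams", function(object) {
  cat(sprintf("HmmParams: recombScale %.3g /Mb, copyError %.3g, minSwitch %.3g\n",
              object@recombScale, object@copyError, object@minSwitch))
})

setMethod("show", "DosageResult", function(object) {
  cat(sprintf("DosageResult: %d individuals x %d sites (%d typed, %d imputed)\n",
              nrow(object@genotypeDosage), nSites(object),
              sum(object@typed), sum(!object@typed)))
  cat(sprintf("  estimated R2: median %.3f, mean %.3f\n",
              stats::median(object@estR2), mean(object@estR2)))
})

setMethod("show", "QCThresholds", function(object) {
  cat(sprintf("QCThresholds on %s R2, target mean >= %.2f\n", object@metric,
              object@targetMean))
  th <- object@thresholds
  cat("  per-bin thresholds:",
      paste(ifelse(is.na(th), "none-pass", sprintf("%.4f", th)), collapse = " "), "\n")
})
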