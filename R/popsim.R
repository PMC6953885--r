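## Synthetic admixed haplotype simulator.
##
## Linkage disequilibrium is induced by mosaic copying from small founder
## pools rather than by a coalescent process: every simulated haplotype is a
## segment-wise copy of pool founders, so target and panel haplotypes share
## long identical stretches -- exactly the structure a haplotype-copying HMM
## exploits -- without demographic realism.

#' Draw site frequencies from a truncated 1/f spectrum
#'
#' Inverse-CDF sampling of the density proportional to 1/f on [lower, upper]:
#' f = lower * (upper/lower)^U with U uniform. This puts most mass near the
#' lower bound, reproducing a rare-variant-dominated spectrum.
#'
#' @param n number of draws.
#' @param lower,upper spectrum bounds, 0 < lower < upper <= 0.5.
#' @return numeric vector of frequencies.
#' @export
rFreqSpectrum <- function(n, lower, upper) {
  if (lower <= 0 || lower >= upper) stop("invalid frequency spectrum bounds: need 0 < lower < upper")
  lower * (upper / lower)^stats::runif(n)
}

#' Simulate per-pool founder haplotype panels
#'
#' For each site a base frequency is drawn from the truncated 1/f spectrum;
#' pool-specific frequencies are obtained by perturbing logit(f) with
#' independent N(0, 4 * fstLikeDivergence) noise (zero divergence leaves all
#' pools identical); founder alleles are then drawn independently per site
#' from the pool frequency. Draws use the current RNG state; seed it (or call
#' via [buildDataset()]) for reproducibility.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return named list with one \linkS4class{HaplotypePanel} per pool; carries
#'   attributes \code{baseFreq} (per-site base frequency) and \code{poolFreq}
#'   (pool-by-site frequency matrix).
#' @export
simulateFounderPools <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  lo <- config@freqSpectrum[1]; up <- config@freqSpectrum[2]
  S <- config@nSites
  if (S > config@regionLengthBp) stop("nSites exceeds the number of available positions")
  pos <- sort(sample.int(config@regionLengthBp, S)) + as.integer(config@regionStartBp)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1), USE.NAMES = FALSE)
  baseFreq <- rFreqSpectrum(S, lo, up)
  K <- config@nPools
  Fp <- config@foundersPerPool
  sdLogit <- 2 * sqrt(config@fstLikeDivergence)
  nm <- names(config@poolProportions)
  if (is.null(nm)) nm <- poolNames(K)
  poolFreq <- matrix(0, K, S, dimnames = list(nm, NULL))
  pools <- stats::setNames(vector("list", K), nm)
  for (k in seq_len(K)) {
    eps <- if (sdLogit > 0) stats::rnorm(S, 0, sdLogit) else numeric(S)
    pf <- stats::plogis(stats::qlogis(baseFreq) + eps)
    poolFreq[k, ] <- pf
    al <- matrix(stats::rbinom(Fp * S, 1L, rep(pf, each = Fp)), nrow = Fp)
    pools[[k]] <- HaplotypePanel(
      alleles = al, positions = pos, chrom = config@chrom, ref = ref, alt = alt,
      haplotypeLabels = sprintf("%s_f%03d", nm[k], seq_len(Fp)),
      poolLabels = rep(nm[k], Fp))
  }
  attr(pools, "baseFreq") <- baseFreq
  attr(pools, "poolFreq") <- poolFreq
  pools
}

#' Simulate one admixed mosaic haplotype
#'
#' Ancestry segments follow a Markov switch process: between consecutive sites
#' at distance d Mb a switch event occurs with probability
#' 1 - exp(-ancestrySwitchRate * d); at an event the new ancestry is drawn from
#' the admixture proportions (so the stationary distribution equals the
#' admixture). Within an ancestry segment, alleles are copied from one founder
#' of that pool, re-choosing the donor at founderSwitchRate; finally each site
#' flips with probability freshMutationRate.
#'
#' @param pools founder panels from [simulateFounderPools()].
#' @param admixture per-pool fractions summing to 1.
#' @param config a \linkS4class{SimConfig} (rates are read from it).
#' @return list with \code{alleles} (integer 0/1 vector), \code{ancestry}
#'   (per-site pool index) and \code{nAncestrySwitchEvents} (number of switch
#'   events drawn after the initial state).
#' @export
simulateMosaicHaplotype <- function(pools, admixture, config) {
  K <- length(pools)
  if (abs(sum(admixture) - 1) > 1e-12) stop("admixture fractions must sum to 1")
  need <- which(admixture > 0)
  empty <- vapply(pools, function(p) nHaplotypes(p) == 0L, logical(1))
  if (any(empty[need])) stop("empty founder pool for a requested ancestry: ",
                             paste(names(pools)[need][empty[need]], collapse = ", "))
  pos <- sitePositions(pools[[1L]])
  S <- length(pos)
  d <- diff(pos) / 1e6
  ancEvent <- stats::runif(S - 1L) < 1 - exp(-config@ancestrySwitchRate * d)
  starts <- c(1L, which(ancEvent) + 1L)
  vals <- sample.int(K, length(starts), replace = TRUE, prob = admixture)
  ancestry <- rep(vals, diff(c(starts, S + 1L)))
  founderEvent <- stats::runif(S - 1L) < 1 - exp(-config@founderSwitchRate * d)
  segStarts <- sort(unique(c(1L, which(ancEvent | founderEvent) + 1L)))
  segEnds <- c(segStarts[-1L] - 1L, S)
  hap <- integer(S)
  for (i in seq_along(segStarts)) {
    idx <- segStarts[i]:segEnds[i]
    k <- ancestry[segStarts[i]]
    donor <- sample.int(nHaplotypes(pools[[k]]), 1L)
    hap[idx] <- pools[[k]]@alleles[donor, idx]
  }
  flip <- stats::runif(S) < config@freshMutationRate
  hap[flip] <- 1L - hap[flip]
  list(alleles = hap, ancestry = ancestry, nAncestrySwitchEvents = sum(ancEvent))
}

## mosaic a block of haplotypes; admixture either a single vector (recycled)
## or per-haplotype one-hot assignments given by pool index vector
.mosaicBlock <- function(pools, admixtures, config, trackAncestry = FALSE) {
  n <- length(admixtures)
  S <- nSites(pools[[1L]])
  al <- matrix(0L, n, S)
  anc <- if (trackAncestry) matrix(0L, n, S) else matrix(integer(0), 0, 0)
  switches <- integer(n)
  for (i in seq_len(n)) {
    m <- simulateMosaicHaplotype(pools, admixtures[[i]], config)
    al[i, ] <- m$alleles
    if (trackAncestry) anc[i, ] <- m$ancestry
    switches[i] <- m$nAncestrySwitchEvents
  }
  list(alleles = al, ancestry = anc, switches = switches)
}

#' Build a complete synthetic dataset: panel, truth cohorts and array masks
#'
#' Seeds the RNG from the config, simulates founder pools, draws the
#' reference panel (haplotypes assigned to pools by \code{poolProportions},
#' each a within-pool founder mosaic) and each target cohort (admixed mosaics
#' of the same founders, truth retained at every site along with the local
#' ancestry track), then chooses each cohort's typed set by the array MAF
#' cutoff followed by uniform thinning to \code{arrayDensity}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return object of class \code{"benchDataset"}: list with \code{panel}
#'   (\linkS4class{HaplotypePanel}), \code{targets} (named list of truth
#'   panels), \code{masks} (named list of typed site indices, with a
#'   \code{provenance} attribute describing the rule), and \code{config}.
#' @examples
#' cfg <- SimConfig(nSites = 60L, nPanelHaplotypes = 40L, foundersPerPool = 10L,
#'                  targetCohorts = list(AA = list(n = 4, admixture = admixturePreset("AA"))))
#' ds <- buildDataset(cfg)
#' ds$panel
#' @export
buildDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  pools <- simulateFounderPools(config)
  K <- config@nPools
  N <- config@nPanelHaplotypes
  counts <- diff(round(cumsum(c(0, config@poolProportions)) * N))
  poolIdx <- rep(seq_len(K), counts)
  oneHots <- lapply(seq_len(K), function(k) { v <- numeric(K); v[k] <- 1; v })
  panelBlock <- .mosaicBlock(pools, oneHots[poolIdx], config)
  nm <- names(pools)
  ref1 <- pools[[1L]]
  panel <- HaplotypePanel(
    alleles = panelBlock$alleles, positions = sitePositions(ref1),
    chrom = config@chrom, ref = ref1@ref, alt = ref1@alt,
    haplotypeLabels = sprintf("R%04d_%d", ceiling(seq_len(N) / 2), rep(1:2, length.out = N)),
    sampleIds = sprintf("R%04d", ceiling(seq_len(N) / 2)),
    poolLabels = nm[poolIdx])
  targets <- list()
  masks <- list()
  for (cname in names(config@targetCohorts)) {
    co <- config@targetCohorts[[cname]]
    n2 <- 2L * as.integer(co$n)
    blk <- .mosaicBlock(pools, rep(list(co$admixture), n2), config, trackAncestry = TRUE)
    tg <- HaplotypePanel(
      alleles = blk$alleles, positions = sitePositions(ref1),
      chrom = config@chrom, ref = ref1@ref, alt = ref1@alt,
      haplotypeLabels = sprintf("%s_%04d_%d", cname, ceiling(seq_len(n2) / 2),
                                rep(1:2, length.out = n2)),
      sampleIds = sprintf("%s_%04d", cname, ceiling(seq_len(n2) / 2)),
      poolLabels = rep(cname, n2), localAncestry = blk$ancestry)
    f <- colMeans(blk$alleles)
    maf <- pmin(f, 1 - f)
    eligible <- which(maf >= config@arrayMafThreshold & maf > 0)
    if (!length(eligible))
      stop("no site passes the array MAF threshold in cohort ", cname)
    nTyped <- max(1L, floor(config@arrayDensity * length(eligible)))
    typed <- sort(sample(eligible, nTyped))
    attr(typed, "provenance") <- sprintf(
      "target MAF >= %.4g then uniform thinning to density %.3g",
      config@arrayMafThreshold, config@arrayDensity)
    targets[[cname]] <- tg
    masks[[cname]] <- typed
  }
  structure(list(panel = panel, targets = targets, masks = masks, config = config),
            class = "benchDataset")
}

#' @export
print.benchDataset <- function(x, ...) {
  cat(sprintf("benchDataset: panel %d haplotypes x %d sites; cohorts: %s\n",
              nHaplotypes(x$panel), nSites(x$panel),
              paste(sprintf("%s (%d ind, %d typed sites)", names(x$targets),
                            vapply(x$targets, function(t) nHaplotypes(t) %/% 2L, integer(1)),
                            lengths(x$masks)), collapse = ", ")))
  invisible(x)
}

#' Simulate several independent regions
#'
#' Builds \code{nRegions} datasets under the same configuration with
#' region-specific chromosome names and deterministically fanned-out seeds
#' (seed + 101 * regionIndex), emulating evaluation across a handful of
#' multi-megabase regions.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param nRegions number of regions.
#' @return list of \code{benchDataset}.
#' @export
simulateRegions <- function(config, nRegions = 3L) {
  lapply(seq_len(nRegions), function(i) {
    cfg <- config
    cfg@chrom <- sprintf("chr%d", i)
    cfg@seed <- config@seed + 101L * i
    buildDataset(cfg)
  })
}

#' Simulate an unlinked genotype dosage matrix
#'
#' Convenience generator for association-calibration experiments: site
#' frequencies from the truncated 1/f spectrum, restricted to
#' \code{mafMin}, genotypes drawn as Binomial(2, f) per individual under
#' Hardy-Weinberg with no linkage.
#'
#' @param nInd number of diploid individuals.
#' @param nSites number of variants to return.
#' @param mafMin minimum minor allele frequency.
#' @param lower,upper spectrum bounds.
#' @return numeric matrix (individuals x sites) of genotype counts with an
#'   attribute \code{freq} of the generating allele frequencies.
#' @export
simulateGenotypeMatrix <- function(nInd, nSites, mafMin = 0.01, lower = 1e-3, upper = 0.5) {
  f <- numeric(0)
  while (length(f) < nSites) {
    draw <- rFreqSpectrum(2L * nSites, lower, upper)
    f <- c(f, draw[pmin(draw, 1 - draw) >= mafMin])
  }
  f <- f[seq_len(nSites)]
  g <- matrix(stats::rbinom(nInd * nSites, 2L, rep(f, each = nInd)), nrow = nInd)
  attr(g, "freq") <- f
  g
}
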