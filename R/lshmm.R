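## Li-Stephens haplotype-copying HMM imputation engine.
##
## The hidden state at each typed marker is the reference haplotype being
## copied; transitions mix a "stay" mass with a uniform switch mass tau that
## grows with physical distance, emissions allow a small copy error epsilon.
## The forward-backward recursion is scaled per site so panels of 10^4
## haplotypes and 10^5 markers run without underflow.

.switchProbs <- function(positions, params) {
  pmax(params@minSwitch, 1 - exp(-params@recombScale * diff(positions) / 1e6))
}

#' Forward-backward state posteriors over typed sites
#'
#' Standard scaled Li-Stephens forward-backward. The transition between
#' consecutive typed markers at distance d Mb places switch mass
#' tau = max(minSwitch, 1 - exp(-recombScale * d)) uniformly over the H
#' reference haplotypes (so the current state retains 1 - tau + tau/H);
#' emissions are 1 - epsilon on allele match and epsilon on mismatch; the
#' copying prior is uniform over reference haplotypes.
#'
#' @param targetHap 0/1 vector of the target haplotype at the typed sites.
#' @param panelAlleles reference haplotype-by-site 0/1 matrix restricted to
#'   the typed sites (H x M, H >= 2).
#' @param positions base-pair positions of the typed sites.
#' @param params \linkS4class{HmmParams}.
#' @return numeric matrix (site x reference haplotype) of state posteriors;
#'   every row sums to 1.
#' @export
forwardBackward <- function(targetHap, panelAlleles, positions, params) {
  M <- length(targetHap)
  H <- nrow(panelAlleles)
  if (M < 1L) stop("at least one typed site is required")
  if (H < 2L) stop("at least two reference haplotypes are required")
  stopifnot(ncol(panelAlleles) == M, length(positions) == M)
  eps <- params@copyError
  ta <- t(panelAlleles)                       # M x H
  emis <- matrix(eps, M, H)
  emis[ta == targetHap] <- 1 - eps            # recycles targetHap down columns
  tau <- .switchProbs(positions, params)
  f <- matrix(0, M, H)
  cs <- numeric(M)
  v <- emis[1L, ] / H
  cs[1L] <- sum(v)
  f[1L, ] <- v / cs[1L]
  if (M > 1L) {
    for (m in 2:M) {
      pred <- (1 - tau[m - 1L]) * f[m - 1L, ] + tau[m - 1L] / H
      v <- pred * emis[m, ]
      cs[m] <- sum(v)
      f[m, ] <- v / cs[m]
    }
  }
  b <- matrix(0, M, H)
  b[M, ] <- 1
  if (M > 1L) {
    for (m in (M - 1L):1L) {
      u <- emis[m + 1L, ] * b[m + 1L, ]
      b[m, ] <- ((1 - tau[m]) * u + tau[m] / H * sum(u)) / cs[m + 1L]
    }
  }
  post <- f * b
  post / rowSums(post)
}

#' Linear interpolation of state posteriors to untyped sites
#'
#' At an untyped site strictly between typed neighbours at distances dL and
#' dR, each state's posterior is the linear blend with weights dR/(dL+dR) on
#' the left flank and dL/(dL+dR) on the right; outside the typed range the
#' nearest typed posterior is used; rows are renormalised. Physical distance
#' proxies genetic distance (the simulator has no genetic map).
#'
#' @param postTyped posterior matrix over typed sites (from
#'   [forwardBackward()]).
#' @param typedPositions positions of the typed sites (subset of
#'   \code{allPositions}).
#' @param allPositions positions of all sites to interpolate to.
#' @return posterior matrix over all sites; rows sum to 1.
#' @export
interpolatePosteriors <- function(postTyped, typedPositions, allPositions) {
  if (!all(typedPositions %in% allPositions))
    stop("typed positions must be a subset of all positions")
  w <- .interpWeights(typedPositions, allPositions)
  post <- w$wL * postTyped[w$L, , drop = FALSE] +
    w$wR * postTyped[w$R, , drop = FALSE]
  post / rowSums(post)
}

## shared mapping: for every all-site, flanking typed row indices and weights
.interpWeights <- function(typedPositions, allPositions) {
  Mt <- length(typedPositions)
  idx <- findInterval(allPositions, typedPositions)
  L <- pmax(idx, 1L)
  R <- pmin(idx + 1L, Mt)
  exact <- idx >= 1L & allPositions == typedPositions[L]
  R[exact] <- L[exact]
  dL <- allPositions - typedPositions[L]
  dR <- typedPositions[R] - allPositions
  wL <- ifelse(L == R, 1, dR / (dL + dR))
  list(L = L, R = R, wL = wL, wR = 1 - wL)
}

#' Haplotype dosages from state posteriors
#'
#' Dosage at site s is the posterior-weighted mean of the reference alleles:
#' sum_j posterior(s, j) * allele(j, s).
#'
#' @param post posterior matrix (site x reference haplotype).
#' @param panelAlleles reference haplotype-by-site matrix over the same sites.
#' @return numeric vector of per-site haplotype dosages in [0, 1].
#' @export
dosageFromPosteriors <- function(post, panelAlleles) {
  stopifnot(nrow(post) == ncol(panelAlleles), ncol(post) == nrow(panelAlleles))
  rowSums(post * t(panelAlleles))
}

#' Estimated imputation R-squared at one site
#'
#' The standard imputation-software quality metric: the ratio of the observed
#' (population) variance of the haplotype dosages to the binomial variance
#' p(1-p) expected from the estimated allele frequency p (the mean haplotype
#' dosage). Returns 0 for monomorphic estimates (p of 0 or 1); the ratio is
#' not capped at 1. With \code{diploid = TRUE} the same ratio is computed on
#' genotype dosages with denominator 2p(1-p).
#'
#' @param dosages numeric vector of per-haplotype dosages (length >= 2), or
#'   genotype dosages when \code{diploid = TRUE}.
#' @param diploid compute the genotype-dosage variant.
#' @return scalar estimated R-squared (>= 0).
#' @export
estimatedR2 <- function(dosages, diploid = FALSE) {
  if (length(dosages) < 2L) stop("need at least two dosages")
  mu <- mean(dosages)
  p <- if (diploid) mu / 2 else mu
  denom <- (if (diploid) 2 else 1) * p * (1 - p)
  if (denom <= 0) return(0)
  mean((dosages - mu)^2) / denom
}

## dosages at all sites directly from the typed-site posterior, grouping
## untyped runs that share flanking typed markers (avoids materialising the
## full site-by-haplotype posterior per target haplotype)
.dosageAllSites <- function(postTyped, panelAlleles, w) {
  S <- length(w$L)
  out <- numeric(S)
  grp <- w$L * (max(w$R) + 1L) + w$R
  for (g in unique(grp)) {
    idx <- which(grp == g)
    L <- w$L[idx[1L]]; R <- w$R[idx[1L]]
    a <- panelAlleles[, idx, drop = FALSE]
    vL <- colSums(a * postTyped[L, ])
    if (L == R) {
      out[idx] <- vL
    } else {
      vR <- colSums(a * postTyped[R, ])
      out[idx] <- w$wL[idx] * vL + w$wR[idx] * vR
    }
  }
  out
}

#' Impute a target cohort against a reference panel
#'
#' Runs the Li-Stephens forward-backward per target haplotype over the typed
#' sites, interpolates state posteriors to every panel site, converts them to
#' haplotype and genotype dosages, and computes the per-site estimated
#' R-squared from the cohort's haplotype dosages. Fully deterministic.
#'
#' @param target \linkS4class{HaplotypePanel} of target haplotypes; either
#'   already restricted to the typed sites, or full-size with \code{typedIdx}
#'   giving the typed columns.
#' @param panel reference \linkS4class{HaplotypePanel}; its site universe
#'   defines the output sites. Typed sites must match panel sites on
#'   chrom/pos with identical ref/alt alleles.
#' @param params \linkS4class{HmmParams}.
#' @param typedIdx optional integer columns of \code{target} that are typed.
#' @return a \linkS4class{DosageResult} over all panel sites.
#' @export
imputeCohort <- function(target, panel, params = HmmParams(), typedIdx = NULL) {
  stopifnot(is(target, "HaplotypePanel"), is(panel, "HaplotypePanel"))
  if (!is.null(typedIdx)) target <- target[, typedIdx]
  keyT <- paste(target@chrom, target@positions)
  keyP <- paste(panel@chrom, panel@positions)
  mt <- match(keyT, keyP)
  if (anyNA(mt))
    stop("typed sites absent from the panel: ",
         paste(utils::head(siteIds(target)[is.na(mt)], 3L), collapse = ", "))
  bad <- target@ref != panel@ref[mt] | target@alt != panel@alt[mt]
  if (any(bad))
    stop("allele mismatch between target and panel at site ",
         siteIds(target)[which(bad)[1L]])
  H <- nHaplotypes(panel)
  nHapT <- nHaplotypes(target)
  if (nHapT %% 2L != 0L) stop("target must contain diploid haplotype pairs")
  S <- nSites(panel)
  panelTyped <- panel@alleles[, mt, drop = FALSE]
  typedPos <- panel@positions[mt]
  w <- .interpWeights(typedPos, panel@positions)
  hd <- matrix(0, nHapT, S)
  for (h in seq_len(nHapT)) {
    postT <- forwardBackward(target@alleles[h, ], panelTyped, typedPos, params)
    hd[h, ] <- .dosageAllSites(postT, panel@alleles, w)
  }
  hd[hd < 0] <- 0
  hd[hd > 1] <- 1
  odd <- seq(1L, nHapT, by = 2L)
  gd <- hd[odd, , drop = FALSE] + hd[odd + 1L, , drop = FALSE]
  r2 <- vapply(seq_len(S), function(s) estimatedR2(hd[, s]), numeric(1))
  typed <- logical(S)
  typed[mt] <- TRUE
  new("DosageResult", haplotypeDosage = hd, genotypeDosage = gd, estR2 = r2,
      typed = typed, positions = panel@positions, chrom = panel@chrom,
      ref = panel@ref, alt = panel@alt, siteIds = panel@siteIds,
      sampleIds = target@sampleIds[odd])
}
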