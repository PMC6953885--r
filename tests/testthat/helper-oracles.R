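# Independent oracles and small fixture builders shared across tests.

# Brute-force Li-Stephens posterior by exhaustive enumeration of all H^M
# copying paths; tractable for H, M <= 6. Kept deliberately naive and
# independent of the package's forward-backward implementation (only the
# model definition -- transition/emission probabilities -- is shared).
bruteForcePosterior <- function(targetHap, panelAlleles, positions, params) {
  H <- nrow(panelAlleles)
  M <- length(targetHap)
  eps <- params@copyError
  tau <- pmax(params@minSwitch,
              1 - exp(-params@recombScale * diff(positions) / 1e6))
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), M)))
  logp <- rep(log(1 / H), nrow(paths))
  for (m in seq_len(M)) {
    match <- panelAlleles[cbind(paths[, m], m)] == targetHap[m]
    logp <- logp + log(ifelse(match, 1 - eps, eps))
    if (m < M) {
      stay <- paths[, m] == paths[, m + 1L]
      logp <- logp + log(ifelse(stay, 1 - tau[m] + tau[m] / H, tau[m] / H))
    }
  }
  w <- exp(logp - max(logp))
  post <- matrix(0, M, H)
  for (m in seq_len(M))
    post[m, ] <- vapply(seq_len(H), function(j) sum(w[paths[, m] == j]), numeric(1))
  post / rowSums(post)
}

# a small but imputation-friendly simulation config for unit tests
smallConfig <- function(nSites = 200L, nPanel = 120L, nInd = 12L, seed = 1L,
                        regionLengthBp = 2e6, ...) {
  SimConfig(nSites = as.integer(nSites), nPanelHaplotypes = as.integer(nPanel),
            foundersPerPool = 30L, regionLengthBp = regionLengthBp,
            targetCohorts = list(AA = list(n = as.integer(nInd),
                                           admixture = admixturePreset("AA"))),
            seed = as.integer(seed), ...)
}

# random per-variant quality records for QC property tests
randomQualityRecords <- function(n, seed) {
  set.seed(seed)
  maf <- imputeBench::rFreqSpectrum(n, 1e-4, 0.5)
  data.frame(siteId = sprintf("chr1:%d:A:C", seq_len(n)),
             pos = seq_len(n),
             typed = FALSE,
             targetMaf = maf,
             targetMac = pmax(1L, round(maf * 1000)),
             eafDosage = maf,
             panelMac = sample(1:200, n, replace = TRUE),
             estR2 = pmin(1, pmax(0, stats::rbeta(n, 2, 0.8))),
             trueR2 = stats::runif(n),
             mafBin = imputeBench::assignMafBin(maf))
}
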