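## Post-imputation quality evaluation: true R2 against held-out genotypes,
## seven-MAF-bin adaptive thresholds targeting a mean quality of 0.8 among
## passing variants, heterozygote concordance, MAC-stratified rescue tables,
## genome-wide extrapolation from a few core regions, and filtering
## stringency curves.

#' True imputation R-squared at one site
#'
#' Squared Pearson correlation between the imputed genotype dosages and the
#' true genotype counts; undefined (NA) when either vector is constant.
#'
#' @param dosages per-individual genotype dosages at one site.
#' @param truth per-individual true genotype counts in \{0,1,2\}.
#' @return scalar in [0,1], or NA when undefined.
#' @export
trueR2 <- function(dosages, truth) {
  stopifnot(length(dosages) == length(truth), length(truth) >= 2L)
  if (stats::sd(dosages) == 0 || stats::sd(truth) == 0) return(NA_real_)
  stats::cor(dosages, truth)^2
}

.mafBinBreaks <- c(0.0005, 0.002, 0.005, 0.01, 0.03, 0.05)

#' MAF bin labels
#' @return character vector of the seven bin labels.
#' @export
mafBinLabels <- function() {
  c("<0.05%", "0.05-0.2%", "0.2-0.5%", "0.5-1%", "1-3%", "3-5%", ">5%")
}

#' Assign the seven-category MAF bin
#'
#' Bins are left-closed/right-open at the interior boundaries:
#' [0, 0.05%), [0.05%, 0.2%), [0.2%, 0.5%), [0.5%, 1%), [1%, 3%), [3%, 5%),
#' [5%, 50%]. A MAF exactly at a printed boundary therefore falls in the
#' higher bin.
#'
#' @param maf minor allele frequency in (0, 0.5]; vectorised.
#' @return integer bin 1..7.
#' @export
assignMafBin <- function(maf) {
  if (any(maf <= 0) || any(maf > 0.5)) stop("MAF must lie in (0, 0.5]")
  findInterval(maf, .mafBinBreaks) + 1L
}

#' Select the per-bin estimated R-squared threshold
#'
#' Candidate thresholds are 0 plus the sorted unique observed values; the
#' smallest threshold t such that the mean of all values >= t reaches
#' \code{targetMean} is returned (0 when the overall mean already suffices);
#' NA (the "none-pass" sentinel) when even the largest observed value falls
#' short, i.e. the passing set must be empty.
#'
#' @param r2Values observed quality values in one MAF bin (nonempty).
#' @param targetMean required mean among passing variants (default 0.8).
#' @return scalar threshold, or NA for none-pass.
#' @export
selectBinThreshold <- function(r2Values, targetMean = 0.8) {
  stopifnot(length(r2Values) >= 1L)
  vs <- sort(r2Values, decreasing = TRUE)
  u <- unique(vs)
  last <- cumsum(tabulate(match(vs, u)))   # index of last occurrence per unique value
  means <- cumsum(vs)[last] / last         # mean of {r >= u_i}, non-increasing in i
  ok <- which(means >= targetMean)
  if (!length(ok)) return(NA_real_)
  k <- max(ok)                             # smallest qualifying candidate
  if (k == length(u)) return(0)
  u[k]
}

#' Evaluate an imputed cohort against truth
#'
#' Builds the per-variant quality table: target MAF/MAC from the truth
#' genotypes, dosage-estimated allele frequency, reference-panel MAC,
#' estimated and true R-squared, and the MAF bin. Sites monomorphic in the
#' target truth are excluded (their MAF bin and true R2 are undefined); the
#' exclusion count is kept in attribute \code{nExcludedMonomorphic}.
#'
#' @param dosage a \linkS4class{DosageResult}.
#' @param truth truth \linkS4class{HaplotypePanel} over the same sites.
#' @param panel reference \linkS4class{HaplotypePanel} (for panel MAC).
#' @param includeTyped keep array-typed sites (default FALSE: evaluate
#'   imputed sites only).
#' @param coreRange optional c(lo, hi) positions; evaluation is restricted to
#'   this core window (imputation having used the full flanked region).
#' @return data.frame with one row per evaluated variant: siteId, pos, typed,
#'   targetMaf, targetMac, eafDosage, panelMac, estR2, trueR2, mafBin.
#' @export
evaluateImputation <- function(dosage, truth, panel, includeTyped = FALSE,
                               coreRange = NULL) {
  stopifnot(is(dosage, "DosageResult"), is(truth, "HaplotypePanel"))
  if (!identical(siteIds(dosage), siteIds(truth)))
    stop("dosage and truth must cover identical sites; mismatched truth")
  geno <- genotypeMatrix(truth)
  gd <- genotypeDosage(dosage)
  stopifnot(nrow(geno) == nrow(gd))
  n2 <- 2L * nrow(geno)
  alt <- colSums(geno)
  mac <- pmin(alt, n2 - alt)
  keep <- mac > 0L
  if (!includeTyped) keep <- keep & !typedSites(dosage)
  if (!is.null(coreRange))
    keep <- keep & sitePositions(dosage) >= coreRange[1] & sitePositions(dosage) <= coreRange[2]
  nMono <- sum(mac == 0L)
  idx <- which(keep)
  tr2 <- vapply(idx, function(s) trueR2(gd[, s], geno[, s]), numeric(1))
  pAlt <- colSums(alleleMatrix(panel))
  panelMac <- pmin(pAlt, nHaplotypes(panel) - pAlt)
  out <- data.frame(
    siteId = siteIds(dosage)[idx],
    pos = sitePositions(dosage)[idx],
    typed = typedSites(dosage)[idx],
    targetMaf = mac[idx] / n2,
    targetMac = mac[idx],
    eafDosage = colMeans(gd[, idx, drop = FALSE]) / 2,
    panelMac = panelMac[idx],
    estR2 = estR2(dosage)[idx],
    trueR2 = tr2,
    stringsAsFactors = FALSE)
  out$mafBin <- assignMafBin(out$targetMaf)
  attr(out, "nExcludedMonomorphic") <- nMono
  rownames(out) <- NULL
  out
}

#' Compute adaptive per-MAF-bin QC thresholds
#'
#' Applies [selectBinThreshold()] within each of the seven MAF bins on the
#' chosen metric (estimated R2 by default; true R2 optionally, with undefined
#' values dropped). Bins with no variants get the none-pass sentinel.
#'
#' @param records quality table from [evaluateImputation()].
#' @param targetMean required mean among passers (default 0.8).
#' @param metric "estimated" or "true".
#' @return a \linkS4class{QCThresholds}.
#' @export
computeThresholds <- function(records, targetMean = 0.8,
                              metric = c("estimated", "true")) {
  metric <- match.arg(metric)
  vals <- if (metric == "estimated") records$estR2 else records$trueR2
  th <- rep(NA_real_, 7L)
  summ <- data.frame(bin = 1:7, label = mafBinLabels(), n = 0L,
                     threshold = NA_real_, stringsAsFactors = FALSE)
  for (b in 1:7) {
    v <- vals[records$mafBin == b & !is.na(vals)]
    summ$n[b] <- length(v)
    if (length(v)) th[b] <- selectBinThreshold(v, targetMean)
  }
  summ$threshold <- th
  new("QCThresholds", thresholds = th, targetMean = targetMean,
      metric = metric, binSummary = summ)
}

#' Apply QC thresholds to a quality table
#'
#' Sets \code{qcPass = metric >= threshold(bin)}; every variant in a
#' none-pass bin fails. Attaches a per-bin summary (counts, pass counts,
#' achieved mean of the thresholded metric among passers) as attribute
#' \code{binSummary}.
#'
#' @param records quality table from [evaluateImputation()].
#' @param thresholds a \linkS4class{QCThresholds} computed on the same
#'   cohort/panel.
#' @return \code{records} with a logical \code{qcPass} column.
#' @export
applyQC <- function(records, thresholds) {
  stopifnot(is(thresholds, "QCThresholds"))
  if (any(is.na(records$mafBin))) stop("records with unassigned MAF bin")
  vals <- if (thresholds@metric == "estimated") records$estR2 else records$trueR2
  th <- thresholds@thresholds[records$mafBin]
  records$qcPass <- !is.na(th) & !is.na(vals) & vals >= th
  summ <- do.call(rbind, lapply(1:7, function(b) {
    inBin <- records$mafBin == b
    pass <- inBin & records$qcPass
    data.frame(bin = b, label = mafBinLabels()[b], n = sum(inBin),
               nPass = sum(pass),
               threshold = thresholds@thresholds[b],
               meanMetricPass = if (any(pass)) mean(vals[pass]) else NA_real_,
               meanTrueR2Pass = if (any(pass)) mean(records$trueR2[pass], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(records, "binSummary") <- summ
  records
}

#' Heterozygote concordance
#'
#' Among (individual, site) pairs whose true genotype is heterozygous --
#' generally the hardest to impute -- the fraction whose hard-called dosage
#' (nearest integer, ties to even) equals 1.
#'
#' @param dosages genotype-dosage matrix or vector.
#' @param truth matching true genotype counts.
#' @return fraction in [0,1], or NA when there are no true heterozygotes.
#' @export
hetConcordance <- function(dosages, truth) {
  stopifnot(length(dosages) == length(truth))
  het <- which(truth == 1L)
  if (!length(het)) {
    warning("no true heterozygotes; concordance undefined")
    return(NA_real_)
  }
  mean(round(dosages[het]) == 1)
}

#' MAC-stratified imputation quality table
#'
#' One row per target minor allele count 1..\code{macMax}, restricted to
#' variants with reference-panel MAC strictly above \code{panelMacFloor}
#' (variants rarer than that in the panel are not evaluated, mirroring the
#' panel's own allele-count exclusion). The MAC = 1 row captures cohort
#' singletons that are present in multiple copies in the reference panel.
#'
#' @param records QC'd quality table (needs targetMac, panelMac, estR2,
#'   trueR2, qcPass).
#' @param macMax largest target MAC row (default 10).
#' @param panelMacFloor panel-MAC exclusion floor (default 5, i.e. keep
#'   panel MAC > 5).
#' @return data.frame with columns mac, nVariants, nQcPass, avgPanelMacAll,
#'   avgPanelMacPass, avgEstR2, avgTrueR2 (averages NA over empty sets; true
#'   R2 averaged over defined values only).
#' @export
macStratifiedTable <- function(records, macMax = 10L, panelMacFloor = 5L) {
  r <- records[records$panelMac > panelMacFloor, , drop = FALSE]
  do.call(rbind, lapply(seq_len(macMax), function(m) {
    rm <- r[r$targetMac == m, , drop = FALSE]
    pass <- rm[rm$qcPass, , drop = FALSE]
    data.frame(
      mac = m,
      nVariants = nrow(rm),
      nQcPass = nrow(pass),
      avgPanelMacAll = if (nrow(rm)) mean(rm$panelMac) else NA_real_,
      avgPanelMacPass = if (nrow(pass)) mean(pass$panelMac) else NA_real_,
      avgEstR2 = if (nrow(rm)) mean(rm$estR2) else NA_real_,
      avgTrueR2 = if (any(!is.na(rm$trueR2))) mean(rm$trueR2, na.rm = TRUE) else NA_real_)
  }))
}

#' Extrapolate a genome-wide well-imputed count from core regions
#'
#' Scales the summed pass counts observed in a few evaluated core regions to
#' a genome-wide span: estimate = sum(coreCounts) * genomeSpanBp /
#' coreSpanBp. The evaluation harness imputes each region with flanking
#' sequence and counts only core-region variants.
#'
#' @param coreCounts per-region pass counts.
#' @param coreSpanBp total evaluated core span in bp (> 0).
#' @param genomeSpanBp genome span to scale to (default 2.88 Gb autosomes).
#' @return scalar estimate.
#' @export
extrapolateWellImputed <- function(coreCounts, coreSpanBp, genomeSpanBp = 2.88e9) {
  if (coreSpanBp <= 0) stop("core span must be positive")
  sum(coreCounts) * genomeSpanBp / coreSpanBp
}

#' Filtering stringency curve
#'
#' For each estimated-R2 cutoff on a grid: the number of surviving variants
#' and their mean true R2 (over defined values). Counts are non-increasing in
#' the cutoff by construction.
#'
#' @param records quality table.
#' @param r2Grid cutoffs in [0,1].
#' @return data.frame with columns cutoff, n, meanTrueR2.
#' @export
stringencyCurve <- function(records, r2Grid = seq(0, 0.95, by = 0.05)) {
  stopifnot(all(r2Grid >= 0 & r2Grid <= 1))
  do.call(rbind, lapply(sort(r2Grid), function(cut) {
    keep <- records$estR2 >= cut
    data.frame(cutoff = cut, n = sum(keep),
               meanTrueR2 = if (any(keep & !is.na(records$trueR2)))
                 mean(records$trueR2[keep], na.rm = TRUE) else NA_real_)
  }))
}

#' Multi-panel comparison report
#'
#' Evaluates several imputation runs of the same target cohort (identical
#' truth and site universe), recomputing the adaptive QC thresholds per
#' panel, and reports per-panel totals, pass counts and mean true R2 in
#' MAF strata, plus pass-count fold changes of every panel relative to a
#' baseline panel.
#'
#' @param recordsList named list of quality tables (one per panel) from
#'   [evaluateImputation()] on the same cohort.
#' @param targetMean,metric threshold rule, as in [computeThresholds()].
#' @param strata named list of MAF intervals \code{c(lo, hi)}, applied as
#'   lo <= MAF < hi; defaults to all, MAF < 0.5\% and MAF < 0.05\%.
#' @param baseline name of the reference panel for fold changes (default the
#'   last element, conventionally the smaller panel).
#' @return list with \code{table} (per panel x stratum: nPass, meanTrueR2)
#'   and \code{folds} (pass-count fold change vs baseline).
#' @export
panelComparisonReport <- function(recordsList, targetMean = 0.8,
                                  metric = "estimated",
                                  strata = list(all = c(0, 0.51),
                                                "maf<0.5%" = c(0, 0.005),
                                                "maf<0.05%" = c(0, 0.0005)),
                                  baseline = names(recordsList)[length(recordsList)]) {
  ids <- lapply(recordsList, function(r) sort(r$siteId))
  if (length(ids) > 1L && !all(vapply(ids[-1L], identical, logical(1), ids[[1L]])))
    stop("panels must be evaluated on an identical target cohort and site universe")
  qcd <- lapply(recordsList, function(r) applyQC(r, computeThresholds(r, targetMean, metric)))
  tab <- do.call(rbind, lapply(names(qcd), function(pn) {
    r <- qcd[[pn]]
    do.call(rbind, lapply(names(strata), function(sn) {
      s <- strata[[sn]]
      keep <- r$targetMaf >= s[1] & r$targetMaf < s[2]
      pass <- keep & r$qcPass
      data.frame(panel = pn, stratum = sn, n = sum(keep), nPass = sum(pass),
                 meanTrueR2 = if (any(pass & !is.na(r$trueR2)))
                   mean(r$trueR2[pass], na.rm = TRUE) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  base <- tab[tab$panel == baseline, c("stratum", "nPass")]
  folds <- do.call(rbind, lapply(unique(tab$panel), function(pn) {
    t1 <- tab[tab$panel == pn, ]
    data.frame(panel = pn, stratum = t1$stratum,
               foldVsBaseline = t1$nPass / base$nPass[match(t1$stratum, base$stratum)],
               stringsAsFactors = FALSE)
  }))
  list(table = tab, folds = folds)
}
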