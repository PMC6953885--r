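test_that("true R2 is the squared Pearson correlation with truth", {
  truth <- c(0, 1, 2, 1, 0)
  expect_equal(trueR2(truth, truth), 1)
  expect_true(is.na(trueR2(rep(0.4, 5), truth)))
  d <- c(0.1, 0.9, 1.8)
  expect_equal(trueR2(d, c(0, 1, 2)), cor(d, c(0, 1, 2))^2)
})

test_that("MAF bins are left-closed/right-open at the printed boundaries", {
  expect_identical(assignMafBin(0.0004), 1L)
  expect_identical(assignMafBin(0.0005), 2L)
  expect_identical(assignMafBin(0.002), 3L)
  expect_identical(assignMafBin(0.005), 4L)
  expect_identical(assignMafBin(0.01), 5L)
  expect_identical(assignMafBin(0.03), 6L)
  expect_identical(assignMafBin(0.05), 7L)
  expect_identical(assignMafBin(0.5), 7L)
  expect_error(assignMafBin(0), "MAF")
  expect_error(assignMafBin(0.6), "MAF")
})

test_that("threshold selection enforces the mean-0.8 rule", {
  expect_equal(selectBinThreshold(c(0.9, 0.9, 0.9)), 0)
  expect_true(is.na(selectBinThreshold(c(0.7, 0.6))))
  expect_equal(selectBinThreshold(c(0.9, 0.6)), 0.9)
  # ties: the passing set {r >= t} includes every duplicate of t, so 0.8
  # cannot qualify at target 0.85 (mean 0.833) and the answer is 0.9
  expect_equal(selectBinThreshold(c(0.9, 0.8, 0.8), targetMean = 0.85), 0.9)
  # exhaustive check against the definition on random vectors
  set.seed(21)
  for (i in 1:30) {
    v <- round(runif(sample(1:40, 1)), 2)
    t <- selectBinThreshold(v)
    cand <- c(0, sort(unique(v)))
    ok <- cand[vapply(cand, function(ct) mean(v[v >= ct]) >= 0.8, logical(1))]
    if (is.na(t)) expect_length(ok, 0) else expect_equal(t, min(ok))
  }
})

test_that("applyQC matches a per-record re-evaluation and handles none-pass bins", {
  rec <- randomQualityRecords(200, seed = 31)
  rec$estR2[rec$mafBin == 5] <- runif(sum(rec$mafBin == 5), 0, 0.5)  # none-pass bin
  th <- computeThresholds(rec)
  out <- applyQC(rec, th)
  manual <- mapply(function(b, r2) {
    t <- qcThresholds(th)[b]
    !is.na(t) && r2 >= t
  }, rec$mafBin, rec$estR2)
  expect_identical(out$qcPass, unname(manual))
  expect_true(all(!out$qcPass[out$mafBin == 5]))
  summ <- attr(out, "binSummary")
  passBins <- summ$nPass > 0
  expect_true(all(summ$meanMetricPass[passBins] >= 0.8))
  recAll1 <- transform(rec, estR2 = 1)
  expect_true(all(applyQC(recAll1, computeThresholds(recAll1))$qcPass))
})

test_that("heterozygote concordance uses nearest-integer ties-to-even hard calls", {
  truth <- c(1, 1, 0, 2)
  expect_equal(hetConcordance(c(1.1, 0.2, 0, 2), truth), 0.5)
  expect_equal(hetConcordance(truth, truth), 1)
  # ties-to-even: 0.5 -> 0, 1.5 -> 2, neither counts as heterozygous
  expect_equal(hetConcordance(c(0.5, 1.5, 0, 2), truth), 0)
  expect_warning(res <- hetConcordance(c(0, 2), c(0, 2)), "undefined")
  expect_true(is.na(res))
  # brute-force recount on a random fixture
  set.seed(8)
  tr <- sample(0:2, 100, replace = TRUE)
  dos <- pmin(2, pmax(0, tr + rnorm(100, 0, 0.4)))
  het <- tr == 1
  expect_equal(hetConcordance(dos, tr), sum(round(dos[het]) == 1) / sum(het))
})

test_that("MAC-stratified table matches a hand tally and applies the panel-MAC floor", {
  rec <- data.frame(
    siteId = letters[1:6], pos = 1:6, typed = FALSE,
    targetMaf = rep(0.01, 6), targetMac = c(1L, 1L, 2L, 3L, 1L, 2L),
    eafDosage = 0.01, panelMac = c(10L, 30L, 8L, 4L, 6L, 12L),
    estR2 = c(0.9, 0.8, 0.95, 0.9, 0.2, 0.85),
    trueR2 = c(0.95, NA, 0.9, 0.8, 0.1, 0.9),
    mafBin = 5L, qcPass = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  tab <- macStratifiedTable(rec, macMax = 3L)
  # panelMac = 4 record (MAC 3) excluded entirely
  expect_equal(tab$nVariants, c(3L, 2L, 0L))
  expect_equal(tab$nQcPass, c(2L, 2L, 0L))
  expect_equal(tab$avgPanelMacAll[1], mean(c(10, 30, 6)))
  expect_equal(tab$avgPanelMacPass[1], mean(c(10, 30)))
  expect_equal(tab$avgEstR2[1], mean(c(0.9, 0.8, 0.2)))
  expect_equal(tab$avgTrueR2[1], mean(c(0.95, 0.1)))   # NA true R2 excluded
  expect_true(is.na(tab$avgEstR2[3]))
  expect_true(all(tab$nQcPass <= tab$nVariants))
})

test_that("genome-wide extrapolation is the span-ratio product", {
  expect_equal(extrapolateWellImputed(c(100, 100, 100), 9e6, 2.88e9), 96000)
  expect_equal(extrapolateWellImputed(c(0, 0, 0), 9e6), 0)
  expect_error(extrapolateWellImputed(10, 0), "positive")
  set.seed(13)
  counts <- rpois(3, 50)
  expect_equal(extrapolateWellImputed(counts, 9e6, 2.88e9),
               sum(counts) * 2.88e9 / 9e6)
})

test_that("stringency curves shrink monotonically and match brute-force filtering", {
  rec <- randomQualityRecords(120, seed = 41)
  grid <- c(0, 0.5, 0.9)
  sc <- stringencyCurve(rec, grid)
  expect_equal(sc$n[1], nrow(rec))
  expect_true(all(diff(sc$n) <= 0))
  for (i in seq_along(grid)) {
    keep <- rec$estR2 >= grid[i]
    expect_equal(sc$n[i], sum(keep))
    expect_equal(sc$meanTrueR2[i], mean(rec$trueR2[keep]))
  }
  above <- stringencyCurve(rec, max(rec$estR2) + 1e-9)
  expect_equal(above$n, 0L)
  expect_true(is.na(above$meanTrueR2))
})

test_that("panel comparison reports unit folds for identical inputs and 2x for halved panels", {
  rec <- randomQualityRecords(300, seed = 51)
  rep1 <- panelComparisonReport(list(A = rec, B = rec))
  expect_true(all(rep1$folds$foldVsBaseline[is.finite(rep1$folds$foldVsBaseline)] == 1))

  recB <- rec
  qc <- applyQC(rec, computeThresholds(rec))
  passIdx <- which(qc$qcPass)
  kill <- passIdx[seq(2, length(passIdx), by = 2)]
  recB$estR2[kill] <- 0
  rep2 <- panelComparisonReport(list(A = rec, B = recB))
  allRow <- rep2$table[rep2$table$stratum == "all", ]
  # B passes at most half of A's passing set in the affected stratum
  expect_gte(rep2$folds$foldVsBaseline[rep2$folds$panel == "A" &
                                         rep2$folds$stratum == "all"], 1.5)
  expect_error(panelComparisonReport(list(A = rec, B = rec[-1, ])),
               "identical target cohort")
})

test_that("self-consistency: truth-equal dosages give perfect quality", {
  cfg <- smallConfig(nInd = 10L, seed = 17L)
  ds <- buildDataset(cfg)
  truth <- ds$targets$AA
  g <- genotypeMatrix(truth)
  hd <- alleleMatrix(truth) * 1.0
  odd <- seq(1L, nrow(hd), 2L)
  dose <- new("DosageResult", haplotypeDosage = hd,
              genotypeDosage = hd[odd, ] + hd[odd + 1L, ],
              estR2 = apply(hd, 2, estimatedR2), typed = rep(FALSE, ncol(hd)),
              positions = sitePositions(truth), chrom = truth@chrom,
              ref = truth@ref, alt = truth@alt, siteIds = siteIds(truth),
              sampleIds = sampleIds(truth)[odd])
  rec <- evaluateImputation(dose, truth, ds$panel)
  expect_equal(rec$trueR2, rep(1, nrow(rec)), tolerance = 1e-12)
  expect_equal(hetConcordance(as.vector(genotypeDosage(dose)), as.vector(g)), 1)
})
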