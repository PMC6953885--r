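test_that("phenotype cleaning applies strict bounds and the WBC-subtype rule", {
  tb <- data.frame(sampleId = sprintf("s%d", 1:5),
                   WBC = c(250, 6, 7, 5, 8),
                   NEU = c(4, 3, 2, 3, 4),
                   HCT = c(40, 60, 61, 45, 44),
                   HGB = c(14, 13, 15, 21, 20))
  expect_equal(cleanPhenotypes(tb, "WBC")$sampleId, c("s2", "s3", "s4", "s5"))
  # subtype analysis drops individuals whose total WBC exceeded the bound
  expect_equal(cleanPhenotypes(tb, "NEU")$sampleId, c("s2", "s3", "s4", "s5"))
  # HCT = 60 retained (strict >), 61 removed
  expect_equal(cleanPhenotypes(tb, "HCT")$sampleId, c("s1", "s2", "s4", "s5"))
  # HGB = 20 retained, 21 removed
  expect_equal(cleanPhenotypes(tb, "HGB")$sampleId, c("s1", "s2", "s3", "s5"))
  expect_equal(attr(cleanPhenotypes(tb, "HCT"), "nRemoved"), 1L)
  empty <- tb[0, ]
  expect_equal(nrow(cleanPhenotypes(empty, "WBC")), 0L)
  expect_error(cleanPhenotypes(tb, "RBC"), "unknown trait")
})

test_that("trait transformation logs WBC-family traits only", {
  expect_equal(transformTrait(1, "WBC"), 0)
  expect_equal(transformTrait(exp(1), "WBC"), 1)
  expect_equal(transformTrait(14.2, "HGB"), 14.2)
  expect_equal(transformTrait(c(2, 4), "LYM"), log(c(2, 4)))
  expect_error(transformTrait(c(1, 0), "WBC"), "nonpositive")
})

test_that("inverse-normal transform hits the exact normal quantiles", {
  # unevenly spaced covariate so the three residuals are distinct
  covar <- data.frame(age = c(30, 40, 60))
  out <- residualizeInverseNormalize(c(1, 5, 2), covar)
  expect_equal(sort(out), qnorm(c(1, 3, 5) / 6), tolerance = 1e-4)
  expect_equal(sort(out), c(-0.9674, 0, 0.9674), tolerance = 1e-4)
  # rank preservation under a monotone setting
  set.seed(2)
  y <- rnorm(50); x <- rnorm(50)
  o <- residualizeInverseNormalize(y, data.frame(x = x))
  res <- lm(y ~ x)$residuals
  expect_identical(rank(o), unname(rank(res)))
  # perfect fit: all residual ranks tied, transform ~ 0
  expect_equal(residualizeInverseNormalize(x, data.frame(x = x)),
               rep(0, 50), tolerance = 1e-6)
  expect_error(residualizeInverseNormalize(y, data.frame(a = x, b = 2 * x)),
               "collinear.*b")
})

test_that("single-variant OLS matches the closed-form and lm oracles", {
  set.seed(5)
  d <- c(0, 1, 2, 1, 0, 2, 1, 1)
  y <- 2 * d
  res <- singleVariantTest(d, y, minMac = 1)
  expect_equal(res$beta, 2, tolerance = 1e-12)
  expect_lt(res$p, 1e-200)

  y2 <- c(1.2, 0.4, 2.5, 1.9, 0.2, 2.2, 1.4, 0.9)
  res2 <- singleVariantTest(d, y2, minMac = 1)
  # textbook simple-regression formulas
  bHat <- sum((d - mean(d)) * (y2 - mean(y2))) / sum((d - mean(d))^2)
  resid <- y2 - mean(y2) - bHat * (d - mean(d))
  seHat <- sqrt(sum(resid^2) / (8 - 2) / sum((d - mean(d))^2))
  expect_equal(res2$beta, bHat, tolerance = 1e-12)
  expect_equal(res2$se, seHat, tolerance = 1e-12)
  sm <- summary(lm(y2 ~ d))$coefficients
  expect_equal(res2$beta, sm["d", 1])
  expect_equal(res2$se, sm["d", 2])
  expect_equal(res2$eaf, mean(d) / 2)

  covar <- data.frame(age = rnorm(8))
  res3 <- singleVariantTest(d, y2, covariates = covar, minMac = 1)
  sm3 <- summary(lm(y2 ~ d + age, data = cbind(covar, y2 = y2)))$coefficients
  expect_equal(res3$beta, sm3["d", 1])
  expect_equal(res3$se, sm3["d", 2])
})

test_that("variants are skipped below the MAC threshold or with constant dosage", {
  y <- rnorm(20)
  expect_true(singleVariantTest(c(1, rep(0, 19)), y, minMac = 5)$skipped)
  expect_match(singleVariantTest(c(1, rep(0, 19)), y, minMac = 5)$reason, "MAC")
  expect_true(singleVariantTest(rep(1, 20), y, minMac = 0)$skipped)
  # minor-allele homozygote removal drops dosage > 1.5
  d <- c(rep(0, 12), rep(1, 6), 2, 2)
  res <- singleVariantTest(d, y, minMac = 1, dropMinorHomozygotes = TRUE)
  expect_equal(res$n, 18L)
})

test_that("IVW meta-analysis obeys its identities", {
  one <- data.frame(beta = 1.3, se = 0.4, cohort = "A")
  m1 <- ivwMeta(one, minCohorts = 2)
  expect_equal(m1$beta, 1.3)
  expect_equal(m1$se, 0.4)
  expect_false(m1$tested)

  two <- data.frame(beta = c(1, 3), se = c(1, 1), cohort = c("A", "B"))
  m2 <- ivwMeta(two)
  expect_equal(m2$beta, 2)
  expect_equal(m2$se, 1 / sqrt(2))
  expect_true(m2$tested)
  expect_equal(m2$direction, "++")

  three <- data.frame(beta = c(0.5, -0.2, 1.1), se = c(0.2, 0.5, 1))
  w <- 1 / three$se^2
  m3 <- ivwMeta(three)
  expect_equal(m3$beta, sum(w * three$beta) / sum(w))
  expect_equal(m3$se, 1 / sqrt(sum(w)))
  expect_equal(m3$direction, "+-+")

  bad <- data.frame(beta = c(1, 1), se = c(1, 1), effectAllele = c("A", "C"))
  expect_error(ivwMeta(bad), "harmonized")
})

test_that("genomic lambda behaves like the median chi-square ratio", {
  expect_equal(genomicLambda(rep(0.5, 11)), 1)
  set.seed(3)
  expect_equal(genomicLambda(runif(1e6)), 1, tolerance = 0.01)
  # halving every chi-square statistic halves lambda
  chi <- rchisq(1001, df = 1)
  p1 <- pchisq(chi, 1, lower.tail = FALSE)
  p2 <- pchisq(chi / 2, 1, lower.tail = FALSE)
  expect_equal(genomicLambda(p2), genomicLambda(p1) / 2, tolerance = 1e-12)
  expect_error(genomicLambda(c(0.5, 0)), "p")
})

test_that("LD r2 is correlation-based and sign-invariant", {
  a <- c(0, 1, 2, 1, 0, 2, 1, 0)
  expect_equal(ldR2(a, a), 1)
  expect_equal(ldR2(a, 2 - a), 1)
  expect_equal(ldR2(a, rep(1, 8)), 0)
  set.seed(5)
  x <- rbinom(10000, 2, 0.3); y <- rbinom(10000, 2, 0.3)
  expect_lt(ldR2(x, y), 0.01)
})

test_that("novelty filter applies the window-and-LD rule and is monotone", {
  set.seed(7)
  g <- rbinom(400, 2, 0.3)
  flip <- function(v, k) { i <- sample(length(v), k); v[i] <- rbinom(k, 2, 0.3); v }
  geno <- cbind(known = g, linked = flip(g, 120), weak = rbinom(400, 2, 0.3),
                far = g)
  colnames(geno) <- c("k1", "h1", "h2", "h3")
  expect_gt(ldR2(geno[, "k1"], geno[, "h1"]), 0.2)
  expect_lt(ldR2(geno[, "k1"], geno[, "h2"]), 0.2)
  known <- data.frame(trait = "WBC", chrom = "chr1", pos = 5e6, siteId = "k1")
  hits <- data.frame(trait = "WBC", chrom = "chr1",
                     pos = c(5.5e6, 5.5e6, 6.5e6),
                     siteId = c("h1", "h2", "h3"))
  out <- noveltyFilter(hits, known, list(AA = geno))
  expect_equal(out$status, c("known-linked", "novel", "novel"))

  # monotonicity: raising the cut or shrinking the window never creates links
  out2 <- noveltyFilter(hits, known, list(AA = geno), r2Cut = 0.9)
  out3 <- noveltyFilter(hits, known, list(AA = geno), windowBp = 1e5)
  novel1 <- out$status == "novel"
  expect_true(all(out2$status[novel1] == "novel"))
  expect_true(all(out3$status[novel1] == "novel"))
})

test_that("significance thresholds are ancestry-specific and strict", {
  expect_true(classifySignificance(4e-9, "HL"))
  expect_false(classifySignificance(4e-9, "AA"))
  expect_false(classifySignificance(5e-9, "HL"))
  expect_false(classifySignificance(1e-9, "AA"))
  expect_true(classifySignificance(0.9e-9, "AA"))
  expect_error(classifySignificance(0.5, "EUR"), "unknown ancestry")
})
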