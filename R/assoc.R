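## Downstream association stage: phenotype cleaning and transformation,
## single-variant dosage tests, inverse-variance weighted meta-analysis,
## genomic-control lambda, LD and the known-signal novelty filter.

.wbcSubtypes <- c("NEU", "LYM", "MON", "EOS", "BAS")
.traitBounds <- c(WBC = 200, HGB = 20, HCT = 60)

#' Remove extreme phenotype outliers
#'
#' Drops rows whose trait value exceeds the clinical plausibility bound
#' (strict inequality): WBC > 200 x 10^9/L, HGB > 20 g/dL, HCT > 60%. When a
#' WBC subtype count is analysed, individuals whose total WBC exceeds 200 are
#' also removed (their subtype values are considered unusable).
#'
#' @param table data.frame with one row per sample, containing the trait
#'   column (and a WBC column when a subtype is analysed).
#' @param trait one of "WBC", "HGB", "HCT" or a WBC subtype
#'   ("NEU","LYM","MON","EOS","BAS").
#' @return filtered data.frame; the number of removed rows is in attribute
#'   \code{nRemoved}.
#' @export
cleanPhenotypes <- function(table, trait) {
  known <- c(names(.traitBounds), .wbcSubtypes)
  if (!trait %in% known) stop("unknown trait: ", trait)
  if (!nrow(table)) {
    attr(table, "nRemoved") <- 0L
    return(table)
  }
  drop <- rep(FALSE, nrow(table))
  if (trait %in% names(.traitBounds))
    drop <- drop | (!is.na(table[[trait]]) & table[[trait]] > .traitBounds[[trait]])
  if (trait %in% c("WBC", .wbcSubtypes) && "WBC" %in% names(table))
    drop <- drop | (!is.na(table$WBC) & table$WBC > .traitBounds[["WBC"]])
  drop <- drop | is.na(table[[trait]])
  out <- table[!drop, , drop = FALSE]
  attr(out, "nRemoved") <- sum(drop)
  out
}

#' Transform a trait prior to analysis
#'
#' WBC and its subtype counts are natural-log transformed (they are strongly
#' right-skewed); HGB and HCT are analysed untransformed.
#'
#' @param values numeric trait values (post-cleaning).
#' @param trait trait name as in [cleanPhenotypes()].
#' @return transformed values.
#' @export
transformTrait <- function(values, trait) {
  if (trait %in% c("WBC", .wbcSubtypes)) {
    if (any(values <= 0, na.rm = TRUE))
      stop("nonpositive ", trait, " values cannot be log transformed")
    log(values)
  } else values
}

#' Residualize on covariates and inverse-normalize
#'
#' Least-squares residuals of the trait on the covariates (with intercept),
#' then the rank-based inverse-normal transform qnorm((rank - 0.5)/n) with
#' average ranks for ties. The output preserves the residual ranks and has
#' sample mean approximately 0.
#'
#' @param values numeric trait values.
#' @param covariates data.frame or matrix of covariates (no intercept
#'   column).
#' @return analysis-ready numeric vector.
#' @export
residualizeInverseNormalize <- function(values, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- stats::lm.fit(X, values)$residuals
  n <- length(res)
  # round away sub-1e-8 numerical noise so exactly-fitted values share ranks
  stats::qnorm((rank(round(res, 8), ties.method = "average") - 0.5) / n)
}

#' Single-variant dosage association test
#'
#' Ordinary least squares of the (transformed, residualized,
#' inverse-normalized) trait on the genotype dosage, covariates and optional
#' conditioning dosages, with a Wald test against the standard normal (the
#' large-sample GWAS convention). Variants below the minor-allele-count
#' threshold or with zero dosage variance are skipped with a reason. The
#' synthetic samples are unrelated, so no kinship variance component is
#' fitted.
#'
#' @param dosages per-individual genotype dosages in [0,2].
#' @param trait analysis-ready trait values.
#' @param covariates optional covariate data.frame/matrix.
#' @param conditioning optional matrix/vector of conditioning variant
#'   dosages added as covariates (conditional analysis).
#' @param minMac minimum dosage-based minor allele count (default 5).
#' @param dropMinorHomozygotes drop individuals with dosage > 1.5 before
#'   fitting (the "removing potential minor allele homozygotes" rule for
#'   dosage data without hard calls).
#' @param cohort optional cohort label carried into the result.
#' @param siteId optional variant id carried into the result.
#' @return one-row data.frame: siteId, cohort, beta, se, z, p, eaf, mac, n,
#'   skipped, reason.
#' @export
singleVariantTest <- function(dosages, trait, covariates = NULL,
                              conditioning = NULL, minMac = 5,
                              dropMinorHomozygotes = FALSE,
                              cohort = NA_character_, siteId = NA_character_) {
  stopifnot(length(dosages) == length(trait))
  keep <- !is.na(dosages) & !is.na(trait)
  if (dropMinorHomozygotes) keep <- keep & dosages <= 1.5
  d <- dosages[keep]; y <- trait[keep]
  n <- length(d)
  skipRow <- function(reason)
    data.frame(siteId = siteId, cohort = cohort, beta = NA_real_, se = NA_real_,
               z = NA_real_, p = NA_real_, eaf = if (n) mean(d) / 2 else NA_real_,
               mac = NA_real_, n = n, skipped = TRUE, reason = reason,
               stringsAsFactors = FALSE)
  if (n < 3L) return(skipRow("too few samples"))
  ac <- sum(d)
  mac <- min(ac, 2 * n - ac)
  if (mac < minMac) return(skipRow(sprintf("MAC %.1f below threshold %g", mac, minMac)))
  if (stats::var(d) == 0) return(skipRow("zero dosage variance"))
  X <- cbind(`(Intercept)` = 1, dosage = d)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[keep, , drop = FALSE])
  if (!is.null(conditioning)) {
    cm <- as.matrix(conditioning)
    colnames(cm) <- paste0("cond", seq_len(ncol(cm)))
    X <- cbind(X, cm[keep, , drop = FALSE])
  }
  XtX <- crossprod(X)
  XtXi <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(XtXi)) return(skipRow("singular design"))
  beta <- drop(XtXi %*% crossprod(X, y))
  resid <- y - drop(X %*% beta)
  sigma2 <- sum(resid^2) / (n - ncol(X))
  se <- sqrt(sigma2 * diag(XtXi))
  b <- beta[2L]; s <- se[2L]
  z <- b / s
  data.frame(siteId = siteId, cohort = cohort, beta = b, se = s, z = z,
             p = 2 * stats::pnorm(-abs(z)), eaf = mean(d) / 2, mac = mac, n = n,
             skipped = FALSE, reason = NA_character_, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Pools per-cohort effect estimates with weights 1/se^2: pooled beta =
#' sum(w b)/sum(w), pooled se = 1/sqrt(sum(w)), z = beta/se, two-sided normal
#' p. The \code{tested} flag is FALSE when fewer than \code{minCohorts}
#' cohorts contribute (the two-cohort pass rule for reporting a variant).
#'
#' @param stats data.frame of per-cohort statistics with columns beta, se and
#'   optionally cohort, effectAllele, n.
#' @param minCohorts minimum contributing cohorts for the tested flag.
#' @return one-row data.frame: beta, se, z, p, nCohorts, nTotal, direction
#'   (one of +/-/? per cohort), tested.
#' @export
ivwMeta <- function(stats, minCohorts = 2L) {
  stopifnot(nrow(stats) >= 1L, all(c("beta", "se") %in% names(stats)))
  if ("effectAllele" %in% names(stats) &&
      length(unique(stats$effectAllele[!is.na(stats$effectAllele)])) > 1L)
    stop("effect alleles are not harmonized across cohorts")
  if (any(!is.na(stats$se) & stats$se <= 0)) stop("standard errors must be positive")
  direction <- paste(ifelse(is.na(stats$beta), "?",
                            ifelse(stats$beta > 0, "+", "-")), collapse = "")
  ok <- !is.na(stats$beta) & !is.na(stats$se)
  b <- stats$beta[ok]; s <- stats$se[ok]
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  data.frame(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
             nCohorts = sum(ok),
             nTotal = if ("n" %in% names(stats)) sum(stats$n[ok]) else NA_integer_,
             direction = direction, tested = sum(ok) >= minCohorts,
             stringsAsFactors = FALSE)
}

#' Genomic-control lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values, divided
#' by the null median qchisq(0.5, 1) = 0.4549364. Values near 1 indicate no
#' global test-statistic inflation.
#'
#' @param pValues p-values in (0, 1].
#' @return scalar lambda.
#' @export
genomicLambda <- function(pValues) {
  stopifnot(length(pValues) >= 1L, all(pValues > 0 & pValues <= 1))
  stats::median(stats::qchisq(pValues, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Composite LD r-squared from genotype counts
#'
#' Squared Pearson correlation of genotype counts across individuals
#' (composite LD; no phasing needed). Undefined for a monomorphic vector,
#' returned as 0 so that filters treat such pairs as unlinked.
#'
#' @param a,b aligned genotype-count (or dosage) vectors.
#' @return scalar in [0,1].
#' @export
ldR2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)^2
}

#' Label association hits as novel or known-linked
#'
#' A hit is "known-linked" iff some previously reported variant for the same
#' trait lies within +/- \code{windowBp} and has LD r-squared >=
#' \code{r2Cut} with the hit in ANY supplied LD cohort; otherwise "novel".
#'
#' @param hits data.frame with columns trait, chrom, pos, siteId.
#' @param known data.frame of previously reported variants with the same
#'   columns.
#' @param ldCohorts named list of genotype matrices (individuals x variants,
#'   columns named by siteId) used to compute LD.
#' @param windowBp window half-width (default 1 Mb).
#' @param r2Cut LD threshold (default 0.2).
#' @return \code{hits} with added columns status ("novel"/"known-linked"),
#'   maxR2 and nearestKnown.
#' @export
noveltyFilter <- function(hits, known, ldCohorts, windowBp = 1e6, r2Cut = 0.2) {
  hits$status <- "novel"
  hits$maxR2 <- NA_real_
  hits$nearestKnown <- NA_character_
  for (i in seq_len(nrow(hits))) {
    kv <- known[known$trait == hits$trait[i] &
                  known$chrom == hits$chrom[i] &
                  abs(known$pos - hits$pos[i]) <= windowBp, , drop = FALSE]
    if (!nrow(kv)) next
    best <- 0
    bestId <- NA_character_
    for (j in seq_len(nrow(kv))) {
      r2 <- max(0, vapply(ldCohorts, function(g) {
        if (!all(c(hits$siteId[i], kv$siteId[j]) %in% colnames(g))) return(0)
        ldR2(g[, hits$siteId[i]], g[, kv$siteId[j]])
      }, numeric(1)))
      if (r2 > best) { best <- r2; bestId <- kv$siteId[j] }
    }
    hits$maxR2[i] <- best
    hits$nearestKnown[i] <- bestId
    if (best >= r2Cut) hits$status[i] <- "known-linked"
  }
  hits
}

#' Ancestry-specific genome-wide significance call
#'
#' Strict-inequality comparison against the ancestry-specific threshold
#' appropriate for sequencing-resolution association scans: p < 1e-9 for
#' African-ancestry analyses and p < 5e-9 for Hispanic/Latino analyses.
#'
#' @param p p-value(s).
#' @param ancestry "AA" or "HL" (recycled).
#' @param thresholds named thresholds, configurable.
#' @return logical vector.
#' @export
classifySignificance <- function(p, ancestry,
                                 thresholds = c(AA = 1e-9, HL = 5e-9)) {
  if (!all(ancestry %in% names(thresholds)))
    stop("unknown ancestry label: ",
         paste(setdiff(ancestry, names(thresholds)), collapse = ", "))
  p < unname(thresholds[ancestry])
}

#' Simulate hematological phenotypes for synthetic samples
#'
#' Generates age, sex and raw trait values on clinically plausible scales,
#' optionally with a genetic effect \code{beta} of a dosage vector on the
#' latent (log for WBC) scale. Intended for calibration and power-recovery
#' experiments; samples are unrelated by construction.
#'
#' @param sampleIds character vector of sample ids.
#' @param dosage optional causal dosage vector (aligned with sampleIds).
#' @param beta effect size per alternate allele on the latent scale.
#' @param trait trait carrying the effect ("WBC", "HGB" or "HCT").
#' @return data.frame with sampleId, age, age2, sex, WBC, HGB, HCT, NEU, LYM.
#' @export
simulatePhenotypes <- function(sampleIds, dosage = NULL, beta = 0, trait = "WBC") {
  n <- length(sampleIds)
  age <- round(stats::runif(n, 21, 80))
  sex <- stats::rbinom(n, 1L, 0.5)
  eff <- function(tr) {
    e <- 0.004 * (age - 50) + 0.15 * sex + stats::rnorm(n)
    if (!is.null(dosage) && tr == trait) e <- e + beta * dosage
    e
  }
  wbcLatent <- eff("WBC")
  data.frame(
    sampleId = sampleIds, age = age, age2 = age^2, sex = sex,
    WBC = exp(log(6.5) + 0.35 * wbcLatent),
    HGB = 13.8 + 1.2 * eff("HGB"),
    HCT = 41 + 3.5 * eff("HCT"),
    NEU = exp(log(3.8) + 0.35 * wbcLatent + 0.15 * stats::rnorm(n)),
    LYM = exp(log(2.0) + 0.30 * wbcLatent + 0.15 * stats::rnorm(n)),
    stringsAsFactors = FALSE)
}
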