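## End-to-end orchestration: simulate -> impute (one or more panel
## scenarios) -> evaluate -> associate -> meta -> report. A single global
## seed is fanned out to per-stage seeds through fixed small offsets so each
## stage is independently reproducible.

.stageSeed <- function(seed, stage) {
  offsets <- c(sim = 0L, panelSubset = 17L, phenotypes = 29L, assoc = 43L)
  as.integer(seed) + offsets[[stage]]
}

.cohortAncestry <- function(cohortName) {
  if (grepl("^HL", cohortName)) "HL" else "AA"
}

#' Assemble a pipeline configuration
#'
#' Bundles the simulation config, named imputation-panel scenarios (panel
#' size plus HMM parameters), the QC rule and the association settings into
#' one validated list. Scenario names must be unique; the conventional pair
#' contrasts a large panel with a downsampled sub-panel.
#'
#' @param sim a \linkS4class{SimConfig}.
#' @param nRegions number of independently simulated regions.
#' @param scenarios named list; each element
#'   \code{list(panelHaplotypes =, params = HmmParams())}.
#' @param qc list(targetMean =, metric =).
#' @param assoc list(trait =, beta =, effectMaf =, minMac =); beta > 0
#'   injects a genetic effect at the QC-passing variant with target MAF
#'   closest to effectMaf.
#' @param seed global seed; overrides \code{sim@seed}.
#' @return a validated list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(sim = SimConfig(
                             nSites = 300L, nPanelHaplotypes = 600L,
                             targetCohorts = list(
                               AA1 = list(n = 60L, admixture = admixturePreset("AA")),
                               AA2 = list(n = 60L, admixture = admixturePreset("AA")))),
                           nRegions = 2L,
                           scenarios = list(
                             large = list(panelHaplotypes = 600L, params = HmmParams()),
                             small = list(panelHaplotypes = 150L, params = HmmParams())),
                           qc = list(targetMean = 0.8, metric = "estimated"),
                           assoc = list(trait = "WBC", beta = 0, effectMaf = 0.05,
                                        minMac = 5),
                           seed = 42L) {
  cfg <- list(sim = sim, nRegions = as.integer(nRegions), scenarios = scenarios,
              qc = qc, assoc = assoc, seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema checks run before any compute: unique scenario names, positive
#' panel sizes not exceeding the simulated panel, at least one target
#' individual per cohort, a known QC metric.
#'
#' @param config a \code{pipelineConfig}.
#' @return \code{config}, invisibly; errors otherwise.
#' @export
validatePipelineConfig <- function(config) {
  stopifnot(is(config$sim, "SimConfig"))
  validObject(config$sim)
  ns <- names(config$scenarios)
  if (is.null(ns) || anyDuplicated(ns)) stop("scenario names must be present and unique")
  for (s in ns) {
    ph <- config$scenarios[[s]]$panelHaplotypes
    if (is.null(ph) || ph < 2L || ph > config$sim@nPanelHaplotypes)
      stop("scenario '", s, "' panelHaplotypes must lie in [2, nPanelHaplotypes]")
  }
  if (any(vapply(config$sim@targetCohorts, function(x) x$n, numeric(1)) < 1))
    stop("every target cohort needs at least one individual")
  if (!config$qc$metric %in% c("estimated", "true")) stop("unknown QC metric")
  if (config$nRegions < 1L) stop("nRegions must be >= 1")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipelineConfig()]: a \code{sim} block of
#' \linkS4class{SimConfig} fields (cohorts may give an admixture preset name
#' "AA"/"HL" instead of a numeric vector), \code{scenarios} with
#' panelHaplotypes and HMM parameters, \code{qc}, \code{assoc}, \code{seed}
#' and \code{nRegions}. Validated before any compute.
#'
#' @param path YAML file path.
#' @return a \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  if (!is.null(simArgs$targetCohorts)) {
    nPools <- if (is.null(simArgs$nPools)) 5L else as.integer(simArgs$nPools)
    simArgs$targetCohorts <- lapply(simArgs$targetCohorts, function(co) {
      if (is.character(co$admixture)) co$admixture <- admixturePreset(co$admixture, nPools)
      # YAML 1.1 reads a bare `n:` key as boolean FALSE; prefer nIndividuals
      nv <- co$nIndividuals
      if (is.null(nv)) nv <- co$n
      if (is.null(nv)) nv <- co[["FALSE"]]
      list(n = as.integer(nv), admixture = co$admixture)
    })
  }
  for (nm in c("nPools", "foundersPerPool", "nSites", "nPanelHaplotypes", "seed"))
    if (!is.null(simArgs[[nm]])) simArgs[[nm]] <- as.integer(simArgs[[nm]])
  sim <- do.call(SimConfig, simArgs)
  scen <- lapply(y$scenarios, function(sc) {
    list(panelHaplotypes = as.integer(sc$panelHaplotypes),
         params = HmmParams(
           recombScale = if (is.null(sc$recombScale)) 1 else sc$recombScale,
           copyError = if (is.null(sc$copyError)) 0.001 else sc$copyError,
           minSwitch = if (is.null(sc$minSwitch)) 1e-5 else sc$minSwitch))
  })
  args <- list(sim = sim, scenarios = scen)
  if (!is.null(y$nRegions)) args$nRegions <- as.integer(y$nRegions)
  if (!is.null(y$qc)) args$qc <- utils::modifyList(list(targetMean = 0.8, metric = "estimated"), y$qc)
  if (!is.null(y$assoc)) args$assoc <- utils::modifyList(
    list(trait = "WBC", beta = 0, effectMaf = 0.05, minMac = 5), y$assoc)
  if (!is.null(y$seed)) args$seed <- as.integer(y$seed)
  do.call(pipelineConfig, args)
}

## subsample a panel to nHap haplotypes, keeping individuals' pairs together
.subsamplePanel <- function(panel, nHap, seed) {
  if (nHap >= nHaplotypes(panel)) return(panel)
  set.seed(seed)
  nInd <- nHaplotypes(panel) %/% 2L
  pick <- sort(sample.int(nInd, nHap %/% 2L))
  rows <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  panel[rows, ]
}

#' Impute, evaluate and QC one cohort across regions and scenarios
#'
#' Worker shared by [runPipeline()] and the panel-size benchmark: imputes
#' each region with the full flanked region, evaluates only the core window
#' (1 Mb trimmed from each edge), pools records across regions and applies
#' the adaptive QC per scenario.
#'
#' @param datasets list of \code{benchDataset} (one per region).
#' @param cohort cohort name.
#' @param scenarios named scenario list as in [pipelineConfig()].
#' @param targetMean,metric QC rule.
#' @param seed seed used for panel subsampling.
#' @param coreMarginBp margin excluded from evaluation at each region edge.
#' @param panelMacFloor evaluation is restricted to variants whose minor
#'   allele count in the \emph{full} simulated panel exceeds this floor
#'   (default 5), mirroring the allele-count exclusion a sequencing panel
#'   applies to itself before serving as an imputation reference; the
#'   resulting site universe is identical across panel scenarios.
#' @return list per scenario: records (QC'd), thresholds, dosages (region
#'   list of \linkS4class{DosageResult}).
#' @export
imputeAndEvaluate <- function(datasets, cohort, scenarios,
                              targetMean = 0.8, metric = "estimated",
                              seed = 1L, coreMarginBp = 1e6,
                              panelMacFloor = 5L) {
  out <- list()
  for (sn in names(scenarios)) {
    sc <- scenarios[[sn]]
    recs <- list()
    doses <- list()
    for (ri in seq_along(datasets)) {
      ds <- datasets[[ri]]
      panel <- .subsamplePanel(ds$panel, sc$panelHaplotypes,
                               .stageSeed(seed, "panelSubset") + ri)
      truth <- ds$targets[[cohort]]
      dose <- imputeCohort(truth[, ds$masks[[cohort]]], panel, sc$params)
      cfg <- ds$config
      core <- c(cfg@regionStartBp + coreMarginBp,
                cfg@regionStartBp + cfg@regionLengthBp - coreMarginBp)
      r <- evaluateImputation(dose, truth, panel, coreRange = core)
      fullAlt <- colSums(alleleMatrix(ds$panel))
      fullMac <- pmin(fullAlt, nHaplotypes(ds$panel) - fullAlt)
      r <- r[fullMac[match(r$siteId, siteIds(ds$panel))] > panelMacFloor, ,
             drop = FALSE]
      recs[[ri]] <- r
      doses[[ri]] <- dose
    }
    records <- do.call(rbind, recs)
    th <- computeThresholds(records, targetMean, metric)
    out[[sn]] <- list(records = applyQC(records, th), thresholds = th,
                      dosages = doses)
  }
  out
}

#' Benchmark a large reference panel against a downsampled sub-panel
#'
#' The package's flagship experiment: a fixed admixed target cohort is
#' imputed from the same simulated regions using the full panel and a
#' sub-panel, quality is evaluated in the core of each region, adaptive QC
#' thresholds are recomputed per panel, and pass counts / mean true R2 are
#' compared in MAF strata (with a focus on rare variants, MAF < 0.5%).
#'
#' @param seed global seed (default 42).
#' @param config a \linkS4class{SimConfig}; defaults to the package default
#'   conditions (200-individual AA-like cohort, 2,000-haplotype panel).
#' @param nRegions regions to simulate (default 3).
#' @param panelSizes named haplotype counts, largest first
#'   (default c(large = 2000, small = 200)).
#' @param params \linkS4class{HmmParams}.
#' @param cohort cohort to evaluate (default the first).
#' @return list: perScenario (records/thresholds per panel), report (from
#'   [panelComparisonReport()]), rare (named rare-stratum summary: pass
#'   counts, fold, mean true R2), extrapolation (genome-wide well-imputed
#'   estimate per panel).
#' @export
runPanelSizeBenchmark <- function(seed = 42L, config = NULL, nRegions = 3L,
                                  panelSizes = c(large = 2000L, small = 200L),
                                  params = HmmParams(), cohort = NULL) {
  if (is.null(config)) config <- SimConfig(seed = as.integer(seed))
  config@seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- names(config@targetCohorts)[1L]
  datasets <- simulateRegions(config, nRegions)
  scenarios <- lapply(panelSizes, function(n) list(panelHaplotypes = as.integer(n),
                                                   params = params))
  per <- imputeAndEvaluate(datasets, cohort, scenarios, seed = seed)
  recordsList <- lapply(per, `[[`, "records")
  report <- panelComparisonReport(recordsList)
  rareOf <- function(r) {
    keep <- r$targetMaf < 0.005
    list(nPass = sum(r$qcPass[keep]),
         meanTrueR2 = mean(r$trueR2[keep & r$qcPass], na.rm = TRUE),
         meanTrueR2All = mean(r$trueR2[keep], na.rm = TRUE),
         n = sum(keep))
  }
  rare <- lapply(recordsList, rareOf)
  fold <- rare[[1L]]$nPass / max(1L, rare[[length(rare)]]$nPass)
  coreSpan <- nRegions * (config@regionLengthBp - 2e6)
  extrap <- vapply(recordsList, function(r)
    extrapolateWellImputed(sum(r$qcPass), coreSpan), numeric(1))
  list(perScenario = per, report = report,
       rare = list(byPanel = rare, passFold = fold),
       extrapolation = extrap, config = config, cohort = cohort)
}

#' Run the full benchmarking pipeline
#'
#' Executes every stage in order -- simulate regions, impute each cohort
#' under every panel scenario, evaluate and QC, tabulate (MAF-bin summary,
#' MAC-stratified table, stringency curves, genome-wide extrapolation,
#' panel comparison), simulate phenotypes, run single-variant association
#' per cohort and inverse-variance meta-analysis per ancestry -- and writes
#' every table as TSV under \code{outDir} together with a checksum manifest.
#' Deterministic: identical configs give identical checksums.
#'
#' @param config a \code{pipelineConfig}.
#' @param outDir output directory.
#' @return invisible list with all in-memory stage outputs plus
#'   \code{manifest}.
#' @export
runPipeline <- function(config, outDir) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    f <- file.path(outDir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, f)
    f
  }
  sim <- config$sim
  sim@seed <- .stageSeed(config$seed, "sim")
  datasets <- withCallingHandlers(
    simulateRegions(sim, config$nRegions),
    error = function(e) stop("stage 'simulate' failed: ", conditionMessage(e)))
  dsFiles <- writeDataset(datasets[[1L]], file.path(outDir, "region1"))
  written <- c(written, unname(dsFiles))
  cohorts <- names(sim@targetCohorts)
  evalOut <- list()
  assocStats <- list()
  phenos <- list()
  primary <- names(config$scenarios)[1L]
  for (co in cohorts) {
    ev <- tryCatch(
      imputeAndEvaluate(datasets, co, config$scenarios,
                        targetMean = config$qc$targetMean,
                        metric = config$qc$metric, seed = config$seed),
      error = function(e) stop("stage 'impute/evaluate' failed: ", conditionMessage(e)))
    evalOut[[co]] <- ev
    for (sn in names(ev)) {
      r <- ev[[sn]]$records
      emit(attr(r, "binSummary"), sprintf("bin_summary_%s_%s.tsv", sn, co))
      emit(r, sprintf("records_%s_%s.tsv", sn, co))
      emit(macStratifiedTable(r), sprintf("mac_table_%s_%s.tsv", sn, co))
      strata <- list(`maf<1%` = c(0, 0.01), `maf>=1%` = c(0.01, 0.51))
      curves <- do.call(rbind, lapply(names(strata), function(stn) {
        s <- strata[[stn]]
        cbind(stratum = stn,
              stringencyCurve(r[r$targetMaf >= s[1] & r$targetMaf < s[2], ]))
      }))
      emit(curves, sprintf("stringency_%s_%s.tsv", sn, co))
      coreSpan <- config$nRegions * (sim@regionLengthBp - 2e6)
      perRegion <- vapply(split(r$qcPass, sub(":.*$", "", r$siteId)), sum, numeric(1))
      emit(data.frame(scenario = sn, cohort = co,
                      corePass = sum(r$qcPass), coreSpanBp = coreSpan,
                      genomeEstimate = extrapolateWellImputed(perRegion, coreSpan)),
           sprintf("extrapolation_%s_%s.tsv", sn, co))
    }
    cmp <- panelComparisonReport(lapply(ev, `[[`, "records"),
                                 targetMean = config$qc$targetMean,
                                 metric = config$qc$metric)
    emit(cmp$table, sprintf("comparison_%s.tsv", co))
    emit(cmp$folds, sprintf("comparison_folds_%s.tsv", co))

    ## association on the primary scenario's QC-passing imputed variants
    trait <- config$assoc$trait
    truth1 <- datasets[[1L]]$targets[[co]]
    nInd <- nHaplotypes(truth1) %/% 2L
    set.seed(.stageSeed(config$seed, "phenotypes") + match(co, cohorts))
    rp <- ev[[primary]]
    gd1 <- genotypeDosage(rp$dosages[[1L]])
    causal <- NULL
    if (config$assoc$beta != 0) {
      r1 <- rp$records[rp$records$qcPass & sub(":.*$", "", rp$records$siteId) ==
                         datasets[[1L]]$config@chrom, ]
      if (nrow(r1)) {
        pick <- r1$siteId[which.min(abs(r1$targetMaf - config$assoc$effectMaf))]
        causal <- gd1[, match(pick, siteIds(rp$dosages[[1L]]))]
      }
    }
    ph <- simulatePhenotypes(sampleIds(rp$dosages[[1L]]), dosage = causal,
                             beta = config$assoc$beta, trait = trait)
    phenos[[co]] <- ph
    ph <- cleanPhenotypes(ph, trait)
    yv <- residualizeInverseNormalize(
      transformTrait(ph[[trait]], trait), ph[, c("age", "age2", "sex")])
    passIds <- rp$records$siteId[rp$records$qcPass]
    testIds <- intersect(passIds, siteIds(rp$dosages[[1L]]))
    keepInd <- match(ph$sampleId, sampleIds(rp$dosages[[1L]]))
    st <- do.call(rbind, lapply(testIds, function(id) {
      singleVariantTest(gd1[keepInd, match(id, siteIds(rp$dosages[[1L]]))], yv,
                        minMac = config$assoc$minMac, cohort = co, siteId = id)
    }))
    if (is.null(st))
      st <- singleVariantTest(numeric(0), numeric(0), cohort = co)[0, ]
    assocStats[[co]] <- st
    emit(st, sprintf("assoc_%s.tsv", co))
  }
  ## inverse-variance meta-analysis per ancestry over cohorts
  anc <- vapply(cohorts, .cohortAncestry, character(1))
  metaOut <- list()
  for (a in unique(anc)) {
    grp <- do.call(rbind, assocStats[cohorts[anc == a]])
    grp <- grp[!grp$skipped, , drop = FALSE]
    if (!nrow(grp)) next
    ids <- unique(grp$siteId)
    meta <- do.call(rbind, lapply(ids, function(id) {
      m <- ivwMeta(grp[grp$siteId == id, , drop = FALSE])
      cbind(siteId = id, m)
    }))
    meta$significant <- classifySignificance(meta$p, rep(a, nrow(meta)))
    meta$lambda <- genomicLambda(meta$p)
    metaOut[[a]] <- meta
    emit(meta, sprintf("meta_%s.tsv", a))
  }
  cfgFile <- file.path(outDir, "config.yaml")
  yaml::write_yaml(list(seed = config$seed, nRegions = config$nRegions,
                        qc = config$qc, assoc = config$assoc,
                        scenarios = lapply(config$scenarios, function(s)
                          list(panelHaplotypes = s$panelHaplotypes))), cfgFile)
  written <- c(written, cfgFile)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  utils::write.table(manifest, file.path(outDir, "run_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(datasets = datasets, evaluation = evalOut, assoc = assocStats,
                 meta = metaOut, phenotypes = phenos, manifest = manifest,
                 outDir = outDir))
}

#' Render stringency-curve plots from pipeline outputs
#'
#' Reads the \code{stringency_<scenario>_<cohort>.tsv} tables under
#' \code{outDir} and draws, per cohort and MAF stratum, the mean true R2
#' against the estimated-R2 filtering cutoff with one curve per panel
#' scenario, into \code{stringency_curves.pdf}.
#'
#' @param outDir a directory previously populated by [runPipeline()].
#' @return path of the written PDF, invisibly.
#' @export
renderReports <- function(outDir) {
  files <- list.files(outDir, pattern = "^stringency_.*\\.tsv$", full.names = TRUE)
  if (!length(files))
    stop("missing inputs under ", outDir, ": no stringency_*.tsv found")
  tabs <- lapply(files, utils::read.table, header = TRUE, sep = "\t")
  meta <- do.call(rbind, lapply(basename(files), function(f) {
    parts <- strsplit(sub("^stringency_(.*)\\.tsv$", "\\1", f), "_")[[1L]]
    data.frame(scenario = parts[1L], cohort = paste(parts[-1L], collapse = "_"))
  }))
  pdfFile <- file.path(outDir, "stringency_curves.pdf")
  grDevices::pdf(pdfFile, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  for (co in unique(meta$cohort)) {
    sel <- which(meta$cohort == co)
    strata <- unique(tabs[[sel[1L]]]$stratum)
    for (stn in strata) {
      graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                     xlab = "estimated R2 cutoff", ylab = "mean true R2",
                     main = sprintf("%s, %s", co, stn))
      for (k in seq_along(sel)) {
        d <- tabs[[sel[k]]]
        d <- d[d$stratum == stn & !is.na(d$meanTrueR2), ]
        graphics::lines(d$cutoff, d$meanTrueR2, col = k, lwd = 2)
        graphics::points(d$cutoff, d$meanTrueR2, col = k, pch = 16)
      }
      graphics::legend("bottomright", legend = meta$scenario[sel],
                       col = seq_along(sel), lwd = 2, bty = "n")
    }
  }
  invisible(pdfFile)
}
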