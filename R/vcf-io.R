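## VCFv4.2 I/O. Reading is delegated to vcfR; writing uses a small
## deterministic text serializer (fixed 4-decimal dosage formatting, no
## timestamps) so that identical inputs produce byte-identical files.

.vcfHeader <- function(chrom, maxPos, format) {
  c("##fileformat=VCFv4.2",
    "##source=imputeBench",
    sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(maxPos) + 1L),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Estimated imputation R-squared\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Site was genotyped on the array scaffold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Genotype dosage\">",
    "##FORMAT=<ID=HDS,Number=2,Type=Float,Description=\"Haplotype dosages\">")[format]
}

#' Write a phased haplotype panel as VCF
#'
#' Emits a minimal VCFv4.2 with phased GT ("|" separator) and AC/AN INFO
#' fields; record order follows position; output is byte-identical across
#' runs for identical input.
#'
#' @param panel a \linkS4class{HaplotypePanel} with an even number of
#'   haplotypes (adjacent rows are one individual's pair).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeHaplotypeVcf <- function(panel, path) {
  H <- nHaplotypes(panel)
  if (H %% 2L != 0L) stop("panel must contain an even number of haplotypes")
  odd <- seq(1L, H, by = 2L)
  sm <- panel@sampleIds[odd]
  S <- nSites(panel)
  h1 <- t(panel@alleles[odd, , drop = FALSE])        # S x n
  h2 <- t(panel@alleles[odd + 1L, , drop = FALSE])
  gt <- matrix(paste0(h1, "|", h2), nrow = S)
  ac <- as.integer(rowSums(h1) + rowSums(h2))
  cols <- c(list(panel@chrom, panel@positions, panel@siteIds, panel@ref,
                 panel@alt, ".", "PASS", sprintf("AC=%d;AN=%d", ac, H), "GT"),
            lapply(seq_along(sm), function(j) gt[, j]))
  body <- do.call(paste, c(cols, sep = "\t"))
  header <- c(.vcfHeader(panel@chrom, max(panel@positions), c(1:4, 8)),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sm), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write imputed dosages as VCF
#'
#' Emits DS (genotype dosage) and HDS (the two haplotype dosages) FORMAT
#' fields and R2 / TYPED INFO fields, all serialized with 4 decimal places in
#' deterministic position order.
#'
#' @param dosage a \linkS4class{DosageResult}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDosageVcf <- function(dosage, path) {
  S <- nSites(dosage)
  n <- nrow(dosage@genotypeDosage)
  odd <- seq(1L, 2L * n, by = 2L)
  info <- sprintf("R2=%.4f%s", dosage@estR2, ifelse(dosage@typed, ";TYPED", ""))
  cols <- c(list(dosage@chrom, dosage@positions, dosage@siteIds, dosage@ref,
                 dosage@alt, ".", "PASS", info, "DS:HDS"),
            lapply(seq_len(n), function(j) {
              sprintf("%.4f:%.4f,%.4f", dosage@genotypeDosage[j, ],
                      dosage@haplotypeDosage[odd[j], ],
                      dosage@haplotypeDosage[odd[j] + 1L, ])
            }))
  body <- do.call(paste, c(cols, sep = "\t"))
  header <- c(.vcfHeader(dosage@chrom, max(dosage@positions), c(1:2, 5:7, 9:10)),
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIds(dosage)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased haplotype VCF into a HaplotypePanel
#'
#' Parses phased GT ("|" separator required; an unphased record is an error
#' naming the site) into the haplotype-by-site 0/1 matrix. One chromosome per
#' file.
#'
#' @param path VCF path.
#' @return a \linkS4class{HaplotypePanel}.
#' @export
readHaplotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (length(unique(fix[, "CHROM"])) > 1L) stop("expected a single chromosome per file")
  gt <- vcfR::extract.gt(v)
  if (anyNA(gt)) stop("missing genotypes are not supported in panel files")
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow(gt))
  if (any(unphased)) {
    rec <- which(unphased, arr.ind = TRUE)[1L, ]
    stop("unphased genotype in panel file at record ", rownames(gt)[rec[1L]],
         " sample ", colnames(gt)[rec[2L]])
  }
  nInd <- ncol(gt)
  S <- nrow(gt)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), S, nInd)
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), S, nInd)
  al <- matrix(0L, 2L * nInd, S)
  al[seq(1L, 2L * nInd, 2L), ] <- t(a1)
  al[seq(2L, 2L * nInd, 2L), ] <- t(a2)
  sm <- colnames(gt)
  HaplotypePanel(alleles = al, positions = as.integer(fix[, "POS"]),
                 chrom = fix[1L, "CHROM"], ref = unname(fix[, "REF"]),
                 alt = unname(fix[, "ALT"]),
                 haplotypeLabels = sprintf("%s_%d", rep(sm, each = 2L), rep(1:2, nInd)),
                 sampleIds = rep(sm, each = 2L))
}

#' Read an imputed dosage VCF into a DosageResult
#'
#' Parses DS, HDS, the R2 INFO field and the TYPED flag.
#'
#' @param path VCF path.
#' @return a \linkS4class{DosageResult}.
#' @export
readDosageVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  hds <- vcfR::extract.gt(v, element = "HDS")
  if (is.null(ds) || is.null(hds) || anyNA(ds) || anyNA(hds))
    stop("requested FORMAT fields DS/HDS are missing from ", path)
  r2 <- as.numeric(vcfR::extract.info(v, "R2"))
  if (anyNA(r2)) stop("requested INFO field R2 is missing from ", path)
  typed <- grepl("(^|;)TYPED(;|$)", fix[, "INFO"])
  nInd <- ncol(ds)
  S <- nrow(ds)
  sp <- strsplit(as.vector(hds), ",", fixed = TRUE)
  h1 <- matrix(as.numeric(vapply(sp, `[`, character(1), 1L)), S, nInd)
  h2 <- matrix(as.numeric(vapply(sp, `[`, character(1), 2L)), S, nInd)
  hd <- matrix(0, 2L * nInd, S)
  hd[seq(1L, 2L * nInd, 2L), ] <- t(h1)
  hd[seq(2L, 2L * nInd, 2L), ] <- t(h2)
  odd <- seq(1L, 2L * nInd, 2L)
  new("DosageResult", haplotypeDosage = hd,
      genotypeDosage = hd[odd, , drop = FALSE] + hd[odd + 1L, , drop = FALSE],
      estR2 = r2, typed = typed, positions = as.integer(fix[, "POS"]),
      chrom = fix[1L, "CHROM"], ref = unname(fix[, "REF"]),
      alt = unname(fix[, "ALT"]),
      siteIds = sprintf("%s:%s:%s:%s", fix[, "CHROM"], fix[, "POS"],
                        fix[, "REF"], fix[, "ALT"]),
      sampleIds = colnames(ds))
}

#' Write a simulated dataset to disk
#'
#' Emits the reference panel VCF, per-cohort truth and typed-only VCFs (all
#' phased GT), a per-cohort local-ancestry TSV (sites x haplotypes of pool
#' indices) and a manifest TSV of the generating parameters and seed.
#'
#' @param dataset a \code{benchDataset} from [buildDataset()].
#' @param outDir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
writeDataset <- function(dataset, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c(panel = file.path(outDir, "panel.vcf"))
  writeHaplotypeVcf(dataset$panel, files[["panel"]])
  for (cname in names(dataset$targets)) {
    tg <- dataset$targets[[cname]]
    f1 <- file.path(outDir, sprintf("%s.truth.vcf", cname))
    f2 <- file.path(outDir, sprintf("%s.typed.vcf", cname))
    f3 <- file.path(outDir, sprintf("%s.ancestry.tsv", cname))
    writeHaplotypeVcf(tg, f1)
    writeHaplotypeVcf(tg[, dataset$masks[[cname]]], f2)
    la <- localAncestry(tg)
    anc <- data.frame(siteId = siteIds(tg), t(la), check.names = FALSE)
    colnames(anc) <- c("siteId", tg@haplotypeLabels)
    utils::write.table(anc, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    files[paste0(cname, c(".truth", ".typed", ".ancestry"))] <- c(f1, f2, f3)
  }
  cfg <- dataset$config
  man <- data.frame(
    key = c("seed", "nPools", "foundersPerPool", "nSites", "regionLengthBp",
            "nPanelHaplotypes", "arrayMafThreshold", "arrayDensity",
            "founderSwitchRate", "ancestrySwitchRate", "freshMutationRate",
            "fstLikeDivergence", "chrom"),
    value = c(cfg@seed, cfg@nPools, cfg@foundersPerPool, cfg@nSites,
              cfg@regionLengthBp, cfg@nPanelHaplotypes, cfg@arrayMafThreshold,
              cfg@arrayDensity, cfg@founderSwitchRate, cfg@ancestrySwitchRate,
              cfg@freshMutationRate, cfg@fstLikeDivergence, cfg@chrom))
  fman <- file.path(outDir, "manifest.tsv")
  utils::write.table(man, fman, sep = "\t", quote = FALSE, row.names = FALSE)
  files["manifest"] <- fman
  invisible(files)
}
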