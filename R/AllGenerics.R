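#' @rdname HaplotypePanel-class
#' @param x,object a \linkS4class{HaplotypePanel} or \linkS4class{DosageResult}.
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("poolLabels", function(x) standardGeneric("poolLabels"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("localAncestry", function(x) standardGeneric("localAncestry"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname DosageResult-class
#' @export
setGeneric("haplotypeDosage", function(x) standardGeneric("haplotypeDosage"))

#' @rdname DosageResult-class
#' @export
setGeneric("genotypeDosage", function(x) standardGeneric("genotypeDosage"))

#' @rdname DosageResult-class
#' @export
setGeneric("estR2", function(x) standardGeneric("estR2"))

#' @rdname DosageResult-class
#' @export
setGeneric("typedSites", function(x) standardGeneric("typedSites"))

#' @rdname QCThresholds-class
#' @param x a \linkS4class{QCThresholds}.
#' @export
setGeneric("qcThresholds", function(x) standardGeneric("qcThresholds"))
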