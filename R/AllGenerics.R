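#' Accessors for laspa classes
#'
#' @param x an object of the documented class.
#' @name laspa-accessors
NULL

#' @describeIn laspa-accessors dosage matrix, subjects in rows, SNVs in
#'   columns (transpose of the internal SummarizedExperiment layout).
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @describeIn laspa-accessors subject identifiers.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @describeIn laspa-accessors number of subjects.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @describeIn laspa-accessors number of SNVs.
#' @export
setGeneric("nSnvs", function(x) standardGeneric("nSnvs"))

#' @describeIn laspa-accessors per-SNV metadata (chromosome, position) as a
#'   DataFrame in canonical SNV order.
#' @export
setGeneric("snvInfo", function(x) standardGeneric("snvInfo"))

#' @describeIn laspa-accessors per-subject ancestry cluster labels.
#' @export
setGeneric("ancestryLabels", function(x) standardGeneric("ancestryLabels"))

#' @describeIn laspa-accessors number of realized ancestry clusters.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @describeIn laspa-accessors carrier count per rare variant.
#' @export
setGeneric("carrierCounts", function(x) standardGeneric("carrierCounts"))

#' @describeIn laspa-accessors subject scores on principal components.
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @describeIn laspa-accessors adjusted-phenotype residual vector.
#' @export
setGeneric("residualsY", function(x) standardGeneric("residualsY"))

setMethod("dosageMatrix", "GenotypeMatrix",
          function(x) t(SummarizedExperiment::assay(x, "dosage")))
setMethod("subjectIds", "GenotypeMatrix", function(x) colnames(x))
setMethod("nSubjects", "GenotypeMatrix", function(x) ncol(x))
setMethod("nSnvs", "GenotypeMatrix", function(x) nrow(x))
setMethod("snvInfo", "GenotypeMatrix", function(x) rowData(x))

setMethod("ancestryLabels", "LocalAncestry", function(x) x@labels)
setMethod("nClusters", "LocalAncestry", function(x) x@J)
setMethod("pcScores", "LocalAncestry", function(x) x@pcScores)

setMethod("carrierCounts", "CarrierStructure", function(x) x@counts)
setMethod("nSubjects", "CarrierStructure", function(x) x@nSubjects)

setMethod("pcScores", "GlobalPCScores", function(x) x@scores)

setMethod("residualsY", "AdjustedPhenotype", function(x) x@y)

setMethod("show", "GenotypeMatrix", function(object) {
    d <- SummarizedExperiment::assay(object, "dosage")
    nmiss <- sum(is.na(d))
    cat(sprintf("GenotypeMatrix: %d subjects x %d SNVs (%d chromosome%s)\n",
                ncol(object), nrow(object),
                length(unique(rowData(object)$chrom)),
                if (length(unique(rowData(object)$chrom)) == 1L) "" else "s"))
    cat(sprintf("  missing dosages: %d (%.3f%%)\n", nmiss,
                100 * nmiss / length(d)))
})

setMethod("show", "LocalAncestry", function(object) {
    cat(sprintf("LocalAncestry: %d subjects in %d cluster%s (sizes: %s)\n",
                length(object@labels), object@J,
                if (object@J == 1L) "" else "s",
                paste(object@clusterSizes, collapse = ", ")))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CarrierStructure", function(object) {
    cat(sprintf(
        "CarrierStructure: %d rare variants over %d subjects; %d with carriers\n",
        length(object@counts), object@nSubjects, sum(object@counts > 0L)))
})

setMethod("show", "GlobalPCScores", function(object) {
    cat(sprintf("GlobalPCScores: %d subjects x %d components (from %d SNVs",
                nrow(object@scores), ncol(object@scores), object@nSnvsUsed))
    if (object@nMonomorphicDropped > 0L)
        cat(sprintf(", %d monomorphic dropped", object@nMonomorphicDropped))
    cat(")\n  explained variance:",
        paste(sprintf("%.3f", object@explainedVariance), collapse = " "), "\n")
})

setMethod("show", "AdjustedPhenotype", function(object) {
    cat(sprintf(
        "AdjustedPhenotype: %d subjects; adjustment R^2 = %.3f\n  terms: %s\n",
        length(object@y), object@rSquared,
        paste(object@terms, collapse = ", ")))
})
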