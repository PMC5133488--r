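#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   rowData<- colData assayNames rowRanges
NULL

MISSING_DOSAGE <- NA_integer_

#' GenotypeMatrix: subjects-by-SNV minor-allele dosages
#'
#' Container for a cohort's biallelic genotypes, stored as a
#' \linkS4class{SummarizedExperiment} with SNVs as rows and subjects as
#' columns. The single assay \code{"dosage"} holds minor-allele counts in
#' \{0, 1, 2\}, with \code{NA} as the out-of-band missing marker (missingness
#' is never conflated with the reference homozygote). Row metadata carries the
#' chromosome label and base-pair position of each SNV; the row order is the
#' canonical SNV index (file order), and positions must be non-decreasing
#' within each chromosome.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [readGenotypes()], [imputeMissing()], [dosageMatrix()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- d[!is.na(d)]
        if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
            msg <- c(msg, "non-missing dosages must be 0, 1 or 2")
    }
    ids <- colnames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "subject ids (colnames) must be present and unique")
    rd <- rowData(object)
    if (!all(c("chrom", "pos") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
    else {
        unsorted <- tapply(rd$pos, as.character(rd$chrom),
                           function(p) is.unsorted(p, strictly = FALSE))
        if (any(unlist(unsorted)))
            msg <- c(msg, sprintf(
                "positions not sorted within chromosome(s): %s",
                paste(names(unsorted)[unlist(unsorted)], collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeMatrix
#'
#' @param dosages integer matrix of minor-allele dosages, subjects in rows and
#'   SNVs in columns (the orientation genotype text files use); values 0/1/2
#'   or \code{NA} for missing. Row names are subject ids, column names SNV ids.
#' @param chrom character vector of chromosome labels, one per SNV.
#' @param pos integer vector of base-pair positions (1-based), one per SNV.
#' @param subjectIds optional subject ids overriding \code{rownames(dosages)}.
#' @param snvIds optional SNV ids overriding \code{colnames(dosages)}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0L,1L,2L,0L), 2, 2,
#'                            dimnames = list(c("s1","s2"), c("v1","v2"))),
#'                     chrom = c("1","1"), pos = c(100L, 200L))
#' nSubjects(g); nSnvs(g)
#' @export
GenotypeMatrix <- function(dosages, chrom, pos, subjectIds = rownames(dosages),
                           snvIds = colnames(dosages)) {
    dosages <- as.matrix(dosages)
    if (is.null(subjectIds))
        stop("subject ids required (rownames of 'dosages' or 'subjectIds')")
    if (is.null(snvIds))
        snvIds <- sprintf("snv%d", seq_len(ncol(dosages)))
    storage.mode(dosages) <- "integer"
    stopifnot(length(chrom) == ncol(dosages), length(pos) == ncol(dosages))
    se <- SummarizedExperiment(
        assays = list(dosage = t(dosages)),
        rowData = DataFrame(chrom = as.character(chrom),
                            pos = as.integer(pos), row.names = snvIds),
        colData = DataFrame(row.names = as.character(subjectIds)))
    new("GenotypeMatrix", se)
}

#' LocalAncestry: per-subject ancestry cluster labels for one region
#'
#' Result of PCA + k-means clustering of a region's common variants. Labels
#' are anonymous cluster indices in \code{1..J}; no identity of clusters
#' across regions (or naming of clusters as ancestral populations) is claimed.
#'
#' @slot labels integer vector, one cluster label per subject.
#' @slot J number of realized clusters.
#' @slot clusterSizes integer vector of length \code{J}.
#' @slot pcScores numeric matrix (subjects x PCs) the clustering ran on
#'   (zero-column matrix when the region was ancestry-unassignable).
#' @slot flags character, any of \code{"ancestry_unassignable"},
#'   \code{"cluster_fallback"}.
#' @seealso [inferLocalAncestry()]
#' @export
setClass("LocalAncestry",
         representation(labels = "integer", J = "integer",
                        clusterSizes = "integer", pcScores = "matrix",
                        flags = "character"))

setValidity("LocalAncestry", function(object) {
    msg <- NULL
    if (object@J < 1L) msg <- c(msg, "J must be >= 1")
    if (!all(object@labels %in% seq_len(object@J)))
        msg <- c(msg, "labels must lie in 1..J")
    if (length(object@clusterSizes) != object@J ||
        sum(object@clusterSizes) != length(object@labels))
        msg <- c(msg, "clusterSizes must have length J and sum to n subjects")
    if (any(object@clusterSizes == 0L))
        msg <- c(msg, "all realized clusters must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' CarrierStructure: rare-variant carrier sets for one region
#'
#' For each rare variant in a region, the set of subjects carrying at least
#' one copy of the minor allele. Variants with no carriers are retained (they
#' contribute zero to the SPA statistics).
#'
#' @slot carriers list of integer vectors of subject indices, one per variant.
#' @slot counts integer carrier count per variant (\code{n_i}).
#' @slot alleleCounts integer minor-allele count per variant (the alternative
#'   weighting behind \code{mode = "allele"}).
#' @slot nSubjects number of subjects the indices refer to.
#' @seealso [buildCarriers()], [computeI1()], [computeIA()]
#' @export
setClass("CarrierStructure",
         representation(carriers = "list", counts = "integer",
                        alleleCounts = "integer", nSubjects = "integer"))

setValidity("CarrierStructure", function(object) {
    msg <- NULL
    if (length(object@carriers) != length(object@counts) ||
        length(object@counts) != length(object@alleleCounts))
        msg <- c(msg, "carriers, counts, alleleCounts must have equal length")
    if (!all(lengths(object@carriers) == object@counts))
        msg <- c(msg, "counts must equal the carrier-set sizes")
    if (any(object@counts > object@nSubjects))
        msg <- c(msg, "carrier count exceeds number of subjects")
    if (is.null(msg)) TRUE else msg
})

#' GlobalPCScores: subject scores on genome-wide principal components
#'
#' @slot scores numeric matrix, subjects x components; the first column is
#'   the global-ancestry score used in trait adjustment.
#' @slot explainedVariance proportion of (standardized) genotypic variance
#'   per component, decreasing.
#' @slot nSnvsUsed number of polymorphic SNVs entering the PCA.
#' @slot nMonomorphicDropped number of monomorphic SNVs dropped.
#' @seealso [computeGlobalPCs()], [bootstrapPCStability()]
#' @export
setClass("GlobalPCScores",
         representation(scores = "matrix", explainedVariance = "numeric",
                        nSnvsUsed = "integer", nMonomorphicDropped = "integer"))

setValidity("GlobalPCScores", function(object) {
    msg <- NULL
    if (ncol(object@scores) != length(object@explainedVariance))
        msg <- c(msg, "one explained-variance entry per component required")
    if (is.unsorted(rev(object@explainedVariance)))
        msg <- c(msg, "components must be ordered by decreasing variance")
    if (is.null(msg)) TRUE else msg
})

#' AdjustedPhenotype: trait residuals after covariate and ancestry adjustment
#'
#' Residuals of the quantitative trait after ordinary least squares on age,
#' sex, medication status and the global-ancestry principal component score.
#' These residuals are the working phenotype Y of the scan; both SPA
#' statistics compare carrier means against the overall mean of Y.
#'
#' @slot y numeric residual vector, named by subject id; mean numerically 0.
#' @slot rSquared fraction of trait variance explained by the adjustment.
#' @slot terms character names of the design-matrix columns used.
#' @seealso [adjustPhenotype()]
#' @export
setClass("AdjustedPhenotype",
         representation(y = "numeric", rSquared = "numeric",
                        terms = "character"))

setValidity("AdjustedPhenotype", function(object) {
    msg <- NULL
    s <- stats::sd(object@y)
    if (length(object@y) > 1 && is.finite(s) && s > 0 &&
        abs(mean(object@y)) >= 1e-8 * s)
        msg <- c(msg, "residuals must have mean numerically zero")
    if (length(object@rSquared) != 1 || object@rSquared < -1e-12 ||
        object@rSquared > 1 + 1e-12)
        msg <- c(msg, "rSquared must be a single value in [0, 1]")
    if (is.null(msg)) TRUE else msg
})
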