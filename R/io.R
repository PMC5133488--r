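#' Read a genotype matrix from VCF or matrix text format
#'
#' Builds a \linkS4class{GenotypeMatrix} of minor-allele dosages. The minor
#' allele is fixed per SNV at load time from the full sample: the allele with
#' frequency at most 0.5, ties broken towards the VCF ALT allele (or the
#' allele coded 1 in matrix input). Fixing the orientation once keeps carrier
#' definitions stable across all downstream stages.
#'
#' The matrix dialect is: rows = subjects, columns = SNVs, first column the
#' subject id, header row the SNV ids; a companion metadata TSV (columns
#' \code{snv}, \code{chrom}, \code{pos}) supplies per-SNV coordinates.
#'
#' @param path path to a VCF (v4.x, GT field, diploid, biallelic) or a
#'   dosage matrix TSV.
#' @param format \code{"vcf"} or \code{"matrix_tsv"}.
#' @param metaPath SNV metadata TSV; required when \code{format} is
#'   \code{"matrix_tsv"}.
#' @return a \linkS4class{GenotypeMatrix}; missing genotypes (\code{./.} or
#'   empty cells) become \code{NA}.
#' @export
readGenotypes <- function(path, format = c("vcf", "matrix_tsv"),
                          metaPath = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "vcf") .readGenotypesVcf(path) else {
        if (is.null(metaPath))
            stop("matrix_tsv format requires 'metaPath' (SNV metadata TSV)")
        .readGenotypesMatrix(path, metaPath)
    }
}

.readGenotypesVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
    if (any(nalt != 1L))
        stop("multi-allelic or ALT-less record(s) at row(s): ",
             paste(utils::head(which(nalt != 1L), 5L), collapse = ", "),
             " -- decompose to biallelic sites first")
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    ok <- c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1",
            "./.", ".|.", ".")
    bad <- matrix(!(gt %in% ok), nrow(gt))
    if (any(bad)) {
        i <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("unsupported GT '%s' at record %d, sample %d %s",
                     gt[bad][1L], i[1L], i[2L],
                     "(diploid biallelic calls only)"))
    }
    alt <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    alt[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    alt[gt %in% c("1/1", "1|1")] <- 2L
    alt[gt %in% c("./.", ".|.", ".")] <- NA_integer_
    rr <- SummarizedExperiment::rowRanges(vcf)
    g <- GenotypeMatrix(t(alt),
                        chrom = as.character(GenomicRanges::seqnames(rr)),
                        pos = GenomicRanges::start(rr))
    .orientMinor(g)
}

.readGenotypesMatrix <- function(path, metaPath) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("matrix file needs id column plus >=1 SNV: ", path)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate subject id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    d <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(d) <- "integer"
    rownames(d) <- ids
    meta <- utils::read.delim(metaPath, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    need <- c("snv", "chrom", "pos")
    if (!all(need %in% colnames(meta)))
        stop("SNV metadata must have columns: ", paste(need, collapse = ", "))
    m <- match(colnames(d), meta$snv)
    if (anyNA(m))
        stop("SNV(s) missing from metadata: ",
             paste(utils::head(colnames(d)[is.na(m)], 5L), collapse = ", "))
    g <- GenotypeMatrix(d, chrom = meta$chrom[m], pos = meta$pos[m])
    .orientMinor(g)
}

# Flip dosages at SNVs where the coded allele has sample frequency > 0.5,
# so dosage always counts the minor allele (tie at 0.5 keeps the coding).
.orientMinor <- function(g) {
    d <- SummarizedExperiment::assay(g, "dosage")
    f <- rowMeans(d, na.rm = TRUE) / 2
    flip <- !is.na(f) & f > 0.5
    if (any(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
    SummarizedExperiment::assay(g, "dosage") <- d
    rowData(g)$flipped <- flip
    validObject(g)
    g
}

#' Read a phenotype/covariate table
#'
#' Expects a tab- or comma-delimited file with header columns \code{id},
#' \code{trait}, \code{age}, \code{sex} and \code{medication}. Medication may
#' take at most 3 observed levels (on / not on / unknown status); subjects
#' with unknown status are kept as their own level rather than dropped.
#'
#' @param path delimited text file.
#' @param genotypes optional \linkS4class{GenotypeMatrix}; when supplied the
#'   table is checked against and reordered to the genotype subjects
#'   (alignment is always by id, never by row order).
#' @return a data.frame with columns id, trait, age, sex, medication.
#' @export
readPhenotypes <- function(path, genotypes = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    need <- c("id", "trait", "age", "sex", "medication")
    if (!all(need %in% colnames(tab)))
        stop("phenotype table must have columns: ",
             paste(setdiff(need, colnames(tab)), collapse = ", "))
    tab$id <- as.character(tab$id)
    if (anyDuplicated(tab$id))
        stop("duplicate subject id(s) in phenotypes: ",
             paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
    validatePhenotypes(tab)
    if (!is.null(genotypes)) tab <- alignPhenotypes(tab, genotypes)
    tab
}

#' Validate a phenotype table's invariants
#' @param pheno data.frame as returned by [readPhenotypes()].
#' @return the table, invisibly; errors on violation.
#' @export
validatePhenotypes <- function(pheno) {
    if (!is.numeric(pheno$trait) || !is.numeric(pheno$age))
        stop("trait and age must be numeric")
    if (length(unique(pheno$sex)) > 2L)
        stop("sex must be a binary category; observed levels: ",
             paste(unique(pheno$sex), collapse = ", "))
    nmed <- length(unique(pheno$medication))
    if (nmed > 3L)
        stop("medication must have at most 3 levels; observed ", nmed, ": ",
             paste(unique(pheno$medication), collapse = ", "))
    invisible(pheno)
}

#' Align a phenotype table to genotype subjects by id
#' @param pheno phenotype data.frame.
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @return the table reordered to \code{subjectIds(genotypes)}.
#' @export
alignPhenotypes <- function(pheno, genotypes) {
    gids <- subjectIds(genotypes)
    missingG <- setdiff(gids, pheno$id)
    if (length(missingG))
        stop("genotyped subject(s) absent from phenotypes: ",
             paste(missingG, collapse = ", "))
    extra <- setdiff(pheno$id, gids)
    if (length(extra))
        stop("phenotype subject(s) absent from genotypes: ",
             paste(extra, collapse = ", "))
    out <- pheno[match(gids, pheno$id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Impute missing genotypes by within-SNV resampling
#'
#' Each missing dosage at a SNV is replaced by a draw made uniformly over the
#' multiset of observed dosages at that SNV (so imputed values follow the
#' SNV's empirical genotype distribution). Non-missing entries are never
#' touched; a fully observed matrix is returned unchanged.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param seed integer; draws are deterministic given the seed.
#' @return a complete \linkS4class{GenotypeMatrix}.
#' @export
imputeMissing <- function(g, seed = 1L) {
    d <- SummarizedExperiment::assay(g, "dosage")
    miss <- is.na(d)
    if (!any(miss)) return(g)
    nMissRow <- rowSums(miss)
    allMiss <- which(nMissRow == ncol(d))
    if (length(allMiss))
        stop("SNV(s) with all genotypes missing: ",
             paste(utils::head(rownames(d)[allMiss], 5L), collapse = ", "))
    rows <- which(nMissRow > 0L)
    withSeed(seed, {
        for (i in rows) {
            obs <- d[i, !miss[i, ]]
            d[i, miss[i, ]] <- sample(obs, nMissRow[i], replace = TRUE)
        }
    })
    SummarizedExperiment::assay(g, "dosage") <- d
    validObject(g)
    g
}

#' Write a region scan result table
#'
#' Tab-separated, one row per region: chromosome, position of the first and
#' last SNV (1-based), number of rare variants, observed statistics and the
#' three permutation p-values (global and local for the ancestry-partitioned
#' statistic, plus the marginal statistic's p-value).
#'
#' @param results data.frame from [runScan()]; must be non-empty.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
    if (!is.data.frame(results) || nrow(results) == 0L)
        stop("results must be a non-empty data.frame")
    lead <- c("chrom", "pos_first", "pos_last", "n_rare",
              "global_p_IA", "local_p_IA", "p_I1")
    if (!all(lead %in% colnames(results)))
        stop("results lack required column(s): ",
             paste(setdiff(lead, colnames(results)), collapse = ", "))
    out <- results[, c(lead, setdiff(colnames(results), lead)), drop = FALSE]
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                          conditionMessage(ok))
    invisible(path)
}
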