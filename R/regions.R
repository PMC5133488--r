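# Stage 2: fixed-size windows of consecutive SNVs per chromosome, each
# stratified into rare and common variants by folded minor allele frequency.

#' Per-SNV minor allele frequency
#'
#' \code{maf_i = (sum of dosages at i) / (2 n)}, folded to
#' \code{min(f, 1 - f)} so the value always refers to the less common allele.
#' Requires a complete (imputed) matrix.
#'
#' @param g a \linkS4class{GenotypeMatrix} with no missing dosages.
#' @return numeric vector in \code{[0, 0.5]}, one entry per SNV in canonical
#'   order, named by SNV id.
#' @export
computeMAF <- function(g) {
    d <- SummarizedExperiment::assay(g, "dosage")
    if (anyNA(d)) stop("dosages contain missing values; run imputeMissing()")
    f <- rowSums(d) / (2 * ncol(d))
    stats::setNames(pmin(f, 1 - f), rownames(d))
}

#' Partition SNVs into fixed-size chromosome windows
#'
#' Within each chromosome, consecutive SNVs (in file order) are grouped into
#' blocks of \code{regionSize}; a trailing block of fewer SNVs becomes its own
#' region and is flagged \code{partial}. Regions never span chromosomes. Each
#' region's SNVs are split by MAF: rare when \code{maf < mafCutoff}, common
#' otherwise (a MAF exactly at the cutoff is classed common, keeping the rare
#' set strictly rare).
#'
#' @param g a complete \linkS4class{GenotypeMatrix}.
#' @param regionSize SNVs per window (default 500).
#' @param mafCutoff rare/common threshold in (0, 0.5) (default 0.05).
#' @return a \link[GenomicRanges]{GRanges}, one range per region spanning the
#'   first to last SNV position, with metadata columns \code{region_id},
#'   \code{idx_start}/\code{idx_end} (1-based closed range into the canonical
#'   SNV index), \code{n_snvs}, \code{n_rare}, \code{n_common},
#'   \code{partial}, and \code{rare_idx}/\code{common_idx}
#'   (\link[IRanges]{IntegerList} of absolute SNV indices). The per-SNV MAF
#'   vector and the cutoff are stored in \code{metadata()}.
#' @export
partitionRegions <- function(g, regionSize = 500L, mafCutoff = 0.05) {
    if (regionSize < 2L) stop("regionSize must be at least 2")
    if (mafCutoff <= 0 || mafCutoff >= 0.5)
        stop("mafCutoff must lie strictly between 0 and 0.5")
    maf <- computeMAF(g)
    rd <- rowData(g)
    chrom <- as.character(rd$chrom)
    pos <- rd$pos
    # chromosomes in order of first appearance; SNVs are contiguous per
    # chromosome in canonical order (validity guarantees position sorting)
    chromLevels <- unique(chrom)
    ri <- 0L
    rows <- list()
    for (ch in chromLevels) {
        idx <- which(chrom == ch)
        if (length(idx) > 1L && any(diff(idx) != 1L))
            stop("SNVs of chromosome ", ch,
                 " are not contiguous in file order")
        starts <- seq.int(1L, length(idx), by = regionSize)
        for (s in starts) {
            e <- min(s + regionSize - 1L, length(idx))
            ri <- ri + 1L
            rows[[ri]] <- list(chrom = ch, i0 = idx[s], i1 = idx[e])
        }
    }
    i0 <- vapply(rows, `[[`, integer(1L), "i0")
    i1 <- vapply(rows, `[[`, integer(1L), "i1")
    chR <- vapply(rows, `[[`, character(1L), "chrom")
    rareIdx <- lapply(seq_along(rows), function(r) {
        ii <- i0[r]:i1[r]
        ii[maf[ii] < mafCutoff]
    })
    commonIdx <- lapply(seq_along(rows), function(r) {
        ii <- i0[r]:i1[r]
        ii[maf[ii] >= mafCutoff]
    })
    gr <- GenomicRanges::GRanges(
        seqnames = chR,
        ranges = IRanges::IRanges(start = pos[i0], end = pos[i1]))
    S4Vectors::mcols(gr) <- DataFrame(
        region_id = seq_along(rows),
        idx_start = i0, idx_end = i1,
        n_snvs = i1 - i0 + 1L,
        n_rare = lengths(rareIdx),
        n_common = lengths(commonIdx),
        partial = (i1 - i0 + 1L) < regionSize,
        rare_idx = IRanges::IntegerList(rareIdx),
        common_idx = IRanges::IntegerList(commonIdx))
    metadata(gr)$maf <- maf
    metadata(gr)$maf_cutoff <- mafCutoff
    metadata(gr)$region_size <- as.integer(regionSize)
    gr
}

#' Export region boundaries as BED
#'
#' Standard BED convention: 0-based half-open intervals.
#'
#' @param regions GRanges from [partitionRegions()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportRegionsBED <- function(regions, path) {
    bed <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(regions)),
        start = GenomicRanges::start(regions) - 1L,
        end = GenomicRanges::end(regions),
        name = sprintf("region_%d", S4Vectors::mcols(regions)$region_id))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
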