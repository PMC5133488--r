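# Orchestration of the four-stage scan over all regions.

#' Scan configuration
#'
#' Defaults follow the method's standard settings: 500-SNV regions, MAF
#' cutoff 0.05, one global PC in the adjustment, 3 local PCs clustered with
#' k = 3, and 10000 permutations.
#'
#' @param regionSize SNVs per region window.
#' @param mafCutoff rare/common MAF threshold.
#' @param nPcsGlobal global PCs entering the trait adjustment.
#' @param nPcsLocal PCs clustered for local ancestry.
#' @param kClusters ancestry clusters per region.
#' @param nRestarts k-means++ restarts.
#' @param nPermutations permutations per region and scheme.
#' @param seed master seed; all per-region/per-scheme streams derive from it.
#' @param scaling PCA standardization, \code{"unit"} or \code{"patterson"}.
#' @param mode SPA weighting, \code{"carrier"} (default) or the experimental
#'   \code{"allele"}.
#' @param adjustP add Bonferroni and Benjamini-Hochberg columns for the three
#'   p-values (off by default; raw permutation p-values are reported).
#' @param verbose log per-stage progress to stderr.
#' @return a validated list of class \code{"scanConfig"}.
#' @export
scanConfig <- function(regionSize = 500L, mafCutoff = 0.05, nPcsGlobal = 1L,
                       nPcsLocal = 3L, kClusters = 3L, nRestarts = 10L,
                       nPermutations = 10000L, seed = 1L,
                       scaling = c("unit", "patterson"),
                       mode = c("carrier", "allele"), adjustP = FALSE,
                       verbose = FALSE) {
    cfg <- list(regionSize = as.integer(regionSize), mafCutoff = mafCutoff,
                nPcsGlobal = as.integer(nPcsGlobal),
                nPcsLocal = as.integer(nPcsLocal),
                kClusters = as.integer(kClusters),
                nRestarts = as.integer(nRestarts),
                nPermutations = as.integer(nPermutations),
                seed = as.integer(seed), scaling = match.arg(scaling),
                mode = match.arg(mode), adjustP = isTRUE(adjustP),
                verbose = isTRUE(verbose))
    stopifnot(cfg$regionSize >= 2L, cfg$mafCutoff > 0, cfg$mafCutoff < 0.5,
              cfg$nPcsGlobal >= 1L, cfg$nPcsLocal >= 1L, cfg$kClusters >= 1L,
              cfg$nRestarts >= 1L, cfg$nPermutations >= 1L)
    class(cfg) <- "scanConfig"
    cfg
}

#' Run the full region-based scan
#'
#' Executes the four stages over all regions: (1) covariate + global-ancestry
#' adjustment of the trait, (2) partition of SNVs into fixed-size windows
#' split into rare and common variants, (3) local-ancestry inference from each
#' window's common variants and evaluation of the SPA statistics on its rare
#' variants, (4) three permutation p-values per region. Missing genotypes are
#' imputed first when present. Everything is reproducible from the master
#' seed; per-region streams are derived from (seed, region id, scheme), so
#' results do not depend on processing order.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param pheno phenotype data.frame (see [readPhenotypes()]); aligned to the
#'   genotypes by id internally.
#' @param config a [scanConfig()].
#' @return data.frame with one row per region (sorted by chromosome and
#'   position): region id and coordinates, rare/common counts, observed
#'   \code{I1}/\code{IA}, the three permutation p-values, and a
#'   semicolon-joined \code{flags} column. The adjustment \eqn{R^2}, PC
#'   explained variance and the config are attached as attributes.
#' @export
runScan <- function(g, pheno, config = scanConfig()) {
    stopifnot(is(g, "GenotypeMatrix"), inherits(config, "scanConfig"))
    pheno <- alignPhenotypes(validatePhenotypes(pheno), g)
    d <- SummarizedExperiment::assay(g, "dosage")
    if (anyNA(d)) {
        laspaMessage(config$verbose, "imputing missing genotypes")
        g <- imputeMissing(g, seed = deriveSeed(config$seed, 9L))
        d <- SummarizedExperiment::assay(g, "dosage")
    }
    laspaMessage(config$verbose, "stage 1: global PCs + trait adjustment")
    pcs <- computeGlobalPCs(g, config$nPcsGlobal, config$scaling)
    adj <- adjustPhenotype(pheno, pcScores(pcs))
    y <- residualsY(adj)
    laspaMessage(config$verbose, sprintf("adjustment R^2 = %.3f", adj@rSquared))
    laspaMessage(config$verbose, "stage 2: partitioning regions")
    regions <- partitionRegions(g, config$regionSize, config$mafCutoff)
    mc <- S4Vectors::mcols(regions)
    nR <- length(regions)
    laspaMessage(config$verbose, sprintf(
        "%d regions; stage 3-4 over %d permutations x 3 schemes", nR,
        config$nPermutations))
    rows <- vector("list", nR)
    for (r in seq_len(nR)) {
        ci <- mc$common_idx[[r]]
        la <- inferLocalAncestry(
            t(d[ci, , drop = FALSE]), nPcs = config$nPcsLocal,
            k = config$kClusters, nRestarts = config$nRestarts,
            seed = deriveSeed(config$seed, r, 101L), scaling = config$scaling)
        gRare <- t(d[mc$rare_idx[[r]], , drop = FALSE])
        cs <- buildCarriers(gRare)
        rp <- suppressWarnings(regionPValues(
            y, cs, la, B = config$nPermutations,
            seed = deriveSeed(config$seed, r, 202L), mode = config$mode,
            gRare = if (config$mode == "allele") gRare else NULL))
        rows[[r]] <- data.frame(
            region_id = mc$region_id[r],
            chrom = as.character(GenomicRanges::seqnames(regions)[r]),
            pos_first = GenomicRanges::start(regions)[r],
            pos_last = GenomicRanges::end(regions)[r],
            n_snvs = mc$n_snvs[r], n_rare = mc$n_rare[r],
            n_common = mc$n_common[r], J = nClusters(la),
            I1 = rp$I1, IA = rp$IA,
            global_p_IA = rp$global_p_IA, local_p_IA = rp$local_p_IA,
            p_I1 = rp$p_I1, n_permutations = rp$B,
            flags = paste(rp$flags, collapse = ";"),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    chromNum <- suppressWarnings(as.numeric(sub("^chr", "", res$chrom,
                                                ignore.case = TRUE)))
    res <- res[order(is.na(chromNum), chromNum, res$chrom, res$pos_first), ,
               drop = FALSE]
    rownames(res) <- NULL
    if (config$adjustP) {
        for (col in c("global_p_IA", "local_p_IA", "p_I1")) {
            res[[paste0(col, "_bonf")]] <- stats::p.adjust(res[[col]],
                                                           "bonferroni")
            res[[paste0(col, "_bh")]] <- stats::p.adjust(res[[col]], "BH")
        }
    }
    nFlag <- sum(nzchar(res$flags))
    laspaMessage(config$verbose, sprintf("done; %d region(s) flagged", nFlag))
    attr(res, "config") <- config
    attr(res, "rSquared") <- adj@rSquared
    attr(res, "explainedVariance") <- pcs@explainedVariance
    res
}

#' Manhattan plot of region p-values
#'
#' Plots \eqn{-\log_{10} p} per region for the three p-value series, regions
#' in genome order and chromosomes alternately shaded.
#'
#' @param results data.frame from [runScan()].
#' @param path optional PNG path; when given the plot is written there.
#' @param width,height,res PNG device parameters.
#' @return \code{path} (or \code{NULL} when plotting to the active device),
#'   invisibly.
#' @export
plotManhattan <- function(results, path = NULL, width = 1600, height = 600,
                          res = 120) {
    ok <- !is.na(results$global_p_IA)
    x <- seq_len(nrow(results))
    if (!is.null(path)) {
        grDevices::png(path, width = width, height = height, res = res)
        on.exit(grDevices::dev.off())
    }
    ymax <- max(-log10(unlist(results[ok, c("global_p_IA", "local_p_IA",
                                            "p_I1")])), 1) * 1.1
    graphics::plot(NA, xlim = range(x), ylim = c(0, ymax),
                   xlab = "region (genome order)",
                   ylab = expression(-log[10] ~ p), main = "Region scan")
    chroms <- unique(results$chrom)
    for (i in seq_along(chroms)) {
        xr <- range(x[results$chrom == chroms[i]])
        if (i %% 2L == 0L)
            graphics::rect(xr[1] - 0.5, 0, xr[2] + 0.5, ymax,
                           col = "grey93", border = NA)
    }
    graphics::points(x[ok], -log10(results$global_p_IA[ok]), pch = 16,
                     col = "#1b6ca8", cex = 0.7)
    graphics::points(x[ok], -log10(results$local_p_IA[ok]), pch = 17,
                     col = "#c84b31", cex = 0.7)
    graphics::points(x[ok], -log10(results$p_I1[ok]), pch = 1,
                     col = "grey40", cex = 0.7)
    graphics::legend("topright", bty = "n", pch = c(16, 17, 1),
                     col = c("#1b6ca8", "#c84b31", "grey40"),
                     legend = c("global p (IA)", "local p (IA)", "p (I1)"))
    invisible(path)
}
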