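# Stage 3a: local ancestry within a region from its common variants, by PCA
# on standardized dosages followed by k-means on the leading score columns.

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance from the nearest chosen center.
# Returns row indices; fewer than k if the data have fewer distinct points.
.kmeansppCenters <- function(x, k) {
    n <- nrow(x)
    centers <- integer(0L)
    first <- sample.int(n, 1L)
    centers <- first
    d2 <- rowSums(sweep(x, 2L, x[first, ], "-")^2)
    while (length(centers) < k) {
        if (all(d2 <= 0)) break   # no distinct point left
        nxt <- sample.int(n, 1L, prob = d2)
        centers <- c(centers, nxt)
        d2 <- pmin(d2, rowSums(sweep(x, 2L, x[nxt, ], "-")^2))
    }
    centers
}

.kmeansBest <- function(x, k, nRestarts) {
    best <- NULL
    for (r in seq_len(nRestarts)) {
        ctr <- .kmeansppCenters(x, k)
        if (length(ctr) < k) return(NULL)     # fewer distinct points than k
        fit <- tryCatch(
            stats::kmeans(x, centers = x[ctr, , drop = FALSE],
                          iter.max = 100L),
            error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit) || any(fit$size == 0L)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
}

#' Infer local ancestry for one region
#'
#' PCA (same standardization convention as the global stage) on the region's
#' common variants, then k-means with k-means++ initialization on the first
#' \code{nPcs} score columns, keeping the best of \code{nRestarts} starts by
#' within-cluster sum of squares. Labels are anonymous cluster indices: the
#' statistic downstream only needs a partition of subjects per region, so no
#' identity of clusters across regions is claimed.
#'
#' Degenerate regions are handled rather than failed: with fewer polymorphic
#' common SNVs than \code{nPcs} the region is flagged
#' \code{ancestry_unassignable} and all subjects fall into one cluster; if
#' every k-means start yields an empty cluster (or there are fewer distinct
#' score points than \code{k}), the fit is retried with \code{k - 1} and
#' flagged \code{cluster_fallback}.
#'
#' @param gCommon numeric/integer matrix of dosages at the region's common
#'   SNVs, subjects in rows.
#' @param nPcs number of leading PCs to cluster on (default 3).
#' @param k number of ancestry clusters (default 3).
#' @param nRestarts k-means++ restarts (default 10).
#' @param seed integer seed; the fit is deterministic given it.
#' @param scaling PCA standardization, as in [computeGlobalPCs()].
#' @return a \linkS4class{LocalAncestry}.
#' @export
inferLocalAncestry <- function(gCommon, nPcs = 3L, k = 3L, nRestarts = 10L,
                               seed = 1L, scaling = c("unit", "patterson")) {
    stopifnot(nPcs >= 1L, k >= 1L, nRestarts >= 1L)
    scaling <- match.arg(scaling)
    gCommon <- as.matrix(gCommon)
    n <- nrow(gCommon)
    d <- t(gCommon)                      # SNVs x subjects for the PCA helper
    nPoly <- sum(rowSums((d - rowMeans(d))^2) > 0)
    if (nPoly < nPcs) {
        return(new("LocalAncestry", labels = rep(1L, n), J = 1L,
                   clusterSizes = n,
                   pcScores = matrix(numeric(0L), nrow = n, ncol = 0L),
                   flags = "ancestry_unassignable"))
    }
    scores <- .pcaScores(d, nPcs, scaling)$scores
    flags <- character(0L)
    fit <- NULL
    kk <- k
    withSeed(seed, {
        repeat {
            fit <- if (kk == 1L)
                list(cluster = rep(1L, n), size = n)
            else .kmeansBest(scores, kk, nRestarts)
            if (!is.null(fit)) break
            kk <- kk - 1L
            flags <- unique(c(flags, "cluster_fallback"))
        }
    })
    labels <- as.integer(fit$cluster)
    new("LocalAncestry", labels = labels, J = as.integer(kk),
        clusterSizes = as.integer(tabulate(labels, kk)),
        pcScores = scores, flags = flags)
}
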