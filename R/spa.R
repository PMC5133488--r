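# Stage 3b: the summation partition approach (SPA) statistics.
#
# For a region with K rare variants, the marginal statistic is
#     I1 = sum_i n_i^2 (Ybar_i - Ybar)^2
# where n_i is the number of carriers of variant i (subjects with dosage >= 1),
# Ybar_i the mean adjusted phenotype over those carriers, and Ybar the overall
# sample mean. The local-ancestry partitioned statistic is
#     IA = sum_j sum_i n_{i,j}^2 (Ybar_{i,j} - Ybar)^2
# with the inner quantities restricted to carriers in ancestry cluster j; Ybar
# stays the overall mean. Zero-carrier terms contribute 0 (weight n^2 = 0), so
# monomorphic rare variants never produce NaN. With J = 1, IA collapses to I1
# exactly.

#' Build the carrier structure of a region's rare variants
#'
#' A carrier is a subject with at least one copy of the minor allele; a
#' homozygote counts once as a carrier (dosage 2 contributes a single subject
#' to the carrier set). Variants without carriers are retained — they carry
#' zero weight in the statistics.
#'
#' @param gRare matrix of dosages at the region's rare SNVs, subjects in rows;
#'   zero columns (\code{K = 0}) are allowed and yield an empty structure.
#' @return a \linkS4class{CarrierStructure}.
#' @export
buildCarriers <- function(gRare) {
    gRare <- as.matrix(gRare)
    if (anyNA(gRare)) stop("dosages contain missing values; impute first")
    n <- nrow(gRare)
    K <- ncol(gRare)
    carriers <- lapply(seq_len(K), function(i) which(gRare[, i] >= 1L))
    new("CarrierStructure",
        carriers = carriers,
        counts = as.integer(lengths(carriers)),
        alleleCounts = as.integer(if (K) colSums(gRare) else integer(0L)),
        nSubjects = as.integer(n))
}

# Per-cluster sparse precomputation shared by the exported statistics and the
# permutation engine: for each cluster j, the carrier indicator restricted to
# the cluster's subjects, the per-variant carrier counts c_{ij}, and the
# squared weights w_{ij}^2 (carrier counts by default; within-cluster allele
# counts in the experimental allele mode).
.spaPrecompute <- function(cs, labels = NULL, mode = c("carrier", "allele"),
                           gRare = NULL) {
    mode <- match.arg(mode)
    n <- cs@nSubjects
    K <- length(cs@counts)
    if (is.null(labels)) labels <- rep(1L, n)
    stopifnot(length(labels) == n)
    J <- max(labels)
    Z <- Matrix::sparseMatrix(i = unlist(cs@carriers),
                              j = rep.int(seq_len(K), cs@counts),
                              x = 1, dims = c(n, K))
    Zw <- if (mode == "allele") {
        if (is.null(gRare))
            stop("allele mode needs the rare-dosage matrix 'gRare'")
        methods::as(Matrix::Matrix(as.matrix(gRare), sparse = TRUE),
                    "generalMatrix")
    } else Z
    clusters <- lapply(seq_len(J), function(j) {
        rows <- which(labels == j)
        Zj <- Z[rows, , drop = FALSE]
        cts <- Matrix::colSums(Zj)
        w <- if (mode == "allele")
            Matrix::colSums(Zw[rows, , drop = FALSE]) else cts
        list(rows = rows, Zj = Zj, counts = cts, w = w, keep = cts > 0)
    })
    list(n = n, K = K, J = J, clusters = clusters)
}

# Evaluate the partitioned statistic for every column of the phenotype matrix
# Y (n x B). Returns total (length B) and the per-cluster decomposition
# (J x B). The identity n^2 (S/n - ybar)^2 = (S - n ybar)^2 with S the carrier
# phenotype sum lets everything run as one sparse cross-product per cluster.
.spaStat <- function(pre, Y, ybar) {
    B <- ncol(Y)
    per <- matrix(0, pre$J, B)
    for (j in seq_len(pre$J)) {
        cl <- pre$clusters[[j]]
        if (!any(cl$keep)) next
        S <- as.matrix(Matrix::crossprod(cl$Zj, Y[cl$rows, , drop = FALSE]))
        keep <- cl$keep
        dev <- (cl$w[keep] / cl$counts[keep]) * S[keep, , drop = FALSE] -
            cl$w[keep] * ybar
        per[j, ] <- colSums(dev^2)
    }
    list(total = colSums(per), perCluster = per)
}

#' Marginal SPA statistic I1
#'
#' @param y numeric adjusted-phenotype vector (or an
#'   \linkS4class{AdjustedPhenotype}), one value per subject.
#' @param carriers a \linkS4class{CarrierStructure} for the region.
#' @param mode \code{"carrier"} weights each variant by its carrier count
#'   (default); \code{"allele"} weights by minor-allele count (experimental
#'   alternative reading, requires \code{gRare}).
#' @param gRare rare-dosage matrix, only for \code{mode = "allele"}.
#' @return the non-negative statistic, or \code{NA} when the region has no
#'   rare variants (K = 0, signalled with a warning).
#' @examples
#' y <- c(2, 0, -2, 4, -4)
#' cs <- buildCarriers(cbind(a = c(1,1,0,0,0), b = c(0,0,0,2,0)))
#' computeI1(y, cs)   # 2^2 * 1^2 + 1^2 * 4^2 = 20
#' @export
computeI1 <- function(y, carriers, mode = c("carrier", "allele"),
                      gRare = NULL) {
    if (is(y, "AdjustedPhenotype")) y <- residualsY(y)
    if (length(carriers@counts) == 0L) {
        warning("region has no rare variants; I1 undefined")
        return(NA_real_)
    }
    stopifnot(length(y) == carriers@nSubjects)
    pre <- .spaPrecompute(carriers, NULL, match.arg(mode), gRare)
    .spaStat(pre, matrix(y, ncol = 1L), mean(y))$total
}

#' Local-ancestry partitioned SPA statistic IA
#'
#' @inheritParams computeI1
#' @param ancestry a \linkS4class{LocalAncestry} (or an integer label vector)
#'   partitioning subjects for this region.
#' @return list with \code{IA} (non-negative total) and \code{perCluster}
#'   (length-J additive decomposition); \code{IA = NA} when K = 0.
#' @examples
#' y <- c(2, 0, -2, 4, -4)
#' cs <- buildCarriers(cbind(v = c(1,0,0,1,0)))
#' computeIA(y, cs, c(1L,1L,1L,2L,2L))$IA   # 1*2^2 + 1*4^2 = 20
#' @export
computeIA <- function(y, carriers, ancestry, mode = c("carrier", "allele"),
                      gRare = NULL) {
    if (is(y, "AdjustedPhenotype")) y <- residualsY(y)
    labels <- if (is(ancestry, "LocalAncestry")) ancestryLabels(ancestry)
              else as.integer(ancestry)
    if (length(carriers@counts) == 0L) {
        warning("region has no rare variants; IA undefined")
        return(list(IA = NA_real_, perCluster = rep(NA_real_,
                                                    max(labels, 1L))))
    }
    stopifnot(length(y) == carriers@nSubjects,
              length(labels) == carriers@nSubjects)
    pre <- .spaPrecompute(carriers, labels, match.arg(mode), gRare)
    st <- .spaStat(pre, matrix(y, ncol = 1L), mean(y))
    list(IA = st$total, perCluster = as.numeric(st$perCluster))
}
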