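# Stage 4: permutation p-values. Ancestry labels are a property of the genome
# and stay fixed; only the adjusted phenotype is permuted. Two permutation
# levels give two null hypotheses for IA:
#   global  - y permuted across all subjects: phenotype independent of both
#             the region's rare variants and its ancestry structure;
#   local   - y permuted within each ancestry cluster: any phenotype-ancestry
#             association is preserved, so only the within-cluster
#             rare-variant signal is tested.
# The marginal statistic I1 gets its own globally permuted null. All p-values
# use the add-one estimator (1 + #exceedances)/(B + 1), with ties counted as
# exceedances, so p is never 0 and always >= 1/(B+1).

#' Permute a phenotype vector across all subjects
#'
#' @param y numeric vector.
#' @param seed integer seed; deterministic given it.
#' @return a uniform random rearrangement of \code{y}.
#' @export
permuteGlobal <- function(y, seed = 1L) {
    withSeed(seed, y[sample.int(length(y))])
}

#' Permute a phenotype vector within ancestry clusters
#'
#' Values are rearranged independently inside each cluster, conserving every
#' cluster's multiset of phenotypes (singleton clusters are fixed points).
#'
#' @param y numeric vector.
#' @param ancestry \linkS4class{LocalAncestry} or integer label vector aligned
#'   to \code{y}.
#' @param seed integer seed.
#' @return permuted vector.
#' @export
permuteLocal <- function(y, ancestry, seed = 1L) {
    labels <- if (is(ancestry, "LocalAncestry")) ancestryLabels(ancestry)
              else as.integer(ancestry)
    stopifnot(length(labels) == length(y))
    withSeed(seed, {
        out <- y
        for (j in unique(labels)) {
            rows <- which(labels == j)
            if (length(rows) > 1L)
                out[rows] <- y[rows][sample.int(length(rows))]
        }
        out
    })
}

# Build an n x B matrix of permuted phenotypes (global or within-cluster).
.permMatrix <- function(y, B, labels = NULL) {
    n <- length(y)
    out <- matrix(0, n, B)
    if (is.null(labels)) {
        for (b in seq_len(B)) out[, b] <- y[sample.int(n)]
    } else {
        idxByCluster <- split(seq_len(n), labels)
        for (b in seq_len(B)) {
            yp <- y
            for (rows in idxByCluster) {
                if (length(rows) > 1L)
                    yp[rows] <- y[rows][sample.int(length(rows))]
            }
            out[, b] <- yp
        }
    }
    out
}

#' Permutation p-values for one region
#'
#' Computes the observed I1 and IA and three permutation p-values: the global
#' and local p-values of IA (unrestricted vs within-cluster phenotype
#' permutation) and the p-value of I1 (unrestricted permutation). The three
#' schemes use independent permutation streams derived from \code{seed}, and
#' permuted statistics are evaluated through the same code path as the
#' observed ones so ties are exact.
#'
#' @param y adjusted phenotype (numeric vector or
#'   \linkS4class{AdjustedPhenotype}).
#' @param carriers \linkS4class{CarrierStructure} for the region's rare
#'   variants.
#' @param ancestry \linkS4class{LocalAncestry} for the region.
#' @param B number of permutations (default 10000).
#' @param seed integer seed.
#' @param mode,gRare see [computeI1()].
#' @param blockSize permutations evaluated per memory block.
#' @return list with \code{I1}, \code{IA}, \code{perClusterIA},
#'   \code{global_p_IA}, \code{local_p_IA}, \code{p_I1}, \code{B} and
#'   \code{flags}. A region with no rare variants returns \code{NA} statistics
#'   and p-values with flag \code{no_rare_variants}.
#' @export
regionPValues <- function(y, carriers, ancestry, B = 10000L, seed = 1L,
                          mode = c("carrier", "allele"), gRare = NULL,
                          blockSize = 2000L) {
    if (is(y, "AdjustedPhenotype")) y <- residualsY(y)
    mode <- match.arg(mode)
    stopifnot(B >= 1L)
    labels <- if (is(ancestry, "LocalAncestry")) ancestryLabels(ancestry)
              else as.integer(ancestry)
    flags <- if (is(ancestry, "LocalAncestry")) ancestry@flags else character(0)
    if (length(carriers@counts) == 0L) {
        return(list(I1 = NA_real_, IA = NA_real_, perClusterIA = NA_real_,
                    global_p_IA = NA_real_, local_p_IA = NA_real_,
                    p_I1 = NA_real_, B = as.integer(B),
                    flags = unique(c(flags, "no_rare_variants"))))
    }
    stopifnot(length(y) == carriers@nSubjects,
              length(labels) == carriers@nSubjects)
    ybar <- mean(y)
    pre1 <- .spaPrecompute(carriers, NULL, mode, gRare)
    preA <- .spaPrecompute(carriers, labels, mode, gRare)
    obs1 <- .spaStat(pre1, matrix(y, ncol = 1L), ybar)
    obsA <- .spaStat(preA, matrix(y, ncol = 1L), ybar)

    countExceed <- function(pre, obs, schemeSeed, clusterLabels) {
        exceed <- 0L
        withSeed(schemeSeed, {
            done <- 0L
            while (done < B) {
                nb <- min(blockSize, B - done)
                Y <- .permMatrix(y, nb, clusterLabels)
                exceed <- exceed + sum(.spaStat(pre, Y, ybar)$total >=
                                           obs)
                done <- done + nb
            }
        })
        exceed
    }
    eGlobalA <- countExceed(preA, obsA$total, deriveSeed(seed, 1L), NULL)
    eLocalA <- countExceed(preA, obsA$total, deriveSeed(seed, 2L), labels)
    eI1 <- countExceed(pre1, obs1$total, deriveSeed(seed, 3L), NULL)
    list(I1 = obs1$total, IA = obsA$total,
         perClusterIA = as.numeric(obsA$perCluster),
         global_p_IA = (1 + eGlobalA) / (B + 1),
         local_p_IA = (1 + eLocalA) / (B + 1),
         p_I1 = (1 + eI1) / (B + 1),
         B = as.integer(B), flags = flags)
}
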