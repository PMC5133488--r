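# Stage 1: global ancestry via PCA of all SNVs, bootstrap stability of the
# leading components, and residualization of the trait on covariates + PC1.

# Subject-space PCA of a (SNV x subject) dosage matrix. With n subjects and
# m >> n SNVs the n x n cross-product eigendecomposition is exact and cheap;
# SNVs are standardized per row and the matrix is streamed in chunks so the
# standardized copy never materializes. Returns scores = U * d (the subject
# loading scores), with the sign of each component fixed so that its
# largest-magnitude SNV loading is positive.
.pcaScores <- function(d, nComponents, scaling = c("unit", "patterson"),
                       chunkSize = 20000L) {
    scaling <- match.arg(scaling)
    if (anyNA(d)) stop("dosages contain missing values; run imputeMissing()")
    n <- ncol(d)
    if (n < 2L) stop("PCA needs at least 2 subjects")
    mu <- rowMeans(d)
    s <- if (scaling == "unit") {
        sqrt(rowSums((d - mu)^2) / (n - 1L))
    } else {
        p <- mu / 2
        sqrt(2 * p * (1 - p))
    }
    keep <- which(s > 0)
    nMono <- nrow(d) - length(keep)
    if (!length(keep)) stop("all SNVs are monomorphic; PCA undefined")
    nComponents <- min(nComponents, n, length(keep))
    if (length(keep) < n) {
        # fewer SNVs than subjects (per-region PCA): eigendecompose the small
        # SNV-side cross-product instead; loadings come out directly
        z <- t((d[keep, , drop = FALSE] - mu[keep]) / s[keep])   # n x m'
        eig <- eigen(crossprod(z), symmetric = TRUE)
        ev <- pmax(eig$values, 0)
        V <- eig$vectors[, seq_len(nComponents), drop = FALSE]
        for (k in seq_len(nComponents)) {
            top <- which.max(abs(V[, k]))
            if (V[top, k] < 0) V[, k] <- -V[, k]
        }
        scores <- z %*% V
        dimnames(scores) <- list(colnames(d),
                                 sprintf("PC%d", seq_len(nComponents)))
        return(list(scores = scores,
                    explainedVariance = ev[seq_len(nComponents)] / sum(ev),
                    nSnvsUsed = length(keep), nMonomorphicDropped = nMono))
    }
    C <- matrix(0, n, n)
    starts <- seq.int(1L, length(keep), by = chunkSize)
    for (st in starts) {
        idx <- keep[st:min(st + chunkSize - 1L, length(keep))]
        z <- (d[idx, , drop = FALSE] - mu[idx]) / s[idx]
        C <- C + crossprod(z)
    }
    eig <- eigen(C, symmetric = TRUE)
    ev <- pmax(eig$values, 0)
    U <- eig$vectors[, seq_len(nComponents), drop = FALSE]
    dvals <- sqrt(ev[seq_len(nComponents)])
    # SNV-side loadings (streamed) decide the sign convention
    V <- matrix(0, length(keep), nComponents)
    for (st in starts) {
        rows <- st:min(st + chunkSize - 1L, length(keep))
        idx <- keep[rows]
        z <- (d[idx, , drop = FALSE] - mu[idx]) / s[idx]
        V[rows, ] <- z %*% U
    }
    for (k in seq_len(nComponents)) {
        top <- which.max(abs(V[, k]))
        if (V[top, k] < 0) U[, k] <- -U[, k]
    }
    scores <- U %*% diag(dvals, nComponents)
    dimnames(scores) <- list(colnames(d), sprintf("PC%d", seq_len(nComponents)))
    list(scores = scores,
         explainedVariance = ev[seq_len(nComponents)] / sum(ev),
         nSnvsUsed = length(keep), nMonomorphicDropped = nMono)
}

#' Global-ancestry principal components
#'
#' PCA of the full subject-by-SNV dosage matrix after per-SNV mean centering
#' and scaling. The per-subject score on the first component is the
#' global-ancestry covariate used when adjusting the trait. Monomorphic SNVs
#' carry no information and are dropped (their count is reported on the
#' returned object). The sign of each component is fixed so its
#' largest-magnitude SNV loading is positive, making scores reproducible.
#'
#' @param g a complete (imputed) \linkS4class{GenotypeMatrix}.
#' @param nComponents number of leading components to return.
#' @param scaling \code{"unit"} (per-SNV unit variance, the default, making
#'   rare and common SNVs commensurate) or \code{"patterson"}
#'   (\eqn{\sqrt{2p(1-p)}} binomial scaling).
#' @param chunkSize SNVs per block when streaming the cross-product.
#' @return a \linkS4class{GlobalPCScores}.
#' @export
computeGlobalPCs <- function(g, nComponents = 1L,
                             scaling = c("unit", "patterson"),
                             chunkSize = 20000L) {
    stopifnot(nComponents >= 1L)
    d <- SummarizedExperiment::assay(g, "dosage")
    r <- .pcaScores(d, nComponents, match.arg(scaling), chunkSize)
    new("GlobalPCScores", scores = r$scores,
        explainedVariance = r$explainedVariance,
        nSnvsUsed = as.integer(r$nSnvsUsed),
        nMonomorphicDropped = as.integer(r$nMonomorphicDropped))
}

#' Bootstrap stability of principal component scores
#'
#' Resamples SNVs with replacement, recomputes subject PC scores on each
#' replicate, and reports per component the mean absolute Pearson correlation
#' between replicate scores and the full-data scores (absolute value, since a
#' principal component's sign is arbitrary). A component that consistently
#' captures population structure correlates near 1 across replicates; noise
#' components do not. This is the diagnostic behind using only PC1 as the
#' global-ancestry covariate.
#'
#' @param g a complete \linkS4class{GenotypeMatrix}.
#' @param nSnvsPerRep SNVs drawn (with replacement) per replicate.
#' @param nReps number of bootstrap replicates.
#' @param nComponents components assessed.
#' @param seed integer seed; resampling is deterministic given it.
#' @param scaling passed to the PCA.
#' @return data.frame with columns \code{component}, \code{meanAbsCor},
#'   \code{minAbsCor}.
#' @export
bootstrapPCStability <- function(g, nSnvsPerRep = 10000L, nReps = 1000L,
                                 nComponents = 5L, seed = 1L,
                                 scaling = c("unit", "patterson")) {
    stopifnot(nSnvsPerRep >= 2L, nReps >= 1L)
    scaling <- match.arg(scaling)
    d <- SummarizedExperiment::assay(g, "dosage")
    full <- .pcaScores(d, nComponents, scaling)$scores
    k <- ncol(full)
    cors <- matrix(NA_real_, nReps, k)
    withSeed(seed, {
        for (b in seq_len(nReps)) {
            idx <- sort(sample.int(nrow(d), nSnvsPerRep, replace = TRUE))
            rep <- try(.pcaScores(d[idx, , drop = FALSE], k, scaling)$scores,
                       silent = TRUE)
            if (inherits(rep, "try-error")) next
            kk <- min(k, ncol(rep))
            cors[b, seq_len(kk)] <-
                abs(diag(stats::cor(full[, seq_len(kk), drop = FALSE],
                                    rep[, seq_len(kk), drop = FALSE])))
        }
    })
    data.frame(component = seq_len(k),
               meanAbsCor = colMeans(cors, na.rm = TRUE),
               minAbsCor = suppressWarnings(apply(cors, 2, min, na.rm = TRUE)))
}

#' Residualize the trait on covariates and global ancestry
#'
#' Ordinary least squares of the quantitative trait on an intercept, age,
#' sex, medication status (dummy coded; the not-on-medication level is the
#' reference when present, and an unknown status is kept as its own level so
#' no subject is dropped) and the global-ancestry PC score(s). The residuals
#' are the working phenotype Y of the scan.
#'
#' @param pheno phenotype data.frame (see [readPhenotypes()]), already aligned
#'   to the genotypes.
#' @param pc1 numeric vector (or matrix of score columns) of global-ancestry
#'   scores, one row per subject in the same order.
#' @return an \linkS4class{AdjustedPhenotype} with residuals \code{y} and the
#'   model \eqn{R^2}.
#' @export
adjustPhenotype <- function(pheno, pc1) {
    pc1 <- as.matrix(pc1)
    stopifnot(nrow(pc1) == nrow(pheno))
    if (anyNA(pheno$trait) || anyNA(pheno$age) || anyNA(pheno$sex) ||
        anyNA(pc1))
        stop("missing values in trait, covariates or PC scores")
    med <- as.character(pheno$medication)
    med[is.na(med)] <- "unknown"
    lev <- unique(med)
    refCand <- intersect(c("not_on", "none", "no", "off", "0", "FALSE"), lev)
    medLevels <- if (length(refCand))
        c(refCand[1L], setdiff(sort(lev), refCand[1L])) else sort(lev)
    med <- factor(med, levels = medLevels)
    sex <- pheno$sex
    if (!is.numeric(sex)) sex <- factor(sex)
    df <- data.frame(trait = pheno$trait, age = pheno$age, sex = sex,
                     medication = med)
    for (k in seq_len(ncol(pc1))) df[[sprintf("PC%d", k)]] <- pc1[, k]
    constant <- names(df)[-1L][vapply(df[-1L],
                                      function(v) length(unique(v)) == 1L,
                                      logical(1L))]
    if (length(constant))
        stop("rank-deficient adjustment design; offending column(s): ",
             paste(constant, collapse = ", "))
    df <- droplevels(df)
    fit <- stats::lm(trait ~ ., data = df)
    beta <- stats::coef(fit)
    if (anyNA(beta))
        stop("rank-deficient adjustment design; offending column(s): ",
             paste(names(beta)[is.na(beta)], collapse = ", "))
    y <- stats::setNames(as.numeric(stats::residuals(fit)), pheno$id)
    new("AdjustedPhenotype", y = y,
        rSquared = summary(fit)$r.squared,
        terms = colnames(stats::model.matrix(fit)))
}
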