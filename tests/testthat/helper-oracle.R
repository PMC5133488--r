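# Independent brute-force oracle for the SPA statistics: plain double loops
# over variants and clusters, no shared code with the package internals.

oracleI1 <- function(y, carrierList, weights = lengths(carrierList)) {
    ybar <- mean(y)
    tot <- 0
    for (i in seq_along(carrierList)) {
        cs <- carrierList[[i]]
        if (length(cs) == 0L) next
        tot <- tot + weights[i]^2 * (mean(y[cs]) - ybar)^2
    }
    tot
}

oracleIA <- function(y, carrierList, labels, gRare = NULL,
                     mode = c("carrier", "allele")) {
    mode <- match.arg(mode)
    ybar <- mean(y)
    tot <- 0
    for (j in sort(unique(labels))) {
        inJ <- which(labels == j)
        for (i in seq_along(carrierList)) {
            cs <- intersect(carrierList[[i]], inJ)
            if (length(cs) == 0L) next
            w <- if (mode == "carrier") length(cs) else sum(gRare[cs, i])
            tot <- tot + w^2 * (mean(y[cs]) - ybar)^2
        }
    }
    tot
}

# Random small instance: dosage matrix, labels, phenotype.
randomSpaInstance <- function(nMax = 50L, kMax = 10L, jMax = 3L) {
    n <- sample(5:nMax, 1L)
    K <- sample(1:kMax, 1L)
    J <- sample(1:jMax, 1L)
    g <- matrix(sample(c(0L, 0L, 0L, 1L, 2L), n * K, replace = TRUE), n, K)
    labels <- sample(seq_len(J), n, replace = TRUE)
    labels[seq_len(min(J, n))] <- seq_len(min(J, n))  # every cluster occupied
    list(y = rnorm(n), g = g, labels = labels)
}
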