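test_that("PC1 separates two differentiated populations with no overlap", {
    sim <- popGenotypeMatrix(nPerPop = 50L, nSnvs = 1000L, fst = 0.2,
                             seed = 21L, nPops = 2L)
    pcs <- computeGlobalPCs(sim$g, nComponents = 2L)
    s1 <- pcScores(pcs)[sim$labels == 1L, 1L]
    s2 <- pcScores(pcs)[sim$labels == 2L, 1L]
    expect_true(max(s1) < min(s2) || max(s2) < min(s1))
    expect_identical(ncol(pcScores(computeGlobalPCs(sim$g, 1L))), 1L)
})

test_that("duplicating every subject leaves per-subject PC scores unchanged", {
    sim <- popGenotypeMatrix(nPerPop = 20L, nSnvs = 300L, fst = 0.2,
                             seed = 22L, nPops = 2L)
    d <- dosageMatrix(sim$g)
    dd <- rbind(d, d)
    rownames(dd) <- c(rownames(d), paste0(rownames(d), "_dup"))
    g2 <- GenotypeMatrix(dd, chrom = snvInfo(sim$g)$chrom,
                         pos = snvInfo(sim$g)$pos)
    s1 <- pcScores(computeGlobalPCs(sim$g, 1L))[, 1L]
    s2 <- pcScores(computeGlobalPCs(g2, 1L))[, 1L]
    n <- nrow(d)
    expect_equal(unname(s2[seq_len(n)]), unname(s2[n + seq_len(n)]),
                 tolerance = 1e-8)
    expect_gt(abs(cor(s1, s2[seq_len(n)])), 1 - 1e-8)
})

test_that("PC scores are invariant (up to sign) under SNV column relabeling", {
    sim <- popGenotypeMatrix(nPerPop = 20L, nSnvs = 200L, fst = 0.2,
                             seed = 23L, nPops = 2L)
    d <- dosageMatrix(sim$g)
    set.seed(1); perm <- sample(ncol(d))
    gp <- GenotypeMatrix(d[, perm], chrom = snvInfo(sim$g)$chrom[perm],
                         pos = seq_along(perm))  # positions reassigned, sorted
    s1 <- pcScores(computeGlobalPCs(sim$g, 1L))[, 1L]
    s2 <- pcScores(computeGlobalPCs(gp, 1L))[, 1L]
    expect_gt(abs(cor(s1, s2)), 1 - 1e-10)
})

test_that("an all-monomorphic matrix is rejected", {
    d <- matrix(2L, 4L, 3L, dimnames = list(letters[1:4], c("a", "b", "c")))
    g <- GenotypeMatrix(d, chrom = rep("1", 3), pos = 1:3)
    expect_error(computeGlobalPCs(g), "monomorphic")
})

test_that("bootstrap stability is exactly 1 when every resample spans the same structure", {
    # all SNV columns are copies of one pattern, so any resample standardizes
    # to the same matrix and scores can only differ in sign
    base <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 2L)
    d <- matrix(rep(base, 40L), nrow = 8L,
                dimnames = list(sprintf("s%d", 1:8), sprintf("v%d", 1:40)))
    g <- GenotypeMatrix(d, chrom = rep("1", 40L), pos = seq_len(40L))
    st <- bootstrapPCStability(g, nSnvsPerRep = 10L, nReps = 5L,
                               nComponents = 1L, seed = 3L)
    expect_equal(st$meanAbsCor[1], 1, tolerance = 1e-12)
})

test_that("trait adjustment residualizes exactly and reports R squared", {
    set.seed(31)
    n <- 400L
    pheno <- data.frame(id = sprintf("s%d", seq_len(n)),
                        age = runif(n, 20, 80),
                        sex = sample(c("F", "M"), n, TRUE),
                        medication = sample(c("not_on", "on", "unknown"),
                                            n, TRUE))
    pc1 <- rnorm(n)
    lin <- 100 + 0.5 * pheno$age + 2 * (pheno$sex == "M") +
        5 * (pheno$medication == "on") + 3 * pc1
    # noise-free linear trait -> zero residuals, R^2 = 1 ("perfect fit"
    # warning from summary.lm is expected on this degenerate input)
    pheno$trait <- lin
    adj <- suppressWarnings(adjustPhenotype(pheno, pc1))
    expect_lt(max(abs(residualsY(adj))), 1e-8)
    expect_equal(adj@rSquared, 1, tolerance = 1e-10)

    # residuals orthogonal to every design column, mean zero
    pheno$trait <- lin + rnorm(n, 0, 8)
    adj <- adjustPhenotype(pheno, pc1)
    y <- residualsY(adj)
    X <- model.matrix(~ age + factor(sex) + factor(medication) + pc1,
                      data = pheno)
    expect_lt(max(abs(crossprod(X, y))), 1e-6)
    expect_lt(abs(mean(y)), 1e-10)

    # invariance to consistent subject reordering
    set.seed(32); ord <- sample(n)
    adj2 <- adjustPhenotype(pheno[ord, ], pc1[ord])
    expect_equal(residualsY(adj2), residualsY(adj)[ord], tolerance = 1e-10)
})

test_that("R squared is near zero for a trait independent of the design", {
    set.seed(33)
    n <- 10000L
    pheno <- data.frame(id = seq_len(n), trait = rnorm(n),
                        age = runif(n, 20, 80),
                        sex = sample(c("F", "M"), n, TRUE),
                        medication = sample(c("not_on", "on", "unknown"),
                                            n, TRUE))
    adj <- adjustPhenotype(pheno, rnorm(n))
    expect_lt(adj@rSquared, 0.01)
})

test_that("rank-deficient designs are rejected naming the column", {
    set.seed(34)
    n <- 50L
    pheno <- data.frame(id = seq_len(n), trait = rnorm(n),
                        age = rep(40, n),   # constant -> collinear
                        sex = sample(c("F", "M"), n, TRUE),
                        medication = "not_on")
    expect_error(adjustPhenotype(pheno, rnorm(n)), "age")
})
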