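test_that("Balding-Nichols frequencies have the requested differentiation", {
    cfg <- simulationConfig(nChromosomes = 1L, snvsPerChromosome = 10000L,
                            fst = 0.2, targetRareFraction = 0.5, seed = 81L)
    fr <- simulateAncestralFreqs(cfg)
    expect_true(all(fr$perAncestry >= 0 & fr$perAncestry <= 1))
    # moment estimator of F on common sites: Var(f_a) = p(1-p) F
    common <- !fr$isRare
    p <- fr$ancestral[common]
    v <- apply(fr$perAncestry[common, , drop = FALSE], 1L, var)
    expect_lt(abs(mean(v / (p * (1 - p))) - 0.2), 0.02)

    # near-zero F collapses every population to the ancestral frequency
    cfg0 <- simulationConfig(nChromosomes = 1L, snvsPerChromosome = 2000L,
                             fst = 0.001, seed = 82L)
    fr0 <- simulateAncestralFreqs(cfg0)
    expect_lt(max(abs(fr0$perAncestry - fr0$ancestral)), 0.15)
    expect_lt(mean(abs(fr0$perAncestry - fr0$ancestral)), 0.01)
})

test_that("config validation rejects infeasible parameters", {
    expect_error(simulationConfig(fst = 0), "fst")
    expect_error(simulationConfig(targetRareFraction = 1),
                 "targetRareFraction")
    expect_error(simulationConfig(missingRate = 1), "missingRate")
    expect_error(simulationConfig(admixtureAlpha = c(1, 1)), "admixtureAlpha")
    expect_error(simulationConfig(causalRegion = list(region = 1)),
                 "causalRegion")
})

test_that("unadmixed cohorts have constant per-region ancestry matching their population frequencies", {
    cfg <- simulationConfig(nSubjects = 150L, nChromosomes = 1L,
                            snvsPerChromosome = 400L, regionSize = 200L,
                            unadmixed = TRUE, fst = 0.2, missingRate = 0,
                            targetRareFraction = 0.3, seed = 83L)
    fr <- simulateAncestralFreqs(cfg)
    sim <- simulateGenotypes(cfg, fr)
    la <- sim$truth$localAncestry
    expect_true(all(la == la[, 1L]))                  # one ancestry throughout
    expect_identical(la, sim$truth$localAncestryHap2)
    # sample allele frequency in each population tracks its generating law
    d <- dosageMatrix(sim$genotypes)
    flipped <- snvInfo(sim$genotypes)$flipped
    for (a in 1:3) {
        rows <- which(la[, 1L] == a)
        fHat <- colMeans(d[rows, , drop = FALSE]) / 2
        fTrue <- ifelse(flipped, 1 - fr$perAncestry[, a], fr$perAncestry[, a])
        expect_lt(mean(abs(fHat - fTrue)), 0.05)
    }
})

test_that("simulation is bit-reproducible and honors the missingness switch", {
    cfg <- simulationConfig(nSubjects = 60L, nChromosomes = 1L,
                            snvsPerChromosome = 300L, seed = 84L)
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(dosageMatrix(c1$genotypes), dosageMatrix(c2$genotypes))
    expect_identical(c1$pheno, c2$pheno)
    expect_identical(c1$truth$localAncestry, c2$truth$localAncestry)

    cfg0 <- simulationConfig(nSubjects = 40L, nChromosomes = 1L,
                             snvsPerChromosome = 200L, missingRate = 0,
                             seed = 85L)
    expect_false(anyNA(dosageMatrix(simulateCohort(cfg0)$genotypes)))
})

test_that("regions carry roughly the configured fraction of rare variants", {
    co <- fixtureCohort()   # target_rare_fraction 0.8, 4 regions of 500
    g <- imputeMissing(co$genotypes, 2L)
    r <- partitionRegions(g, 500L, 0.05)
    mc <- S4Vectors::mcols(r)
    expect_lt(abs(mean(mc$n_rare / mc$n_snvs) - 0.8), 0.05)
})

test_that("covariates plus global ancestry explain about a quarter of trait variance at scale", {
    cfg <- simulationConfig(nSubjects = 2000L, nChromosomes = 1L,
                            snvsPerChromosome = 800L, regionSize = 400L,
                            missingRate = 0, seed = 86L)
    co <- simulateCohort(cfg)
    pcs <- computeGlobalPCs(co$genotypes, 1L)
    adj <- adjustPhenotype(co$pheno, pcScores(pcs))
    expect_gt(adj@rSquared, 0.18)
    expect_lt(adj@rSquared, 0.33)
})

test_that("planted ancestry-specific effects land on real carriers of the named region", {
    cfg <- simulationConfig(nSubjects = 100L, nChromosomes = 1L,
                            snvsPerChromosome = 400L, regionSize = 200L,
                            missingRate = 0,
                            causalRegion = list(region = 2L,
                                                effects = c(5, -5, 0),
                                                nCausal = 5L),
                            seed = 87L)
    co <- simulateCohort(cfg)
    expect_length(co$truth$causalVariants, 5L)
    expect_true(all(co$truth$regionIndex[co$truth$causalVariants] == 2L))
    # non-carriers of all causal variants received zero genetic effect
    d <- dosageMatrix(co$genotypes)
    carrierAny <- rowSums(d[, co$truth$causalVariants, drop = FALSE] >= 1L) > 0L
    expect_true(all(co$truth$geneticEffect[!carrierAny] == 0))
    expect_true(any(co$truth$geneticEffect != 0))

    cfgBad <- simulationConfig(causalRegion = list(region = 99L,
                                                   effects = c(1, 1, 1),
                                                   nCausal = 2L), seed = 1L)
    fr <- simulateAncestralFreqs(cfgBad)
    sim <- simulateGenotypes(cfgBad, fr)
    expect_error(simulatePhenotype(cfgBad, sim$genotypes, sim$truth),
                 "out of range")
})
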