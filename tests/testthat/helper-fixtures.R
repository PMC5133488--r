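# Fixture builders, generated in code at test time.

# Discrete-population Balding-Nichols genotypes, written independently of the
# package simulator so cluster/PC recovery checks have an outside reference.
makePopGenotypes <- function(nPerPop, nSnvs, fst, seed, nPops = 3L) {
    set.seed(seed)
    p <- runif(nSnvs, 0.1, 0.5)
    sh <- (1 - fst) / fst
    f <- vapply(seq_len(nPops),
                function(a) rbeta(nSnvs, p * sh, (1 - p) * sh),
                numeric(nSnvs))
    labels <- rep(seq_len(nPops), each = nPerPop)
    mat <- t(vapply(labels, function(a) rbinom(nSnvs, 2L, f[, a]),
                    integer(nSnvs)))
    rownames(mat) <- sprintf("P%d_%02d", labels, sequence(rep(nPerPop, nPops)))
    colnames(mat) <- sprintf("m%04d", seq_len(nSnvs))
    list(mat = mat, labels = labels)
}

popGenotypeMatrix <- function(nPerPop, nSnvs, fst, seed, nPops = 3L) {
    sim <- makePopGenotypes(nPerPop, nSnvs, fst, seed, nPops)
    list(g = GenotypeMatrix(sim$mat, chrom = rep("1", nSnvs),
                            pos = seq_len(nSnvs) * 100L),
         labels = sim$labels)
}

tinyGenotypes <- function() {
    d <- matrix(c(0L, 1L, 2L, 0L, 1L,
                  0L, 0L, 1L, 2L, 0L,
                  1L, 1L, 0L, 0L, 0L,
                  0L, 0L, 0L, 0L, 0L), nrow = 5L,
                dimnames = list(sprintf("s%d", 1:5), sprintf("v%d", 1:4)))
    GenotypeMatrix(d, chrom = c("1", "1", "2", "2"),
                   pos = c(100L, 200L, 50L, 60L))
}

writeTinyVcf <- function(path) {
    rows <- c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=1>",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", "A", "B", "C"), collapse = "\t"),
        paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
                "0/0", "0/1", "1/1"), collapse = "\t"),
        paste(c("1", "200", "v2", "C", "T", ".", "PASS", ".", "GT",
                "1/1", "1/1", "0/1"), collapse = "\t"),
        paste(c("1", "300", "v3", "G", "A", ".", "PASS", ".", "GT",
                "./.", "0/1", "0/0"), collapse = "\t"))
    writeLines(rows, path)
    path
}

writeTinyMatrix <- function(prefix) {
    # same cohort as writeTinyVcf, allele "1" = the VCF ALT
    gt <- data.frame(id = c("A", "B", "C"),
                     v1 = c(0L, 1L, 2L),
                     v2 = c(2L, 2L, 1L),
                     v3 = c(NA, 1L, 0L))
    meta <- data.frame(snv = c("v1", "v2", "v3"), chrom = "1",
                       pos = c(100L, 200L, 300L))
    gp <- paste0(prefix, "_g.tsv"); mp <- paste0(prefix, "_m.tsv")
    write.table(gt, gp, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    c(genotypes = gp, meta = mp)
}

# Session-cached simulated cohort standing in for a checked-in fixture
# dataset (200 subjects x 2000 SNVs, 4 regions of 500).
.fixtureEnv <- new.env(parent = emptyenv())
fixtureCohort <- function() {
    if (is.null(.fixtureEnv$cohort)) {
        cfg <- simulationConfig(nSubjects = 200L, nChromosomes = 2L,
                                snvsPerChromosome = 1000L, regionSize = 500L,
                                missingRate = 0.005, seed = 99L)
        .fixtureEnv$cohort <- simulateCohort(cfg)
    }
    .fixtureEnv$cohort
}

fixtureCohortFiles <- function() {
    if (is.null(.fixtureEnv$paths)) {
        prefix <- file.path(tempdir(), "laspa_fixture")
        .fixtureEnv$paths <- writeCohort(fixtureCohort(), prefix)
    }
    .fixtureEnv$paths
}
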