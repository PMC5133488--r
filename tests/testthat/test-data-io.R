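test_that("VCF parsing produces minor-allele dosages with the stated tie and missing rules", {
    vcf <- writeTinyVcf(tempfile(fileext = ".vcf"))
    g <- readGenotypes(vcf, "vcf")
    d <- dosageMatrix(g)
    expect_identical(subjectIds(g), c("A", "B", "C"))
    # v1: ALT frequency exactly 0.5 -> tie broken towards ALT, no flip
    expect_identical(unname(d[, "v1"]), c(0L, 1L, 2L))
    # v2: ALT frequency 5/6 -> flipped so dosage counts the minor allele
    expect_identical(unname(d[, "v2"]), c(0L, 0L, 1L))
    expect_true(snvInfo(g)$flipped[2])
    # v3: exactly one ./. becomes exactly one missing marker
    expect_identical(sum(is.na(d)), 1L)
    expect_true(is.na(d["A", "v3"]))
})

test_that("matrix and VCF input of the same cohort give identical dosages", {
    vcf <- writeTinyVcf(tempfile(fileext = ".vcf"))
    paths <- writeTinyMatrix(tempfile())
    g1 <- readGenotypes(vcf, "vcf")
    g2 <- readGenotypes(paths["genotypes"], "matrix_tsv",
                        metaPath = paths["meta"])
    expect_identical(dosageMatrix(g1), dosageMatrix(g2))
    expect_identical(snvInfo(g1)$pos, snvInfo(g2)$pos)
})

test_that("multi-allelic records and malformed genotypes are rejected", {
    path <- tempfile(fileext = ".vcf")
    rows <- readLines(writeTinyVcf(tempfile(fileext = ".vcf")))
    rows[5] <- sub("\tG\t", "\tG,T\t", rows[5])
    writeLines(rows, path)
    expect_error(readGenotypes(path, "vcf"), "multi-allelic")
    rows <- readLines(writeTinyVcf(tempfile(fileext = ".vcf")))
    rows[5] <- sub("0/1", "0/2", rows[5])
    writeLines(rows, path)
    expect_error(readGenotypes(path, "vcf"), "unsupported GT")
})

test_that("monomorphic SNVs are retained with MAF 0", {
    g <- tinyGenotypes()  # v4 is all zero
    expect_identical(nSnvs(g), 4L)
    expect_identical(unname(computeMAF(g)["v4"]), 0)
})

test_that("phenotype reading validates, aligns by id, and errors name the ids", {
    path <- tempfile(fileext = ".tsv")
    tab <- data.frame(id = c("s3", "s1", "s2", "s4", "s5"),
                      trait = c(130, 120, 125, 118, 140), age = 40:44,
                      sex = c("F", "M", "F", "M", "F"),
                      medication = c("on", "not_on", "unknown", "on",
                                     "not_on"))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    g <- tinyGenotypes()
    ph <- readPhenotypes(path, genotypes = g)
    expect_identical(ph$id, subjectIds(g))
    expect_equal(ph$trait[1], 120)  # s1's trait after reordering

    # comma-delimited works too
    pcsv <- tempfile(fileext = ".csv")
    write.csv(tab, pcsv, row.names = FALSE, quote = FALSE)
    expect_equal(readPhenotypes(pcsv)$trait, tab$trait)

    # subject in genotypes but not phenotypes -> error naming it
    write.table(tab[tab$id != "s3", ], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    expect_error(readPhenotypes(path, genotypes = g), "s3")

    # 4-level medication violates the invariant
    tab$medication <- c("on", "not_on", "unknown", "other", "not_on")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readPhenotypes(path), "medication")
})

test_that("imputation fills only missing entries, deterministically, from the observed multiset", {
    g <- tinyGenotypes()
    expect_identical(imputeMissing(g, 1L), g)   # identity on complete data

    d <- dosageMatrix(g)
    d["s2", "v1"] <- NA
    d["s4", "v4"] <- NA
    gm <- GenotypeMatrix(d, chrom = snvInfo(g)$chrom, pos = snvInfo(g)$pos)
    out1 <- imputeMissing(gm, 7L)
    out2 <- imputeMissing(gm, 7L)
    expect_identical(dosageMatrix(out1), dosageMatrix(out2))  # seed-stable
    keep <- !is.na(d)
    expect_identical(dosageMatrix(out1)[keep], d[keep])       # observed kept
    # v4 observed values are all 0 -> the imputed value can only be 0
    expect_identical(dosageMatrix(out1)["s4", "v4"], 0L)
})

test_that("imputed draws follow the observed genotype frequencies", {
    n <- 10002L
    d <- matrix(NA_integer_, n, 1L,
                dimnames = list(sprintf("s%d", seq_len(n)), "v1"))
    d[1L, 1L] <- 0L
    d[2L, 1L] <- 2L
    g <- GenotypeMatrix(d, chrom = "1", pos = 1L)
    out <- dosageMatrix(imputeMissing(g, 11L))
    frac2 <- mean(out[-(1:2), 1L] == 2L)
    expect_lt(abs(frac2 - 0.5), 3 * sqrt(0.25 / 10000))  # 3 SE binomial band
})

test_that("a SNV with no observed genotypes cannot be imputed", {
    d <- matrix(c(0L, 1L, NA, NA), 2L, 2L,
                dimnames = list(c("a", "b"), c("v1", "v2")))
    g <- GenotypeMatrix(d, chrom = c("1", "1"), pos = c(1L, 2L))
    expect_error(imputeMissing(g, 1L), "v2")
})

test_that("result tables round-trip through the TSV writer", {
    res <- data.frame(chrom = c("1", "2"), pos_first = c(100L, 50L),
                      pos_last = c(200L, 60L), n_rare = c(3L, 1L),
                      global_p_IA = c(0.0123, 0.5), local_p_IA = c(0.02, 0.7),
                      p_I1 = c(0.11, 0.9), I1 = c(5.5, 1.1),
                      IA = c(6.6, 1.2), flags = c("", ""))
    path <- tempfile(fileext = ".tsv")
    writeResults(res, path)
    back <- read.delim(path)
    expect_equal(nrow(back), 2L)
    expect_equal(back$global_p_IA, res$global_p_IA)
    expect_equal(back$pos_first, res$pos_first)
    expect_error(writeResults(res[0, ], tempfile()), "non-empty")
})
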