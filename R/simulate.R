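# Admixed-cohort simulator. Emulates the structure the scan targets: a
# three-way admixed population (European / African / Native American-like)
# with Balding-Nichols differentiated allele frequencies, local ancestry
# assigned per region block (two haplotypes per subject per region), ~80%
# rare SNVs per region, trait covariates (age, sex, 3-level medication
# status), a global-ancestry trait effect, and an optional planted
# ancestry-specific rare-variant effect for power studies.

#' Simulation configuration
#'
#' Defaults describe a small but realistic admixed cohort: three ancestral
#' populations at pairwise differentiation \code{fst = 0.15} (continental
#' scale), Dirichlet(5, 4, 1) admixture proportions (on average ~50/40/10,
#' the rough European / Native American / African makeup of a Mexican
#' American sample), 80% rare SNVs at MAF cutoff 0.05, blood-pressure-like
#' trait units (intercept 120 mmHg, noise SD 12), and 0.5% missing genotypes.
#'
#' @param nSubjects cohort size.
#' @param nChromosomes,snvsPerChromosome genome dimensions.
#' @param nAncestries number of ancestral populations.
#' @param fst Balding-Nichols differentiation, in (0, 1).
#' @param admixtureAlpha Dirichlet concentration per ancestry.
#' @param unadmixed when \code{TRUE} each subject belongs wholly to one
#'   ancestry drawn uniformly (no admixture); used for clean cluster-recovery
#'   checks.
#' @param regionSize SNVs per local-ancestry block (matches the scan window).
#' @param targetRareFraction fraction of SNVs drawn from the rare-frequency
#'   law, strictly inside (0, 1).
#' @param mafCutoff rare/common threshold used by the rare-frequency law.
#' @param betaAge,betaSex,betaMedOn,betaMedUnknown covariate effects on the
#'   trait (mmHg per unit).
#' @param globalAncestryEffect trait effect of the first ancestry's global
#'   proportion (mmHg going from 0 to 1).
#' @param causalRegion optional list(\code{region} = region index,
#'   \code{effects} = per-ancestry carrier effect vector, \code{nCausal} =
#'   number of causal rare variants) planting an ancestry-specific
#'   rare-variant effect.
#' @param noiseSd residual trait SD.
#' @param missingRate genotype missingness rate in [0, 1).
#' @param intercept trait intercept.
#' @param medProbs probabilities of medication levels (not_on, on, unknown).
#' @param seed master simulation seed.
#' @return validated list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(nSubjects = 200L, nChromosomes = 2L,
                             snvsPerChromosome = 1000L, nAncestries = 3L,
                             fst = 0.15, admixtureAlpha = c(5, 4, 1),
                             unadmixed = FALSE, regionSize = 500L,
                             targetRareFraction = 0.8, mafCutoff = 0.05,
                             betaAge = 0.3, betaSex = 3, betaMedOn = 10,
                             betaMedUnknown = 5, globalAncestryEffect = 8,
                             causalRegion = NULL, noiseSd = 12,
                             missingRate = 0.005, intercept = 120,
                             medProbs = c(0.6, 0.3, 0.1), seed = 1L) {
    cfg <- as.list(environment())
    cfg$nSubjects <- as.integer(nSubjects)
    cfg$nChromosomes <- as.integer(nChromosomes)
    cfg$snvsPerChromosome <- as.integer(snvsPerChromosome)
    cfg$nAncestries <- as.integer(nAncestries)
    cfg$regionSize <- as.integer(regionSize)
    cfg$seed <- as.integer(seed)
    if (!(fst > 0 && fst < 1)) stop("fst must lie in (0, 1)")
    if (!(targetRareFraction > 0 && targetRareFraction < 1))
        stop("targetRareFraction must lie strictly in (0, 1)")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    if (length(cfg$admixtureAlpha) != cfg$nAncestries ||
        any(cfg$admixtureAlpha <= 0))
        stop("admixtureAlpha must be ", cfg$nAncestries,
             " positive concentrations")
    if (abs(sum(medProbs) - 1) > 1e-8 || any(medProbs < 0))
        stop("medProbs must be 3 non-negative probabilities summing to 1")
    if (!is.null(causalRegion)) {
        need <- c("region", "effects", "nCausal")
        if (!all(need %in% names(causalRegion)))
            stop("causalRegion needs fields: ", paste(need, collapse = ", "))
        if (length(causalRegion$effects) != cfg$nAncestries)
            stop("causalRegion$effects needs one effect per ancestry")
    }
    class(cfg) <- "simulationConfig"
    cfg
}

#' Draw ancestral and per-ancestry allele frequencies
#'
#' Each SNV gets an ancestral frequency — Uniform(mafCutoff, 0.5) for common
#' sites, Beta(0.5, 50) truncated to (0, mafCutoff) for rare sites (the
#' fraction of rare sites is \code{targetRareFraction}) — and then one
#' frequency per ancestral population from the Balding-Nichols law
#' Beta(p(1-F)/F, (1-p)(1-F)/F).
#'
#' @param config a [simulationConfig()].
#' @param seed seed (defaults to the config's).
#' @return list with \code{ancestral} (length-m vector), \code{perAncestry}
#'   (m x A matrix) and \code{isRare} (logical, the generating law per SNV).
#' @export
simulateAncestralFreqs <- function(config, seed = config$seed) {
    stopifnot(inherits(config, "simulationConfig"))
    m <- config$nChromosomes * config$snvsPerChromosome
    A <- config$nAncestries
    F <- config$fst
    withSeed(deriveSeed(seed, 11L), {
        isRare <- stats::runif(m) < config$targetRareFraction
        p <- numeric(m)
        p[!isRare] <- stats::runif(sum(!isRare), config$mafCutoff, 0.5)
        nr <- sum(isRare)
        if (nr) {
            draws <- numeric(nr)
            left <- seq_len(nr)
            while (length(left)) {          # truncation by rejection
                cand <- stats::rbeta(length(left), 0.5, 50)
                ok <- cand > 0 & cand < config$mafCutoff
                draws[left[ok]] <- cand[ok]
                left <- left[!ok]
            }
            p[isRare] <- draws
        }
        shape <- (1 - F) / F
        perAnc <- matrix(stats::rbeta(m * A, rep(p * shape, A),
                                      rep((1 - p) * shape, A)), m, A)
        list(ancestral = p, perAncestry = perAnc, isRare = isRare)
    })
}

# One multinomial draw per row of a probability matrix.
.sampleAncestry <- function(Q) {
    u <- stats::runif(nrow(Q))
    cum <- t(apply(Q, 1L, cumsum))
    as.integer(rowSums(u > cum) + 1L)
}

#' Simulate genotypes with block-wise local ancestry
#'
#' Per subject: global ancestry proportions from a Dirichlet (or a single
#' ancestry when \code{unadmixed}); per region block, two independent
#' haplotype-ancestry draws from those proportions; each SNV's genotype is
#' the sum of two Bernoulli draws at the respective ancestry's frequency.
#' Dosages are then oriented to the minor allele and a missingness mask is
#' applied. The truth's per-region label is the first haplotype's draw.
#'
#' @param config a [simulationConfig()].
#' @param freqs from [simulateAncestralFreqs()].
#' @param seed seed (defaults to the config's).
#' @return list(\code{genotypes} = \linkS4class{GenotypeMatrix},
#'   \code{truth} = list(localAncestry n x regions [haplotype 1],
#'   localAncestryHap2, globalProportions n x A, regionIndex per SNV)).
#' @export
simulateGenotypes <- function(config, freqs, seed = config$seed) {
    stopifnot(inherits(config, "simulationConfig"))
    n <- config$nSubjects
    A <- config$nAncestries
    m <- config$nChromosomes * config$snvsPerChromosome
    withSeed(deriveSeed(seed, 22L), {
        Q <- if (isTRUE(config$unadmixed)) {
            anc <- sample.int(A, n, replace = TRUE)
            diag(A)[anc, , drop = FALSE]
        } else {
            gm <- matrix(stats::rgamma(n * A,
                                       shape = rep(config$admixtureAlpha,
                                                   each = n)), n, A)
            gm / rowSums(gm)
        }
        # region blocks per chromosome, same chunking as the scan
        perChrom <- split(seq_len(m),
                          rep(seq_len(config$nChromosomes),
                              each = config$snvsPerChromosome))
        blocks <- list()
        for (idx in perChrom) {
            starts <- seq.int(1L, length(idx), by = config$regionSize)
            for (s in starts)
                blocks[[length(blocks) + 1L]] <-
                    idx[s:min(s + config$regionSize - 1L, length(idx))]
        }
        nB <- length(blocks)
        hap1 <- hap2 <- matrix(0L, n, nB)
        G <- matrix(0L, n, m)
        regionIndex <- integer(m)
        for (b in seq_len(nB)) {
            snvs <- blocks[[b]]
            regionIndex[snvs] <- b
            a1 <- .sampleAncestry(Q)
            a2 <- .sampleAncestry(Q)
            hap1[, b] <- a1
            hap2[, b] <- a2
            W <- length(snvs)
            for (hap in list(a1, a2)) {
                for (a in seq_len(A)) {
                    rows <- which(hap == a)
                    if (!length(rows)) next
                    f <- freqs$perAncestry[snvs, a]
                    G[rows, snvs] <- G[rows, snvs] +
                        matrix(stats::rbinom(length(rows) * W, 1L,
                                             rep(f, each = length(rows))),
                               length(rows), W)
                }
            }
        }
        if (config$missingRate > 0) {
            mask <- stats::runif(n * m) < config$missingRate
            G[mask] <- NA_integer_
        }
        dimnames(G) <- list(sprintf("S%04d", seq_len(n)),
                            sprintf("snv%05d", seq_len(m)))
        g <- GenotypeMatrix(
            G,
            chrom = as.character(rep(seq_len(config$nChromosomes),
                                     each = config$snvsPerChromosome)),
            pos = rep(seq_len(config$snvsPerChromosome) * 1000L,
                      config$nChromosomes))
        g <- .orientMinor(g)
        list(genotypes = g,
             truth = list(localAncestry = hap1, localAncestryHap2 = hap2,
                          globalProportions = Q, regionIndex = regionIndex))
    })
}

#' Simulate the phenotype/covariate table
#'
#' trait = intercept + betaAge age + betaSex male + medication effects +
#' globalAncestryEffect q1 + planted carrier effects + Normal(0, noiseSd).
#' Covariates: age ~ Uniform(20, 80), sex ~ Bernoulli(0.5), medication a
#' 3-level categorical. When \code{causalRegion} is set, each causal rare
#' variant adds its ancestry-specific effect to carriers, the effect chosen by
#' the subject's true local ancestry (haplotype 1) at that region.
#'
#' @param config a [simulationConfig()].
#' @param g the simulated \linkS4class{GenotypeMatrix}.
#' @param truth truth list from [simulateGenotypes()].
#' @param seed seed (defaults to the config's).
#' @return list(\code{pheno} = data.frame(id, trait, age, sex, medication),
#'   \code{causalVariants} = integer SNV indices (empty when no planted
#'   effect), \code{geneticEffect} = per-subject planted contribution).
#' @export
simulatePhenotype <- function(config, g, truth, seed = config$seed) {
    stopifnot(inherits(config, "simulationConfig"))
    n <- nSubjects(g)
    d <- SummarizedExperiment::assay(g, "dosage")
    withSeed(deriveSeed(seed, 33L), {
        age <- stats::runif(n, 20, 80)
        sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
        medication <- sample(c("not_on", "on", "unknown"), n, replace = TRUE,
                             prob = config$medProbs)
        geneticEffect <- numeric(n)
        causalVariants <- integer(0L)
        if (!is.null(config$causalRegion)) {
            cr <- config$causalRegion
            nRegions <- ncol(truth$localAncestry)
            if (cr$region < 1L || cr$region > nRegions)
                stop("causalRegion$region out of range (1..", nRegions, ")")
            snvs <- which(truth$regionIndex == cr$region)
            f <- rowMeans(d[snvs, , drop = FALSE], na.rm = TRUE) / 2
            maf <- pmin(f, 1 - f)
            eligible <- snvs[maf > 0 & maf < config$mafCutoff]
            if (length(eligible) < cr$nCausal)
                stop("causal region has only ", length(eligible),
                     " polymorphic rare variants; ", cr$nCausal, " requested")
            causalVariants <- sort(sample(eligible, cr$nCausal))
            anc <- truth$localAncestry[, cr$region]
            for (i in causalVariants) {
                carrier <- !is.na(d[i, ]) & d[i, ] >= 1L
                geneticEffect <- geneticEffect +
                    ifelse(carrier, cr$effects[anc], 0)
            }
        }
        trait <- config$intercept + config$betaAge * age +
            config$betaSex * (sex == "M") +
            config$betaMedOn * (medication == "on") +
            config$betaMedUnknown * (medication == "unknown") +
            config$globalAncestryEffect * truth$globalProportions[, 1L] +
            geneticEffect + stats::rnorm(n, 0, config$noiseSd)
        list(pheno = data.frame(id = subjectIds(g), trait = trait, age = age,
                                sex = sex, medication = medication,
                                stringsAsFactors = FALSE),
             causalVariants = causalVariants, geneticEffect = geneticEffect)
    })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper chaining [simulateAncestralFreqs()],
#' [simulateGenotypes()] and [simulatePhenotype()]. Bit-reproducible given
#' the config seed.
#'
#' @param config a [simulationConfig()].
#' @return list(\code{genotypes}, \code{pheno}, \code{truth}, \code{config});
#'   truth additionally carries \code{causalVariants} and
#'   \code{geneticEffect}.
#' @export
simulateCohort <- function(config = simulationConfig()) {
    freqs <- simulateAncestralFreqs(config)
    sim <- simulateGenotypes(config, freqs)
    ph <- simulatePhenotype(config, sim$genotypes, sim$truth)
    truth <- sim$truth
    truth$causalVariants <- ph$causalVariants
    truth$geneticEffect <- ph$geneticEffect
    truth$freqs <- freqs
    list(genotypes = sim$genotypes, pheno = ph$pheno, truth = truth,
         config = config)
}

#' Write a simulated cohort in the package's text dialects
#'
#' Emits \code{<prefix>_genotypes.tsv} (subjects x SNVs dosage matrix),
#' \code{<prefix>_snvs.tsv} (snv/chrom/pos metadata),
#' \code{<prefix>_phenotypes.tsv} and \code{<prefix>_truth.tsv} (per-subject
#' global proportions and per-region haplotype-1 local ancestry).
#'
#' @param cohort from [simulateCohort()].
#' @param prefix output path prefix.
#' @return named character vector of the four paths, invisibly.
#' @export
writeCohort <- function(cohort, prefix) {
    g <- cohort$genotypes
    d <- dosageMatrix(g)
    paths <- c(genotypes = paste0(prefix, "_genotypes.tsv"),
               snvs = paste0(prefix, "_snvs.tsv"),
               phenotypes = paste0(prefix, "_phenotypes.tsv"),
               truth = paste0(prefix, "_truth.tsv"))
    gt <- data.frame(id = rownames(d), d, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(gt, paths["genotypes"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rd <- rowData(g)
    utils::write.table(
        data.frame(snv = rownames(rd), chrom = rd$chrom, pos = rd$pos),
        paths["snvs"], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$pheno, paths["phenotypes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tr <- data.frame(id = subjectIds(g),
                     round(cohort$truth$globalProportions, 6),
                     cohort$truth$localAncestry, check.names = FALSE)
    colnames(tr) <- c("id",
                      sprintf("q%d", seq_len(ncol(
                          cohort$truth$globalProportions))),
                      sprintf("region%d_anc",
                              seq_len(ncol(cohort$truth$localAncestry))))
    utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}
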