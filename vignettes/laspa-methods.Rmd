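---
title: "Region-based rare-variant scans with local ancestry: models, parameters and design choices"
author: "laspa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based rare-variant scans with local ancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laspa)
```

## The model

`laspa` scans the genome of a recently admixed cohort for regions whose rare
variants are associated with a quantitative trait, allowing the association
to differ by the ancestral origin of the region. The working assumptions are:

- the cohort descends from a small number of ancestral populations (three by
  default), and a subject's genome is a mosaic of segments each inherited on
  one ancestral background;
- genome-wide population structure is one-dimensional enough that the first
  principal component of the standardized dosage matrix captures global
  ancestry (this is verified empirically per data set, see *Bootstrap
  stability* below);
- within a window of consecutive SNVs, the common variants carry the
  ancestry signal (their frequencies differ across ancestral populations)
  while the rare variants carry the putative trait signal;
- rare-variant effects act on carriers (dominance coding: a homozygote is
  one carrier), possibly with different sign or magnitude per ancestral
  background.

Stage 1 residualizes the trait on age, sex, medication status and the global
PC1 score; the residual vector $Y$ with overall mean $\bar Y$ is the
phenotype used everywhere downstream. Stage 2 windows the genome. Stage 3
computes, for a window with $K$ rare variants and $J$ inferred local-ancestry
clusters,

$$I_1 = \sum_{i=1}^{K} n_i^2\,(\bar Y_i - \bar Y)^2, \qquad
  I_A = \sum_{j=1}^{J}\sum_{i=1}^{K} n_{i,j}^2\,(\bar Y_{i,j} - \bar Y)^2,$$

where $n_i$ counts carriers of variant $i$, $\bar Y_i$ is their mean
residual phenotype, and $n_{i,j}$, $\bar Y_{i,j}$ restrict both to carriers
in cluster $j$. Two deliberate readings are baked in and exposed:

- $n_i$ is the **carrier count**, not the allele count: the carrier mean
  $\bar Y_i$ is defined over subjects with at least one copy, and the weight
  should square the size of exactly that set. The allele-count alternative
  is available as `mode = "allele"` and is flagged experimental.
- $\bar Y$ in $I_A$ is the **overall** sample mean, not a per-cluster mean.
  Centering per cluster would remove exactly the between-ancestry mean
  differences the partitioned statistic is designed to pick up.

Zero-carrier variants contribute $0^2 \times$ (undefined mean), which is
defined as zero — they are retained but weightless, so no NaN propagates.
With $J = 1$ the outer sum collapses and $I_A \equiv I_1$ exactly (this is a
tested identity, not an approximation).

## Permutation inference

Ancestry labels are a property of the genome, so they are held fixed; only
$Y$ is permuted. Three p-values are reported per region, each from its own
independent permutation stream:

- **global p (IA)** — $Y$ permuted across all subjects. The null is that the
  phenotype is independent of both the region's rare variants and its
  ancestry composition; rejection means the region carries signal through
  rare variants, ancestry structure, or both.
- **local p (IA)** — $Y$ permuted within each ancestry cluster. Cluster-wise
  phenotype multisets are conserved, so any phenotype–ancestry association
  survives the permutation; rejection isolates within-ancestry rare-variant
  signal.
- **p (I1)** — the marginal statistic under unrestricted permutation, for
  comparison.

Phrases like "permutation within and between ancestral origins" admit more
than one scheme; the definition above — unrestricted vs within-cluster
permutation with ancestry labels always fixed — is the one this package
commits to, because it is the only reading we found self-consistent (a
scheme that permuted labels would treat ancestry as a property of the
phenotype rather than of the genome).

The estimator is the add-one Monte-Carlo p-value $(1 + b)/(B + 1)$ with $b$
the number of permuted statistics $\ge$ the observed one. It never returns
zero, is uniform on its grid under the null, and counts ties as exceedances
(conservative). Permuted statistics are evaluated through the same
vectorized code path as the observed statistic, so ties are exact, and the
degenerate case of a constant $Y$ yields $p = 1$ for all three series.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `regionSize` | 500 | SNVs | ~100 common variants per window, enough to infer local ancestry while keeping genomic resolution; 250/750 are the documented sensitivity settings |
| `mafCutoff` | 0.05 | frequency | rare/common split; a MAF exactly at the cutoff is classed common so the rare set is strictly rare |
| `nPcsGlobal` | 1 | components | PC1 carries global ancestry; higher PCs are bootstrap-unstable |
| `nPcsLocal` | 3 | components | three ancestral populations span at most a 2-simplex, 3 PCs give headroom |
| `kClusters` | 3 | clusters | one per assumed ancestral origin of a segment |
| `nRestarts` | 10 | k-means++ starts | best-of-restarts by within-cluster SS |
| `nPermutations` | 10000 | permutations | p-value granularity $10^{-4}$ |
| `scaling` | `"unit"` | — | per-SNV unit variance makes rare and common SNVs commensurate; `"patterson"` ($\sqrt{2p(1-p)}$) is the population-genetics alternative, exposed because the choice is not settled |

The PCA standardization convention is shared between the global and local
stages. Which convention the method "should" use is genuinely open; unit
scaling is the common GWAS default and is ours, with the Patterson option a
one-flag switch.

## Numerical and algorithmic choices

- **PCA** is computed exactly via the cross-product eigendecomposition on
  whichever side is smaller (subjects for the genome-wide stage, SNVs for
  per-region stages), streaming the standardized matrix in chunks so no
  standardized copy of the full genotype matrix is ever materialized.
  Monomorphic SNVs are dropped (counted on the result object). Component
  signs are fixed by making each component's largest-magnitude SNV loading
  positive, which makes scores reproducible and invariant to SNV column
  order.
- **k-means** uses k-means++ seeding (implemented here; the stock k-means
  initialization is uniform) with `nRestarts` starts. If every start yields
  an empty cluster, or the region has fewer distinct score points than `k`,
  the fit retries with `k - 1` and the region is flagged
  `cluster_fallback`. A region with fewer polymorphic common SNVs than
  `nPcsLocal` is flagged `ancestry_unassignable` and falls back to one
  cluster (where $I_A = I_1$). Cluster labels are anonymous integers: the
  statistic needs only a partition per region, and no cross-region identity
  or population naming is claimed.
- **Statistics** are evaluated through one sparse carrier-indicator
  cross-product per cluster, using the identity
  $n^2(S/n - \bar Y)^2 = (S - n\bar Y)^2$ with $S$ the carrier phenotype
  sum; all $B$ permutations of a scheme are processed as matrix columns in
  memory-bounded blocks.
- **Seeds**: a single master seed deterministically derives one stream per
  (region, permutation scheme) via a 32-bit multiplicative hash, so results
  are bit-identical across runs and independent of region processing order.
- **Missing genotypes** are imputed per SNV by uniform draws from the SNV's
  observed dosage multiset (so imputation follows the empirical genotype
  distribution and cannot mistake missing for reference); the missing marker
  is `NA`, never 0. A SNV with no observed genotypes is an error.
- **Minor-allele orientation** is fixed once at load time from the full
  sample (frequency $\le 0.5$, tie broken towards the coded/ALT allele), so
  carrier definitions are stable across all stages.
- **Degenerate regions**: $K = 0$ (no rare variants) yields NA statistics
  and p-values with flag `no_rare_variants`; trailing partial windows are
  retained and flagged `partial` with their size reported, so downstream
  filtering is possible.

## What the simulator emulates — and what it does not

`simulateCohort()` generates: Balding–Nichols per-ancestry allele
frequencies around ancestral frequencies (common sites Uniform(0.05, 0.5);
rare sites Beta(0.5, 50) truncated below the MAF cutoff, a law chosen to
yield roughly the 80 % rare fraction per window typical of sequencing
panels); Dirichlet(5, 4, 1) global admixture proportions (on average about
50/40/10, a rough three-way admixed-cohort profile); per-region diploid
local ancestry drawn from each subject's proportions; covariates
(age ~ U(20, 80), sex ~ Bernoulli(0.5), 3-level medication) with
blood-pressure-like effect sizes (intercept 120 mmHg, noise SD 12); an
optional global-ancestry trait effect; and an optional planted
ancestry-specific carrier effect at named rare variants of one region. With
the defaults, covariates plus global ancestry explain about a quarter of the
trait variance at $n = 2000$ — a realistic adjustment share — and this is
checked by a test rather than asserted.

Deliberate simplifications:

- local ancestry is assigned **per region block**, matching the analysis
  window, rather than via recombination-length tracts. This makes the
  method's assumptions literally true in simulation — which is exactly what
  method-level tests need — but means passing tests do not demonstrate
  robustness to ancestry switches *within* a window;
- no linkage disequilibrium beyond what ancestry differences induce;
- no kinship (the target design is an unrelated sample);
- truth labels for scoring cluster recovery reduce diploid ancestry to the
  first haplotype's draw; with admixture, heterozygous-ancestry regions make
  the achievable ARI less than 1 by construction (cluster-recovery tests
  therefore use unadmixed cohorts).

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen as the
smallest sizes at which the checked quantities are stable: statistic/oracle
agreement on 1000 random instances ($n \le 50$, $K \le 10$, $J \le 3$);
null calibration on 500 regions × 500 SNVs, 500 subjects, $B = 999$ (script:
200 regions, 400 subjects, $B = 499$); the power study at $n = 400$ with an
opposite-sign ±13 mmHg carrier effect on 12 causal rare variants of one
region among six, pre-tuned by pilot simulation to put the partitioned
statistic's power near 0.8; cluster recovery at $F_{ST}$ 0.05/0.15/0.3 with
100 common SNVs; bootstrap stability with 100 replicates of 1000 SNVs.
Adjusted Rand index saturates at 1 once clusters separate, so "recovery
improves with differentiation" is checked as non-decreasing with a strict
overall increase.

## Known limitations

- The local-ancestry step is PCA + k-means, not a haplotype HMM; it infers a
  partition, not named populations, and regions with weak common-variant
  differentiation will cluster noisily (the local p-value then approaches
  the global one).
- Permutation with fixed $B$ bounds the smallest achievable p-value at
  $1/(B+1)$; no adaptive early stopping is implemented.
- No multiple-testing adjustment is applied by default (raw p-values are
  reported, as is conventional for this scan's screening use);
  Bonferroni/Benjamini–Hochberg columns are available via
  `scanConfig(adjustP = TRUE)`.
- Multi-allelic sites are rejected rather than decomposed; phasing and
  genotype likelihoods are out of scope.
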