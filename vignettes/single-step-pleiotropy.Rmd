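---
title: "Single-step GWAS and multi-trait pleiotropy analysis: models and methods"
author: "PleioGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step GWAS and multi-trait pleiotropy analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the single-trait repeatability animal model solved with combined
pedigree-genomic relationships, SNP effects back-solved from genomic breeding
values, the Cholesky-based multi-trait chi-square for pleiotropy, the
segment-based multiple-testing correction, and the window-based QTL
annotation layer. It also documents the synthetic-data generator that the
test suite uses as ground truth, the numerical choices, and the limitations a
user should know about.

## The repeatability animal model

Phenotypes are repeated records on animals (e.g. mature-cow weight, height
and body condition score measured at several parities). The single-trait
model is

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Za} + \mathbf{Wpe} + \mathbf{e},$$

where $\mathbf{b}$ collects the fixed effects — contemporary group
(herd-year-season), parity, and age in days fitted as a linear covariate
nested within age-in-years class (one slope per year class) — $\mathbf{a}$
is the additive genetic effect of every pedigree animal, $\mathbf{pe}$ is a
permanent-environment effect shared by an animal's records, and $\mathbf{e}$
is residual. The variance structure is
$\mathrm{Var}(\mathbf{a}) = \mathbf{H}\sigma^2_a$,
$\mathrm{Var}(\mathbf{pe}) = \mathbf{I}\sigma^2_{pe}$,
$\mathrm{Var}(\mathbf{e}) = \mathbf{I}\sigma^2_e$. Variance components are
*inputs* (fixed to external estimates, as routine genetic evaluations do);
no REML is implemented.

`solveMme()` assembles and solves Henderson's mixed-model equations by
sparse Cholesky factorisation with
$\lambda_a = \sigma^2_e/\sigma^2_a$ and
$\lambda_{pe} = \sigma^2_e/\sigma^2_{pe}$ on the random-effect blocks.
Identifiability: the first level of each fixed factor is dropped when the
design is built, and any residual rank deficiency of $\mathbf{X}$ (detected
by pivoted Cholesky of $\mathbf{X'X}$) is resolved by constraining the
dependent columns to zero; the constrained columns are recorded in the
solution object. The solver verifies the relative residual of the solved
system against a $10^{-8}$ tolerance. Permanent-environment equations are
set up only for animals that actually have records.

## Combined relationship matrix H

The genomic information enters through the inverse of the combined
relationship matrix,

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & \mathbf{G}^{-1} - \mathbf{A}_{22}^{-1}
  \end{bmatrix},$$

with $\mathbf{A}$ the pedigree numerator relationship matrix (tabular
method, compiled code), $\mathbf{A}_{22}$ its genotyped block, and
$\mathbf{G}$ the first VanRaden genomic relationship matrix

$$\mathbf{G} = \frac{\mathbf{ZZ'}}{2\sum_i p_i(1-p_i)},$$

where $\mathbf{Z}$ holds allele counts centred by $2p_i$.
$\mathbf{A}^{-1}$ is built directly by Henderson's rules with inbreeding;
the inbreeding coefficients come from a Meuwissen-Luo style decomposition so
the dense $\mathbf{A}$ is never needed for the inverse. Allele frequencies
are the observed frequencies of the post-QC genotyped set (base-population
frequencies are unavailable in practice); they can be overridden. Missing
genotypes are mean-imputed at $2p_i$ before $\mathbf{G}$ is built.

Because a $\mathbf{G}$ built from in-sample frequencies is singular (the
centring removes the mean), it is blended as
$w\mathbf{G} + (1-w)\mathbf{A}_{22}$ with $w = 0.95$ by default — the
conventional evaluation-software setting; the weight is recorded in the
object and positive definiteness is verified. No tuning of $\mathbf{G}$'s
scale to $\mathbf{A}_{22}$ is applied by default.

## SNP effects back-solved from GEBVs

Under the infinitesimal model with equal SNP variances, the GEBVs of
genotyped animals satisfy $\mathbf{a} = \mathbf{Zu}$, and the SNP effects
are recovered as

$$\hat{\mathbf{u}} = \mathbf{Z}'(\mathbf{Z}\mathbf{I}\mathbf{Z}')^{-1}\hat{\mathbf{a}}.$$

$\mathbf{ZZ'}$ inherits the singularity noted above, so the solve uses a
trace-scaled ridge ($10^{-8}\times$ mean diagonal) whenever the reciprocal
condition number falls below $10^{-8}$; $\mathbf{Z}'$ annihilates the
offending direction, which keeps $\hat{\mathbf{u}}$ stable, and the package
emits a message when the ridge fires. One back-solving pass is performed —
no iterative SNP reweighting — matching the equal-variance assumption.

Standard errors propagate the covariance of the GEBV estimator through the
back-solving map $K = \mathbf{Z}'(\mathbf{ZZ'})^{-1}$:
$\mathrm{Var}(\hat{\mathbf{u}}) = K\,\mathrm{Var}(\hat{\mathbf{a}})\,K'$,
with $\mathrm{Var}(\hat{\mathbf{a}}) = \mathbf{G}\sigma^2_a - \mathrm{PEV}$
and the prediction-error covariance extracted from the inverse of the MME
coefficient matrix. This is the choice that makes the signed t-values
$t_i = \hat{u}_i/\mathrm{SD}(\hat{u}_i)$ approximately standard normal under
the no-QTL (infinitesimal) null, which the calibration tests verify
empirically; p-values are the two-sided normal tail
$p_i = 2(1-\Phi(|t_i|))$. The per-SNP genetic variance explained is
reported as $2p_i(1-p_i)\hat{u}_i^2/\sigma^2_a$, which is additive over SNP
sets; this is a standard approximation that ignores linkage disequilibrium
between SNPs in a set.

## Multiple testing: independent chromosomal segments

Chromosome-wise Bonferroni thresholds divide $\alpha = 0.05$ by the
effective number of independent chromosomal segments,

$$M_{e,c} = \frac{2 N_e L_c}{\ln(4 N_e L_c)},$$

with $N_e = 182$ by default and $L_c$ the chromosome's genetic length in
Morgans (1 Mb treated as 1 cM when only physical maps exist). For
$N_e = 182$ and $L = 1$ Morgan this gives $M_e \approx 55.23$ and a
chromosome-wise threshold of $\approx 9.05\times10^{-4}$. A SNP is
significant iff $p \le \alpha_c$ of its chromosome (boundary inclusive).
Both per-chromosome lengths and a genome-wide average length
(`commonLength = TRUE`) are supported; per-chromosome is the default.

## Pleiotropy: Cholesky decorrelation and the multi-trait chi-square

The multi-trait meta-analysis assumes independent inputs, so the traits are
decorrelated first. The procedure is: (1) pre-adjust every record for the
estimated fixed effects and average the adjusted records per animal
(`adjustedTraitMeans()`); (2) z-score each trait by its complete-case mean
and SD; (3) factor the complete-case covariance of the z-scores (a
correlation matrix by construction) as $LL'$ and transform each animal's
vector $g_n$ to Cholesky scores $c_n = L^{-1} g_n$. Because $L$ is lower
triangular, the $j$-th score needs only traits $1..j$: animals observing a
prefix of the trait order keep their leading scores, which reproduces the
decreasing record counts seen when the last trait is sparsely recorded. The
first score equals the z-scored first trait exactly (the covariance is
normalised so its leading diagonal element is exactly 1). The transform
order is a modelling choice (default here: score trait, then weight, then
height); scores change with the order but the chi-square below is
empirically insensitive to it on null data, which the suite checks.

Each Cholesky-transformed trait (CT) is analysed with an animal model with
the overall mean as its only fixed effect, one record per animal, using the
same single-step machinery (a genotyped-only GBLUP mode is available). The
CT variance components are not observable; the package derives each CT's
shrinkage ratio from its source trait's components on the adjusted-mean
scale, $\lambda = (\sigma^2_{pe} + \sigma^2_e/\bar{n})/\sigma^2_a$ with
$\bar{n}$ the mean records per animal, and scales so
$\sigma^2_{a,ct} + \sigma^2_{e,ct} = 1$ (CTs are unit-variance by
construction). Explicit per-CT values can be supplied instead.

The per-SNP statistic combines the signed t-values of the $k$ CTs:

$$\chi^2_i = \mathbf{t}_i' \mathbf{V}^{-1} \mathbf{t}_i,$$

where $\mathbf{V}$ is the $k\times k$ Pearson correlation matrix of the
signed t-values computed across all SNPs. Significance is the upper tail of
$\chi^2_k$, with the same chromosome-wise Bonferroni thresholds.
$\mathbf{V}$ is inverted directly; above condition number $10^8$ an
eigenvalue pseudo-inverse is used with a warning.

## Annotation and QTL enrichment

Significant SNPs receive windows of 100 kb up- and downstream (clamped at
position 1, never merged, so every SNP reports its own hits). Gene features
come from a GTF (gene-level rows, duplicate gene ids collapsed to their
union span); QTL features from an Animal-QTLdb-style GFF3 carrying a trait
term and a trait-type category. A feature hits a window iff the 1-based
inclusive intervals intersect on the same chromosome; chromosome names are
normalised by stripping a "chr" prefix and a disjoint name set is a hard
error rather than a silent zero-hit result.

Enrichment of a trait term among the window-hit QTL records is tested
against the full database background with the exact hypergeometric upper
tail (a chi-square approximation is available); records are deduplicated
before testing so the draw-without-replacement model is valid even when
windows overlap. Benjamini-Hochberg FDR is applied across terms, with
enrichment declared below FDR 0.05, and the richness factor reported as
(hits of the term) / (background records of the term). Per-chromosome
testing is available (`byChromosome = TRUE`). The exact statistic used by
annotation suites in the field is not always documented; the hypergeometric
choice is deliberate and surfaced here.

## The synthetic-data generator

Every distributional claim in the test suite is validated on data from
`simulateStudy()`, which emulates the structure of a large breed
association's data at desk scale:

* a multi-generation pedigree with non-overlapping generations and random
  mating (no selfing), with a random subset flagged genotyped;
* biallelic SNPs with allele frequencies drawn from a configurable range,
  founder linkage disequilibrium from a Gaussian AR(1) copula whose
  correlation decays exponentially with bp distance, and descent by gene
  dropping with Haldane recombination — so LD decays monotonically with
  distance and full sibs share more alleles than unrelated animals, both of
  which are property-tested;
* three genetically correlated traits under the repeatability model:
  the polygenic term is simulated by pedigree recursion (parent average plus
  Mendelian sampling scaled by parental inbreeding), so its variance equals
  the configured $\sigma^2_a$ by construction, and QTL effects (effect
  times centred genotype) are added on top — QTL signal and polygenic
  background are cleanly separable for power tests;
* repeated records per animal sharing the animal's genetic and
  permanent-environment effects, with contemporary-group, parity and nested
  age fixed effects, a records-per-sex option, and an option that drops the
  last trait's records for a fraction of animals to emulate unbalanced
  height recording.

Default trait parameters are moderate-to-high heritability size traits
(heritabilities 0.25-0.55, repeatabilities ~0.45-0.7 on the configured
variances) with genetic correlations 0.3-0.7; the default QTL architecture
mixes trait-specific and pleiotropic loci each explaining 5% of the
polygenic variance. All randomness is governed by one seed;
identical configurations reproduce bit-identical outputs.

What the generator does *not* emulate: selection and assortative mating,
overlapping generations, realistic bovine demography and LD beyond the
AR(1)+recombination structure, genotyping error, and multi-breed
stratification. Passing tests therefore demonstrate correctness of the
machinery and its calibration under a clean repeatability-model world, not
robustness to the full messiness of field data.

## Validation design and problem sizes

The acceptance layer of the test suite checks, at fixed seeds:

* **Oracle equivalence** — Henderson-rule $\mathbf{A}^{-1}$ against dense
  inversion of tabular $\mathbf{A}$ on 100 random pedigrees (up to 200
  animals); $\mathbf{H}^{-1}$ degenerate identities (no genotyped animals;
  $\mathbf{G} = \mathbf{A}_{22}$); back-solving reconstruction
  $\mathbf{Z}\hat{\mathbf{u}} = \hat{\mathbf{a}}$ on well-conditioned
  fixtures; closed-form Cholesky and hypergeometric oracles.
* **Recovery** — noise-free fixed-effect contrasts to $10^{-8}$;
  corr$(\hat a, a) > 0.45$ on five replicates of ~2,200 recorded animals
  with 2,000 SNPs at $h^2 = 0.4$.
* **Calibration** — with three independent null traits, ~500 genotyped
  animals and 2,000 SNPs on a sparse (low-LD) map, the multi-trait test's
  empirical type-I error at 0.05 stays within three binomial standard
  errors and the mean chi-square within Monte-Carlo error of 3; single
  trait significant counts stay within binomial bounds of the
  segment-based thresholds. The sparse map keeps SNPs close to independent
  so binomial error bounds apply.
* **Power ordering** — a QTL with equal effects on all three traits (5% of
  $\sigma^2_a$ each, independent polygenic backgrounds) ranks at least as
  well under the multi-trait statistic as under its best single-trait GWAS
  in at least 70% of 20 replicates. Two design choices matter here and were
  made once: the three traits have independent polygenic backgrounds, so
  that the shared signal at the test locus is attributable to the QTL
  rather than to genome-wide genetic correlation; and the "rank" of the QTL
  is the best rank within its ±250 kb LD region, applied symmetrically to
  both analyses, since with linked markers the signal may sit on a close
  proxy rather than the causal column itself. Ties (rank 1 under both
  analyses) count in favour of the ordering.

These problem sizes were chosen so the whole suite solves every stage —
including five full single-step evaluations of ~2,200-animal pedigrees —
in a few minutes on one core while keeping Monte-Carlo error small enough
for the stated bounds.

## Numerical choices, degenerate inputs, known limitations

* Ridge: $10^{-8}\times$ trace-scaled, applied to $\mathbf{ZZ'}$ only when
  its reciprocal condition number is below $10^{-8}$; logged via a message.
* Blending: $0.95\,\mathbf{G} + 0.05\,\mathbf{A}_{22}$ default; weight 1
  short-circuits (returns $\mathbf{G}$ unchanged, no PD check).
* SNPs with $\mathrm{SD}(\hat u) = 0$ get missing p-values with a warning;
  monomorphic SNPs are a hard error in $\mathbf{G}$ construction (they
  should have been removed by the MAF filter).
* QC thresholds are strict inequalities exactly as conventional
  (`call rate < 0.90`, `MAF < 0.05`, `|het difference| > 0.15`); the
  heterozygosity rule is the absolute-difference threshold alone, with an
  exact HWE p-value emitted for inspection only. The 3-SD outlier pass is
  applied once, not iterated. The full genotype chain is idempotent on
  complete data; with missingness, re-applying the chain can remove more
  items because call rates are recomputed on the filtered panel — each
  individual filter is idempotent.
* The $M_e$ formula is the Goddard/Corbin segment count; sources that use
  it rarely print it, so the form used here is stated prominently above and
  in the function documentation.
* Desk-scale only: dense operations on the genotyped block (G, PEV) are
  $O(n_g^2)$-$O(n_g^3)$; tens of thousands of genotyped animals would need
  the approximations used by production evaluation software (APY,
  iteration on data), which are out of scope, as are metafounders,
  unknown-parent groups, REML/Gibbs variance estimation, iterative
  SNP-weighted analyses, and external-database functional enrichment.
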