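---
title: "Virtual metabolomics: models, simulation design and numerical choices"
author: "virtmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual metabolomics: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtmet)
```

# Overview

`virtmet` implements a genotype-based ("virtual") metabolomics inference
chain: metabolite polygenic scores (PGS) scanned phenome-wide against
PheCode-derived case/control phenotypes in a discovery biobank, followed by
two-sample Mendelian randomization (MR) of the significant
metabolite–phenotype pairs, pleiotropy diagnostics, and replication against
an independent outcome GWAS.  Because the individual-level biobank data such
analyses run on are access-controlled, the package ships a first-class
synthetic-data module that generates all required inputs with known ground
truth.  This vignette is the package's methods account: the models, the
tunable parameters and their defaults, what the generator does and does not
emulate, the numerical choices, and known limitations.

# The synthetic three-cohort design

Real analyses of this kind use (at least) three non-overlapping cohorts: a
discovery biobank with genotypes and clinical codes, an external metabolite
GWAS supplying exposure summary statistics, and external disease GWAS for
outcome/replication statistics.  `simulateStudy()` mirrors this with four
cohorts (discovery, exposure, outcome, replication) whose individual draws
use disjoint RNG streams derived from one seed, so the two-sample contract
— no shared individuals between exposure and outcome samples — holds by
construction and is asserted in the tests.

## Genotypes

Variants are laid out in contiguous LD blocks distributed over chromosomes
1–22; blocks on the same chromosome sit 5 Mb apart (beyond any clumping
window) and variants within a block 5 kb apart.  Two haplotypes per
individual are drawn from a Gaussian copula: within a block the latent
variables follow an AR(1) correlation and are thresholded at the
frequency-specific normal quantile.  Dichotomizing a bivariate normal
attenuates correlation by roughly $(2/\pi)\arcsin\rho$ for common variants,
so the latent correlation is set to $\sin(\pi r/2)$ to make the realized
adjacent-genotype correlation approximate the configured `within_block_r`.
This gives tunable, block-diagonal LD without coalescent machinery; it does
*not* reproduce realistic recombination maps, allele-frequency spectra or
long-range LD.

Defaults (chosen once, as the package's reference scenario): 120 variants in
24 blocks, `within_block_r = 0.3`, MAF uniform on (0.05, 0.5), discovery
n = 20,000, exposure GWAS n = 6,000 (the scale of a population-based
metabolite GWAS), outcome and replication GWAS n = 20,000.

## Metabolites

Each metabolite receives `snps_per_metabolite` (default 5) causal variants
spread over distinct LD blocks — emulating the sparse, multi-locus
architectures of circulating metabolites — and is simulated as the genetic
value plus Gaussian noise, standardized to mean 0, SD 1, with the genetic
variance fraction equal to `h2_metabolite` (default 0.3).  Two effect-size
distributions are available (the literature does not fix one, so it is
configuration rather than assumption): `"equal"` (default), in which every
causal SNP explains the same share of the genetic variance with a random
sign — matching the observation that detected metabolite QTLs are a handful
of comparably strong signals — and `"gaussian"`, normal draws rescaled to
the target heritability.  The equal-variance default also makes each causal
SNP individually detectable at the instrument threshold in the exposure
GWAS, which is what gives the reference scenario its ≥ 3-SNP instruments.

## Phenotype, events and covariates

Disease liability is logistic (matching the logistic analysis models used
throughout the package, rather than a probit/threshold formulation):

$$\Pr(\text{case}) = \operatorname{logit}^{-1}\!\big(\alpha + \beta_c\,
m_i + \textstyle\sum_v \delta_v d_{iv} + 0.01\,(\text{age}_i - 51.5) +
0.15\,(\text{sex}_i - 0.5)\big)$$

where $m_i$ is the causal metabolite (default effect $\beta_c = 0.5$
log-odds per SD; the first metabolite is causal), and $\delta_v$ are
optional direct (horizontally pleiotropic) effects planted on the causal
metabolite's SNPs — balanced (random signs) or directional (one sign), with
configurable magnitude.  The intercept $\alpha$ is solved numerically
(`uniroot` on the marginal mean) so the realized prevalence matches the
configured value (default 0.1) within the stated tolerance.

Cases are emitted with exactly two PheCode event rows (the minimum
satisfying the two-instance case rule; a jitter option adds
Poisson-distributed extras), and 5% of controls receive a single
sub-threshold instance so that downstream exclusion logic is genuinely
exercised.  Covariates are age ~ Uniform(18, 85), sex ~ Bernoulli(0.5) and
ten standard-normal principal components, independent of genotype by
default; a `pc_confounding` switch ties PC1 to each individual's mean
dosage for stratification stress tests.

## Summary statistics

`simulateSummaryStats()` regenerates a fresh cohort and computes marginal
per-variant statistics: simple linear regression for metabolite traits
(closed-form, vectorized) and additive logistic regression adjusted for
age, sex and 10 PCs for the phenotype — the same per-SNP model the package
uses for real outcome scans.  p-values are two-sided normal throughout, so
reported (beta, se, p) triples are internally consistent, a record
invariant the readers enforce at 10⁻⁶.

# Discovery: PGS and PheWAS

`computePgs()` is the weighted effect-allele dosage sum
$\mathrm{PGS}_i = \sum_j w_j d_{ij}$ with $d_{ij}$ the alt dosage when the
effect allele is alt and $2 -$ alt dosage otherwise.  Missing dosages are
mean-imputed with $2\times$EAF (the PLINK convention) or the variant is
dropped, per policy; the missing-data policy deliberately lives in the PGS
engine, not the file readers.  Scores are standardized to SD 1 before
association so PheWAS effects are log-odds per SD of PGS and comparable
across metabolites (the scaling is a package choice; raw sums are available
via `standardize = FALSE`).

Case/control assembly follows the PheCode conventions: case = ≥ 2 instances
of the target code; excluded = any code in the exclusion range without
reaching case status, or age outside the observed case age window; control
= the rest.  Sets with fewer than `min_cases` (default 100) are marked
unanalyzable.  Age is taken from the covariate table (the generator has no
event dates).  The scan fits logistic regressions adjusted for age and sex
and applies Benjamini–Hochberg FDR *within each phenotype* across
metabolites (a `fdr_scope = "global"` switch exists for sensitivity
analyses).  Non-converged or separated fits are flagged and left out of the
FDR denominator rather than being assigned p = 1, which would deflate the
BH correction with artifacts.

`fitLogistic()` uses IRLS (via `glm.fit`) followed by a few Newton polish
steps to bring coefficients to ~10⁻¹⁰ of the optimum — `glm`'s
deviance-change stopping rule alone can leave third-decimal-of-SE
discrepancies against a converged reference, which matters for the oracle
equivalence checks.  Rank-deficient designs are an error; separation
(fitted probabilities within 10⁻¹⁰ of 0/1) is a flagged result.

# Instruments

Candidate SNPs are exposure-GWAS variants with $p < 5\times10^{-6}$ (the
permissive suggestive threshold, trading instrument breadth against weak
instrument risk — the multi-stage validation downstream is the offset).
Clumping is PLINK-style greedy: rank by ascending p (ties broken by
chromosome, then position), take the best remaining SNP as index, remove
every remaining candidate on the same chromosome within 1,000 kb
(inclusive) with $r^2 \ge 0.05$; $r^2$ is the squared Pearson correlation
of dosages on the supplied LD reference (in-sample by default; an external
panel or precomputed matrix can be passed instead).  The retained set is a
function of the p-order, positions and $r^2$ only — never of input row
order — and candidates missing from the LD source are either assumed
independent or dropped, per policy, with every action logged.

Harmonization aligns the outcome effect to the exposure's effect allele:
copy when orientations agree, flip sign and frequency when swapped,
complement first when the tables are on opposite strands.  Palindromic
SNPs (A/T, C/G) cannot be resolved by strand, so under the default policy
they are dropped when the minor-allele frequency in either table exceeds
0.42 (a common MR convention; above that, frequency cannot distinguish the
strands reliably) and otherwise aligned by which allele is major.  Every
copy/flip/drop lands in the instrument's provenance log, and harmonization
is involution-safe: harmonizing an already-aligned table is a no-op.

# MR estimators

All estimators operate on aligned per-SNP effects $(\hat\gamma_j,
\sigma_{Xj})$ and $(\hat\Gamma_j, \sigma_{Yj})$, with first-order Wald
ratios $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$,
$\mathrm{SE}_j = \sigma_{Yj}/|\hat\gamma_j|$, and IVW weights
$w_j = \hat\gamma_j^2/\sigma_{Yj}^2$.

**IVW.** $\hat\beta = \sum w_j\hat\beta_j / \sum w_j$ (identical to WLS of
$\hat\Gamma$ on $\hat\gamma$ through the origin), fixed-effect
$\mathrm{SE} = (\sum w_j)^{-1/2}$, Cochran's
$Q = \sum w_j(\hat\beta_j-\hat\beta)^2$ on $n-1$ df.  The random-effects
model is multiplicative overdispersion with the factor floored at 1, so the
random-effects SE can never undercut the fixed-effect SE; the corollary —
random-effects p-values are conservative, never anti-conservative — is a
tested property.  A single-SNP instrument collapses to the Wald ratio with
Q undefined (reported absent, df 0).

**MR-Egger.** SNPs are first oriented so $\hat\gamma_j \ge 0$ (the standard
convention under InSIDE), then $\hat\Gamma$ is regressed on $\hat\gamma$
with a free intercept and weights $1/\sigma_{Yj}^2$.  The slope is the
pleiotropy-corrected estimate, the intercept the average directional
pleiotropy; SEs carry $\max(1, \sqrt{Q_E/(n-2)})$ with $Q_E$ the weighted
residual sum of squares.

**Weighted median.** Order the ratios, place each at cumulative weight
minus half its own (normalized) weight, and linearly interpolate the 50%
crossing.  The SE is a parametric bootstrap (effects resampled from
normals centred on the observed values with their reported SEs; default
1,000 draws, fixed seed; `n_boot = 0` returns the point estimate alone for
simulation studies).  The same $w_j$ as IVW are used; the kernel-smoothed
variant of the method is deliberately not implemented.

p-values are two-sided normal everywhere (not t): the package targets the
large-sample GWAS regime, and mixing t and normal references across
estimators would make the FDR stages incoherent.

**Method consistency** across estimators is defined as sign agreement of
the point estimates — the literature's "consistent findings across
methods" is not quantified anywhere we could adopt, so the weakest
defensible formalization is used and recorded as a flag rather than a hard
gate.

# MR-PRESSO

The observed statistic is the leave-one-out weighted residual sum of
squares $\mathrm{RSS} = \sum_j (\hat\Gamma_j - \hat\beta_{(-j)}
\hat\gamma_j)^2/\sigma_{Yj}^2$ with $\hat\beta_{(-j)}$ the IVW estimate
excluding SNP $j$.  The null distribution is simulated:
$\Gamma^*_j \sim N(\hat\beta_{(-j)}\hat\gamma_j, \sigma_{Yj})$,
$\gamma^*_j \sim N(\hat\gamma_j, \sigma_{Xj})$, with the leave-one-out
RSS recomputed on each simulated instrument (vectorized over simulations).
Monte-Carlo p-values use $(1+k)/(1+n_{\mathrm{sim}})$ so they are never
zero.  Per-SNP outlier p-values compare each observed residual with its
simulated distribution and are Bonferroni-multiplied by the SNP count
(capped at 1) before the 0.05 outlier call — the adjustment the reference
software applies.  The distortion test compares the IVW estimate before and
after removing flagged outliers, $D = (\hat\beta_{\text{pre}} -
\hat\beta_{\text{post}})/|\hat\beta_{\text{post}}|$, against the
distortions from removing random same-size subsets of clean SNPs, two-sided
with the +1 correction.  `n_sim` defaults to 5,000 for analyses and 1,000
in simulations; at least 4 SNPs are required (leave-one-out must stay
defined), and when fewer clean SNPs than outliers remain the corrected
estimate is still reported but the distortion p is absent rather than
ill-defined.

# The pipeline and its filter ledger

`runPipeline()` chains the stages and keeps one ledger row per
metabolite–phenotype pair: PheWAS q, IVW estimate and q (BH within
phenotype), Cochran's Q p, SNP count, cross-method sign consistency,
MR-PRESSO block (run when $p_{het} < 0.05$ and the instrument allows), the
replication estimate and q, a single `stage_reached`
(`phewas_sig` → `mr_sig` → `validation_eligible` → `replicated`) and a
machine-readable `drop_reason` for everything that stops short
(`no_exposure_gwas`, `no_instrument_snps`, `harmonization_failed`,
`mr_not_significant`, `too_few_snps`, `heterogeneity`,
`replication_not_significant`, `replication_sign_discordant`,
`no_external_data`).  Validation eligibility requires an FDR-significant
IVW estimate from ≥ 3 independent SNPs with no Q-detected heterogeneity —
one- and two-SNP instruments can too easily be a single pleiotropic signal
in disguise.  Replication re-harmonizes the *same* exposure instrument
against the replication outcome table, applies BH across the replication
batch, and requires the same direction of effect as discovery.  Gates are
monotone: relaxing `fdr` or `het_p` can only grow the significant and
eligible sets (a tested property).  Failures are pair-isolated: one
unbuildable instrument never aborts the scan.

Outcome and replication summary statistics are computed lazily for the
variants that actually enter instruments when the study was simulated with
deferred stats; the full per-variant scan remains available through
`simulateSummaryStats()`.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive (VCF convention); clumping distance is
  a position difference, inclusive at exactly the window size.
* Clumping ties in p break by (chromosome, position); chromosome labels
  are compared numerically when possible.
* Monomorphic variants yield flagged summary rows (absent beta/SE/p), not
  errors; degenerate (constant) polygenic scores are an error of class
  `virtmet_degenerate_score`, which the scan converts to a flagged cell.
* A Wald ratio with $\hat\gamma_j = 0$ is an undefined-ratio error; the
  PRESSO internals avoid dividing by simulated $\gamma^*$ entirely by
  working with $w_j\hat\beta_j = \hat\gamma_j\hat\Gamma_j/\sigma_{Yj}^2$.
* All Monte-Carlo p-values are in (0, 1] by the +1 correction.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; rerunning with the same seed is bit-identical.

# What the simulations show — and what they cannot

The test suite validates the chain at stated problem sizes: oracle
equivalence of IVW/Egger against weighted-least-squares references and of
the weighted median against a brute-force cumulative-weight scan (500
random instruments, 10⁻⁸); greedy clumping against an exhaustive reference
(200 ten-SNP instances); BH against a hand-coded step-up; Cochran's Q
rejection at α = 0.05 within [0.03, 0.07] over 2,000 null instruments;
uniform null p-values for the PheWAS logistic and per-SNP GWAS engines
(1,000 fits each, Kolmogorov–Smirnov); mean bias of IVW, Egger and the
weighted median below 0.02 on a true effect of 0.25 over 1,000 valid
20-SNP instruments, with the Egger intercept centred on zero under
balanced pleiotropy; the robustness ordering |bias(WM)| < |bias(IVW)| and
the MR-PRESSO correction moving estimates toward truth in ≥ 70% of
Q-failing instruments under 30% directional pleiotropy (200 reps); planted
10σ outliers detected in ≥ 90% of 100 instruments with clean SNPs flagged
in ≤ 10%; and 50 end-to-end replicates of the reference scenario in which
the causal pair passes every gate in ≥ 80% of runs while the global-null
scenario replicates in ≤ 5%.

Two estimator-level conditions deserve emphasis because they are easy to
violate silently.  First, MR-Egger assumes the exposure effects are
measured nearly without error relative to their spread across SNPs (high
$I^2_{GX}$, the NOME approximation): when the γ dispersion shrinks toward
the measurement error, the Egger slope attenuates by roughly
$\sigma_X^2/\mathrm{var}(\gamma)$.  The simulated instruments therefore
span close to an order of magnitude in γ, as real metabolite QTLs do;
with narrow-γ instruments users should expect, and will see, Egger
attenuation.  Second, *directional* pleiotropy only biases ratio-based
estimators when SNPs are oriented consistently (e.g., to the
exposure-increasing allele, which harmonization effectively produces);
with random allele orientation the displacements $\alpha_j/\gamma_j$
cancel in expectation and the scenario degenerates to balanced pleiotropy.
The robustness simulations orient γ accordingly.

The generator emulates LD blocks, sparse architectures, case/control
phenotypes and two-sample summary statistics, but not: realistic
recombination or allele-frequency spectra, population structure beyond the
PC1 switch, imputation uncertainty, date-resolved clinical histories,
correlated metabolite panels, or sample overlap between cohorts.  Passing
tests demonstrate the *inference machinery* is correct and calibrated
under the stated generative model; they cannot certify performance on real
biobank data, where instrument validity, phenotype misclassification and
cross-cohort heterogeneity are empirical questions.

# Known limitations

* The PGS weights of the synthetic study are trained in the same cohort
  that supplies exposure summary statistics (two cohorts would be needed
  to also separate weight-training ends; the exposure/outcome two-sample
  property, which MR validity rests on, is preserved).
* No proxy-SNP lookup or external LD reference download; the LD source is
  whatever panel or matrix the caller provides.
* Multivariable MR, MR-RAPS, mode-based estimators and Steiger filtering
  are out of scope, as is construction of ICD→PheCode mappings (a prebuilt
  exclusion-range map is consumed).
* Ancestry stratification is handled by running the pipeline per stratum;
  there is no cross-ancestry meta-analysis.
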