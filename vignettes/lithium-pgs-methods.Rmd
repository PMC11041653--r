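---
title: "Methods: polygenic scoring of lithium treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scoring of lithium treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the statistics it implements:
the phenotype definition, the quality-control rules, the per-variant scan
engines, the continuous-shrinkage posterior for SNP effects, the
leave-one-group-out (LOG) cross-fitting scheme, the association models,
and the gene/pathway layer — together with the numerical choices, the
design decisions that were genuinely open, and the known limitations.
Nothing quantitative is claimed here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The phenotype: ALDA scale and response definitions

The ALDA scale rates long-term lithium response retrospectively. Subscale
A (integer 0–10) rates the observed improvement; five B items (0–2 each)
rate how confidently that improvement can be attributed to lithium
(episode count and frequency before treatment, treatment duration,
adherence, co-medication). The working total is

\[ \mathrm{total} = \max(A - \textstyle\sum_{i=1}^{5} B_i,\; 0), \]

a bounded score with a genuine point mass at 0 created by the floor.
`compute_alda_total()` implements exactly this, and `classify_response()`
calls a patient a *good* responder when the total is at least 7 —
the categorical outcome. For the continuous outcome,
`derive_continuous_outcome()` excludes records with a B total above 4 or
any missing subscale (missing B items are **not** imputed as zero;
missingness excludes). Patients with under 6 months of lithium exposure
are removed up front by `apply_inclusion()` (boundary retained).

One definitional point is genuinely ambiguous in the literature this
package follows: the continuous outcome is sometimes described as
subscale A alone and sometimes as the A-minus-B total. Both are
implemented (`definition = "total"` is the default, `"subscale_a"` the
alternative); the Tobit stage works identically for either since both are
bounded on [0, 10].

## Genotype quality control

Pre-imputation variant filters, applied to hard calls in a fixed, logged
order: call rate ≥ 95%, removal of strand-ambiguous A/T and C/G pairs,
MAF ≥ 1%, and exact Hardy–Weinberg p ≥ 1e-6. The HWE test is the exact
conditional test (total probability of heterozygote counts no more
probable than the observed one, given allele counts) rather than the
chi-square approximation, because the 1e-6 threshold operates in the far
tail where the approximation is unreliable; the suite pins it to a
brute-force enumeration oracle at 1e-12 for all tables up to n = 200.

Sample filters: call rate ≥ 95%; a recorded-versus-genetic sex check; and
relatedness pruning on a kinship matrix estimated as
\(XX^\top / (2M)\) from mean-imputed, standardized dosages. The kinship
cut-off defaults to 0.125 (third-degree relatives) and is configurable —
the appropriate metric and cut-off are conventions, not part of the
phenotype. Of each flagged pair the member with the lower call rate is
dropped (ties: the lexicographically later id). With autosome-only
simulated data there is no X chromosome to derive sex from, so the check
compares against a simulator-provided `genetic_sex` column; with array
data this column would be replaced by an X-heterozygosity call. This is a
documented stub, not a general implementation.

Post-imputation filters keep variants with MAF ≥ 10% and imputation info
R² ≥ 0.6 (both boundaries inclusive). Cross-cohort merging intersects on
(chromosome, position, unordered allele pair), drops position matches
with conflicting allele pairs, and harmonizes the effect-allele
orientation to the first cohort by flipping dosages d → 2 − d.

## Scan engines

Per-variant association uses OLS with t tests for the continuous outcome
and an IRLS maximum-likelihood logistic fit for the categorical one, each
adjusted for age, sex, chip indicators and the first four genotype PCs.
The logistic contract is explicit: convergence when the largest score
component falls below 1e-8, at most 25 iterations, Wald z tests, and a
separation flag (missing p, no fabricated numbers) when any coefficient
passes |15|. Missing dosages are mean-imputed per variant at fit time
only and never written back. PCs come from an LD-pruned (greedy trailing
window, r² ≤ 0.2), standardized dosage matrix; components are scaled to
unit variance with signs fixed by the largest-magnitude loading. PCs are
computed once on the full cohort and reused inside cross-fitting folds:
they are functions of genotype only, so reusing them leaks no outcome
information into the discovery scans.

## Posterior SNP effects under continuous shrinkage

The discovery scan is summarised per variant by the standardized marginal
estimate \(\hat\beta_j = z_j / \sqrt{N}\). With a block-diagonal LD
reference \(R\) (Pearson correlations of standardized reference dosages;
eigenvalue floor 1e-3 imposed by a ridge shift plus diagonal
renormalization), the sampling model per block is
\(\hat\beta \sim \mathcal N(R\beta,\; \sigma^2 R / N)\).

Effects carry a global–local scale-mixture (continuous-shrinkage) prior

\[ \beta_j \sim \mathcal N(0,\; \sigma^2 \phi \psi_j), \qquad
   \psi_j \sim \mathrm{Gamma}(a, \delta_j), \qquad
   \delta_j \sim \mathrm{Gamma}(b, \phi), \]

with defaults a = 1, b = 1/2 — a horseshoe-like family that shrinks null
effects aggressively while leaving large effects nearly unpenalized. The
Gibbs sweep updates, in order: each block's \(\beta\) from its
multivariate-normal conditional (generalized-ridge mean via Cholesky
solves), \(\sigma^2\) from its inverse-gamma conditional, each
\(\delta_j\) from a gamma conditional, each \(\psi_j\) from a
generalized-inverse-Gaussian (GIG) conditional capped at 1, and — when
`phi = "auto"` — the global scale \(\phi\) from a gamma step under the
half-Cauchy prior represented as a gamma mixture. The GIG sampler uses
the closed-form inverse-Gaussian transform for |λ| = 1/2 (the default
path, vectorized) and a ratio-of-uniforms rejection scheme for general λ;
the suite checks both against numerically integrated moments.

Two scaling conventions coexist in the summary-statistics literature:
the prior variance of \(\beta_j\) written as \(\sigma^2\phi\psi_j\) or as
\(\sigma^2\phi\psi_j/N\). This package uses the former, so a single
variant with unit LD, fixed \(\phi\psi = c\) and \(\sigma^2 = 1\) has the
closed-form posterior mean \(\hat\beta \cdot Nc/(Nc+1)\) — the conjugate
sub-case the tests pin, with \(\psi\), \(\sigma^2\) and \(\phi\) all
held fixed via the `fix_psi` / `fix_sigma2` arguments. With `phi="auto"`
the two conventions are reparameterizations of each other (the global
scale absorbs the factor N).

Chain defaults are 1000 iterations, 500 burn-in, thinning 5 — desk-scale
settings, far shorter than production chains; Monte-Carlo tolerances in
the tests are sized for the chain lengths each test actually runs
(60–8000 iterations depending on the check). Every draw is reproducible
from the seed carried in `cs_prior_params()`.

## Cross-fitting and scoring

`score_individuals()` computes \(\mathrm{PGS}_i = \sum_j w_j
\tilde g_{ij}\) over the variants shared between the genotype matrix and
the effect table, with dosages standardized within the scored cohort and
orientation harmonized by flipping d → 2 − d where the effect allele
matches the other allele (so flipping every recorded effect allele
negates the scores exactly — a tested symmetry).

`log_crossfit()` implements five-fold leave-one-group-out cross-fitting:
a seeded balanced partition (sizes differing by at most one, remainder to
the lowest-numbered folds; at n = 2367 and k = 5 this gives target folds
of 474/473 and discovery sets of 1893/1894), a discovery scan and
posterior draw per fold, scoring of the held-out fold only, and a final
z-standardization of the assembled vector. Fold assignment is simple
random by default — stratification by outcome is available and advised
when a class is rare enough that a fold could lose it (the error message
says so). Every sample is scored exactly once, never by weights that saw
its outcome. `external_score()` applies full-cohort weights to a disjoint
replication cohort and standardizes within it.

### What cross-fitting does and does not fix

Cross-fitting removes discovery–target circularity: scoring a cohort with
weights estimated on that same cohort produces wildly anti-conservative
association tests (in the packaged null experiment the in-sample score
rejects at α = 0.05 in essentially every replicate). The LOG score
removes this first-order bias. It does **not** make the naive Wald test
of the assembled score exactly calibrated under the global null: the
score of fold f is still a linear function of the *other* folds'
outcomes, so the association statistic is a zero-diagonal symmetric
quadratic form in the outcome vector whose true variance is twice what
the fixed-covariate standard error estimates. The naive test therefore
rejects at about \(P(|Z| > 1.96/\sqrt 2) \approx 0.17\) at α = 0.05 under
the exact null — independent of cohort size or variant count.
`experiment_circularity()` measures both rates honestly; interpret
near-threshold p-values of cross-fitted scores with this in mind. Under
real signal the weights are dominated by their outcome-independent
component and the issue recedes. A fully calibrated test would require
refitting the whole cross-fit under permutation, which is out of scope.

## Association models

The categorical outcome uses maximum-likelihood logistic regression of
responder status on the standardized PGS plus covariates (age, sex, four
PCs — chip belongs to the per-variant scans, not here), Wald 95% CIs
\(\exp(b \pm 1.96\,\mathrm{se})\), and Nagelkerke pseudo-R² for the full
and covariate-only fits; the incremental difference is the variance
share attributed to the PGS. Effects are per SD of PGS because the score
is z-standardized; odds ratios from differently scaled scores are not
comparable, so the scale is stated rather than assumed.

The continuous outcome uses a two-limit Tobit: the observed total is a
latent Gaussian \(y^* = x^\top\beta + \varepsilon\) censored at 0 and 10.
Interior observations contribute density terms; boundary observations
contribute tail probabilities. The likelihood is maximized by BFGS from
the OLS start with an analytic gradient and the scale kept positive
through a log parameterization; standard errors come from the numerically
differentiated Hessian at the optimum. The two-limit form is not
optional: the scoring rule's floor creates a real point mass at zero and
the 10 ceiling is structural, and OLS on such data attenuates slopes (the
packaged recovery experiment shows a true slope of 0.8 recovered by the
Tobit while OLS returns well under 0.7). The suite also pins the fit to
an independent interval-censored Gaussian fit from the survival package
at 1e-6. The latent-scale pseudo-R² is McKelvey–Zavoina,
\(\mathrm{var}(x^\top\hat\beta) / (\mathrm{var}(x^\top\hat\beta) +
\hat\sigma^2)\). Both pseudo-R² estimators are package choices — reported
R² values from other software need not match any particular published
number, and the estimator is swappable at the function boundary.

Decile stratification ranks samples by PGS into ten groups (stable order
on ties; sizes differ by at most one with the remainder to the lowest
deciles), reports unadjusted odds ratios against the lowest decile from
the 2×2 tables (0.5 continuity correction with a flag when a cell is
empty) and adjusted odds ratios from a logistic model with decile
indicators plus covariates. The 2×2 routine `decile_or()` is exactly the
cross-product ratio with a Woolf standard error, which is why published
decile tables can be recomputed from their printed counts.

## Gene and pathway layer

`gene_test()` is a multi-marker principal-components regression: the
gene's standardized dosage submatrix is reduced to the components
carrying 99.9% of its variance (eigenvalues below 1e-8 dropped, which
absorbs LD and rank deficiency — a duplicated variant changes nothing),
and those components are tested jointly by the F test of the full linear
model against the covariate-only model. Binary outcomes are coded 0/1 and
fitted on the linear scale, mirroring common gene-based-scan practice; a
single-variant gene reproduces the per-variant linear p exactly. Gene
windows default to 0/0 bp (gene body only) and are configurable. Genes
passing a strict p < 0.001 in either outcome's scan form the enrichment
input; `fisher_enrichment()` is the one-sided hypergeometric
(overrepresentation) test per pathway with Bonferroni correction over the
tested pathways and a significance flag at corrected p < 0.05.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, not any real genome. Genotypes: a thresholded Gaussian copula —
per LD block, latent AR(1) haplotypes (correlation `block_rho`, default
0.8) thresholded at per-population allele frequencies drawn from a
Balding–Nichols model around ancestral frequencies uniform on
`maf_range` (default [0.15, 0.45]); two subpopulations (default 50/50,
F\_ST 0.05) make PC1 separate the populations. Frequencies are redrawn
(bounded attempts) until the mixture frequency stays within the
configured range, so empirical MAFs land within ±0.03 of it; an
unsatisfiable range raises an error rather than silently drifting.

Phenotypes: a sparse causal subset (default 30% of variants) with
Gaussian effects scaled so the genetic share of liability variance equals
`h2_liability` (default 0.3); covariate slopes on standardized age and
sex; the A score produced by quantile-mapping the liability's normal
scores through a rounded affine map whose offset is grid-calibrated so
the fraction with total ≥ 7 matches `target_responder_rate` (default
0.279) within ±0.03 — the bounded search fails loudly with the achieved
rate otherwise. B items are iid on {0, 1, 2} with probabilities
(0.5, 0.3, 0.2) — pure confounder noise, independent of genotype.
Demographics follow the cohorts this design emulates: age truncated
normal 47.5 (13.9) on [18, 90], 57.8% female, 95% of samples with at
least 6 months of exposure. Identical configurations produce
byte-identical fixture bundles.

What the generator does **not** emulate: realistic recombination maps or
coalescent genealogies, imputation error (the info column is drawn, not
earned), X chromosomes, genotype–covariate dependence, site or batch
effects beyond the chip label, and rater behaviour in the ALDA scores.
Passing tests on this generator therefore demonstrate the *statistical
machinery* — calibration, recovery, invariances — not performance on real
cohort data.

## Problem sizes and numerical choices

The packaged experiments run at desk scale, chosen once: circularity
control on 200 replicate cohorts of n = 400, m = 200 with short chains
(100 iterations; under the null, chain length affects only Monte-Carlo
noise, not calibration); Tobit recovery at n = 5000 with ~25% boundary
censoring; shrinkage MSE on five n = 800, m = 200 cohorts; null
calibration pooling three n = 500, m = 2000 cohorts (pooling narrows the
Monte-Carlo noise of the genomic-inflation median, which on a single
cohort has an sd of ~0.07 against a target band of [0.9, 1.1]); signal
recovery at n = 2000, m = 400 (tests run reduced replicate counts of the
same experiments). Other numerics: dosage standardization maps
zero-variance variants to all-zero columns; LD blocks get an eigenvalue
floor of 1e-3; the logistic engines clamp linear predictors at ±30 and
floor IRLS weights at 1e-10; Tobit convergence uses `reltol = 1e-12`
with a 500-iteration budget.

## Limitations

Real deployments would add: imputation and its quality modelling
(explicitly out of scope here — the pipeline consumes already-imputed
dosages with an info column), reference-panel LD instead of in-sample
blocks, X-chromosome handling, mixed-model association for close
relatedness rather than exclusion, and calibrated (permutation-based)
inference for cross-fitted scores. Published adjusted odds ratios,
headline p-values and R² values from real cohorts depend on those
cohorts' genotypes and covariates and are not reproduction targets of the
synthetic pipeline; what is reproducible — and what the acceptance
script recomputes — are the arithmetic identities of printed decile
tables and response proportions, the cross-fitting geometry, and the
statistical properties of every engine.
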