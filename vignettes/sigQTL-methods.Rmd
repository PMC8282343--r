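---
title: "Transcriptional signatures and GxE eQTL mapping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional signatures and GxE eQTL mapping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Psychosocial exposures — socioeconomic status, family relationships,
emotionality — leave measurable traces in the blood transcriptome, and
genetic regulatory variants can amplify or dampen those traces. sigQTL
implements the analysis chain that connects the three layers:

1. learn a **transcriptional signature** for each measured variable: a
   sparse linear model predicting the variable from residualized
   expression, whose per-sample prediction is a *denoised, imputed*
   version of the variable available for the whole cohort;
2. map **cis-eQTLs** on the same residualized expression;
3. test each gene's **lead eQTL** for a dosage-by-signature
   **interaction (GxE)**, with an empirical permutation null and
   per-signature Storey q-values;
4. intersect marginal and interaction hits with an external **TWAS**
   table to flag disease-relevant genes whose regulation responds to the
   psychosocial environment.

Because the motivating data are controlled-access human genotypes, the
package ships a synthetic-cohort generator with exported ground truth;
every statistical property claimed below is measured on those cohorts by
the test suite and by `scripts/acceptance.R` — nothing is asserted that
the code does not recompute.

# Preprocessing

**Gene filter.** A gene is dropped when its count falls below 6 reads
*or* 0.1 counts per million in at least 20% of samples; equivalently it
is kept when both thresholds pass in strictly more than 80% of samples.
A gene exactly at the 20% boundary is dropped. Sex-chromosome genes
(`X`/`Y`, with or without a `chr` prefix) are removed first; the order
does not change the retained autosomal set, but library sizes for the
CPM side of the rule are computed after the removal.

**Normalization.** `log2((count + 0.5) / (libsize + 1) * 1e6)`, the
standard log-CPM transform with a 0.5 prior count. Precision weights
are deliberately not computed: every downstream fit (elastic net, OLS)
is unweighted, so weights would never be consumed.

**Covariates.** Technical and biological covariates (RIN-like axes,
batch, demographics, genotype PCs, ...) are median-imputed, one-hot
encoded (first level dropped), z-scored and summarized by their top
principal components; constant columns are dropped with a warning
rather than an error. Expression is residualized gene-by-gene by OLS on
an intercept plus these covariates, and all association testing runs on
the residuals. A rank-deficient design is a hard error naming the
collinear columns, since silently dropping one would change the model.

# Transcriptional signatures

For each variable $y$ the model is the elastic net
$y = \beta_0 + \sum_n \beta_n E(\text{gene}_n)$, fitted with `glmnet`
at mixing parameter $\alpha = 0.1$ — relaxed toward ridge so that
groups of co-regulated genes enter together instead of one arbitrary
representative. The penalty path has 100 log-spaced values from the
data-derived $\lambda_{max}$ down to $10^{-3}\lambda_{max}$; predictors
are standardized internally and coefficients reported on the original
scale.

**Cross-validation and the r² definition.** Leave-one-out CV is the
default (`folds = "loo"`); deterministic k-fold is available and is what
the pipeline driver and the permutation-null replicates use, trading a
slightly noisier error estimate for a ~30x speedup. The reported
variance explained is $r^2 = 1 - \mathrm{cvMSE}/\widehat{var}(y)$ with
the usual $n-1$ sample variance; negative values are kept and reported,
and the 1%-variance rule ($r^2 \ge 0.01$) is the selection criterion
for which signatures proceed to correlation and GxE analyses.

**Penalty selection.** The default is the one-standard-error rule: the
largest penalty whose CV error is within one SE of the curve minimum.
We measured the alternative — taking the exact minimum — under a
permuted-phenotype null at n = 250 and 2,000 genes: because the minimum
of ~100 correlated, noisy CV-MSE estimates is biased downward, it
reports $r^2 > 0.02$ for ~12% of null phenotypes (occasionally above
0.1 when a dataset happens to contain strong chance correlations,
which cross-validation *within* that dataset cannot detect). The 1-SE
rule brings the null exceedance to zero while costing only a few
percent of $r^2$ under signal, so it is the default; `lambdaRule =
"min"` remains available.

**Denoising.** The fitted model's prediction replaces the measured
value for *every* sample, including training samples. Measured values
carry idiosyncratic reporting error; the fitted signature has the same
"biological" error for measured and unmeasured individuals, so using it
uniformly reduces the variance of the environment variable without
introducing bias — fewer false GxE hits, not more.

**Restricted comparison.** `compareRestricted()` refits the same model
on a fixed panel (e.g. the published 53-gene conserved transcriptional
response to adversity, shipped in `inst/extdata/ctra_genes.txt`) and
reports both r² values plus how many panel genes were measurable.

**Longitudinal validation.** With a second wave of expression, the
signature is imputed at wave 2 from samples never seen in training, and
Spearman correlation between observed and imputed *changes* is the
out-of-sample check that the signature tracks the phenotype over time.

# cis-eQTL mapping

Candidates are variants on the gene's chromosome within 1 Mb of the
strand-aware TSS (inclusive window; for minus-strand genes the TSS is
the annotated end coordinate) with cohort MAF strictly above 0.1. MAF
is computed from dosages, $\min(m, 1-m)$ with $m = \overline{d}/2$ —
hard calls and imputed dosages are treated uniformly.

The nominal scan is per-variant OLS of residual expression on dosage
with a two-sided t-test at $n-2$ degrees of freedom. The df ignores the
columns consumed by pre-residualization; with three covariate PCs and
n = 250 the miscounting is negligible, and the permutation pass absorbs
what remains. This is a documented approximation, not an oversight.

**Permutation pass.** The expression vector is shuffled (dosages
fixed), and the minimum nominal p over candidates recorded per
permutation. Permutation proceeds adaptively: at least 1,000 rounds,
then in blocks until 100 permutation minima beat the observed minimum
or 10,000 rounds are reached. Two gene-level p-values are reported:
the direct estimate $(1 + \text{hits})/(1 + P)$ and a smooth one from a
Beta(a, b) maximum-likelihood fit to the permutation minima (moments
start, box-constrained quasi-Newton on log-parameters, bounds
$[10^{-3}, 10^6]$, moments fallback flagged), evaluated as the fitted
CDF at the observed minimum. For one candidate the null minimum is
uniform (shapes ≈ (1,1)); for m independent candidates it is
approximately Beta(1, m) — both recovered by the test suite.

Lead ties are broken by smallest nominal p, then smallest |TSS
distance|, then lexicographic variant id; per-gene permutation streams
are seeded by gene id rank, so results are invariant to gene and
variant input order.

**Gene-level FDR** uses Storey q-values over the beta-approximated
p-values (lambda grid 0.05–0.95 in steps of 0.05, cubic smoothing
spline with 3 df read off at λ = 0.95, π₀ clipped to (0, 1] with a
π₀ = 1 fallback). With π₀ fixed at 1 the q-values reduce exactly to
Benjamini-Hochberg, which the tests assert. eGenes are genes with
q ≤ 0.10.

**Expression-PC optimization.** `optimizeExpressionPCs()` appends top
expression PCs to the residualization, reruns the permutation pass per
grid value of k, and picks the k maximizing eGene count (ties to the
smallest k). Hidden expression-wide axes mask cis effects, so eGene
counts rise with k when such confounding exists; GxE mapping
nevertheless takes its leads from the k = 0 scan, because expression
PCs correlate with cell composition and the environment variables and
would muddy the interaction's interpretation.

# Interaction (GxE) mapping

Each signature is quantile-normalized by the rank-based inverse normal
transform with the Blom offset $(r - 3/8)/(n + 1/4)$ (average ranks for
ties, NA preserved) to blunt outliers. The model, fitted with `lm`, is

```
expression ~ dosage + signature + dosage:signature
```

with estimates, SEs and two-sided t p-values for all four named terms.
The cell-composition-adjusted variant prepends the four blood-cell
signatures (lymphocytes, neutrophils, monocytes, eosinophils — a
formula in circulation writes "leukocytes" where the lymphocyte
signature is meant, and the package uses the lymphocyte reading) as
main-effect covariates; they enter the model rather than being
re-residualized out of expression, matching the printed formula.
Measured-variable reruns drop samples with missing values and report
the per-record sample size rather than imputing.

**Empirical null.** Genotype dosages are permuted (the
expression-signature pairing stays intact), the model refitted, and
interaction p-values pooled across all lead pairs within a signature.
The pooled null is the reference the observed p-values are corrected
against, $p_{corr} = (1 + \#\{p_{null} \le p\})/(1 + n_{null})$ — the
+1/+1 pseudocounts avoid zero p-values. A desk-scale null of $10^6$
values is the default study size; the approach scales to the $10^8$
used on real cohorts by raising `nNull`. Storey q-values are then
computed within each signature separately, and q ≤ 0.10 declares
significance.

The batched permutation fitter works from closed-form cross-products
(one 4×4 solve per refit) and is asserted to agree with the `lm` route
to 1e-8; a million refits take well under a minute on one CPU.

**Replication bookkeeping.** Fisher 2×2 enrichment (gene had an
interaction with the measured variable at p < 0.01 × with the signature
at p < 0.01) uses full hypergeometric enumeration for the two-sided
p-value and the sample odds ratio ad/bc, 0.5-continuity-corrected and
flagged when a cell is empty. Effect concordance is the Pearson
correlation of interaction z-scores (b/se) over records joined on
(gene, variant, variable). TWAS overlap intersects, per signature, the
marginal-signature genes (q ≤ 0.10) and the permutation-corrected
interaction genes (q ≤ 0.10) with each trait's TWAS-significant genes.

# The synthetic cohort generator

The generator is the inverse of the fitted models. Counts are negative
binomial, `var = mu + dispersion * mu^2` (dispersion 0.1, typical of
bulk cohorts), with natural-log mean

```
base + betaG*dosage + betaE*latent + betaGxe*dosage*latent
     + confounders + cell composition + log(libsize share)
```

so `betaG = log(2)` doubles expression per alternate allele. Baseline
abundances are log-uniform over 2–500 CPM; library sizes log-uniform
over 2–8 million — the per-gene depth a ~40M-read blood RNA-seq study
spreads over its ~19,000 genes, scaled to the simulated panel.
Genotypes are Binomial(2, f) hard calls (a dosage mode adds truncated
Gaussian noise), f uniform within the configured MAF range. Phenotypes
are unit-variance latents plus Gaussian measurement noise; the default
noise SD of 1 sets the true signal fraction to 0.5; variables within a
category block share a factor giving within-block correlation 0.6, and
half of the samples are missing per variable by default, mirroring
deep phenotyping on a subcohort. Blood cell proportions are Dirichlet
(neutrophil-dominated) with dedicated 25-gene expression blocks;
technical confounders are Gaussian axes with sparse N(0, 0.3) gene
loadings. One master seed drives everything; each stage uses the seed
plus a fixed offset, so stages are independently reproducible and
identical configurations are byte-identical.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium among variants
(each gene's candidates are independent draws), population structure
and relatedness, read-level artifacts (mapping bias, GC effects),
batch-by-gene interactions, non-Gaussian phenotype scales, and
informative missingness. Effect-size distributions for GxE are chosen
for testability (a fixed 0.4 on the log scale), not estimated from any
cohort.

# Validation studies and their problem sizes

The exported `*Study()` functions define the package's standing
validation battery; `tests/testthat/test-acceptance.R` runs them at
fixed seeds and `scripts/acceptance.R` re-runs them at a user seed:

- **Calibration**: 1,000 null lead pairs, n = 250, confounded NB
  expression; empirical type-I error at p < 0.05 and a KS uniformity
  check of the pooled permutation null at 20,000 values. The
  parametric t p-value under NB-skewed residuals deviates from
  uniformity by ~0.005 in CDF regardless of depth — that intrinsic
  approximation is why the empirical correction exists, and the null
  size is chosen so the KS check flags genuine miscalibration rather
  than that floor.
- **Recovery**: 500 replicates of the interaction model at
  betaGxe = 0.4, MAF 0.3, n = 250; mean estimate and 95% CI coverage.
- **FDR**: 100 true pairs among 1,000, five seeds, pooled null of
  10^6; realized FDP and power at q ≤ 0.10.
- **Signature recovery**: 20 causal genes, signal fraction 0.5,
  n = 250, ~1,900 genes after filtering; LOO-CV r², imputed-vs-latent
  correlation, and 100 permuted-phenotype refits (10-fold CV).
- **Longitudinal**: unit-SD latent drift, measurement noise 0.3,
  ~100 retained pairs; Spearman rho of observed vs imputed changes.
- **Beta approximation**: 100 null genes at 10,000 permutations;
  Spearman agreement of direct and beta-approximated p-values and
  recovery of the Beta(1, m) law.

These sizes are the package's chosen study design: large enough that
the measured quantities are stable to a few percent, small enough that
the whole battery reruns in minutes on a single CPU.

# Known limitations

- The nominal-scan df and the pre-residualization df mismatch noted
  above; both are absorbed by the permutation machinery.
- π₀ estimation is unstable below a few dozen p-values; the π₀ = 1
  (pure BH, conservative) fallback then applies.
- The beta fit to permutation minima assumes independence across
  permutations of a fixed minimum-p functional; with very few
  candidate variants and extreme observed p-values the direct estimate
  saturates at 1/(P+1) while the beta estimate extrapolates — the
  reason both are reported.
- `fitInteraction` is intentionally plain OLS; heteroskedastic or
  count-level alternatives (NB GLMs) are out of scope.
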