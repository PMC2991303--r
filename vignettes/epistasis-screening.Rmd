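---
title: "Methods: multi-stage SNP-SNP interaction screening in sibship cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stage SNP-SNP interaction screening in sibship cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The statistical model

`episcreen` analyzes a positive quantitative trait (the motivating case is
left-ventricular mass in grams) measured in sibships, with genotypes at
candidate-gene SNPs coded as minor-allele counts 0/1/2. The trait is
log-transformed — the natural log makes a multiplicative trait model
additive and brings the residuals close to Gaussian — and adjusted by
least squares for a risk-factor set (age, sex, systolic blood pressure,
height, weight) plus the leading principal components of a marker matrix,
which absorb confounding by admixture. The residuals of this adjustment are
the dependent variable of every association test.

All tests are nested Gaussian linear model comparisons evaluated with the
partial F-test. For nested least-squares fits the F statistic is an exact
monotone transform of the Gaussian likelihood-ratio statistic, so "LRT" and
"partial F" identify the same test; we use the F form because it is exact at
finite samples (the package verifies the asymptotic agreement of the two
forms as a property test).

Genotypes enter as *two indicator dummies* against the common-homozygote
reference. This 2-df coding imposes no dominance/additivity assumption, and
dummy products span every possible two-locus interaction pattern. When a
genotype class is unobserved its dummy is dropped; when joint classes are
missing, the estimable interaction degrees of freedom are determined by the
design-matrix rank difference (QR with tolerance `1e-8`), giving 1 to 4
interaction df per SNP pair. Rank-based accounting, rather than cell-count
heuristics, is used because it is exact and unambiguous for any missingness
pattern.

The three Stage I families are:

| family | full model | reduced model |
|---|---|---|
| SNP main effect | intercept + dummies | intercept |
| SNP x covariate | dummies + covariate + products | dummies + covariate |
| SNP x SNP | d1 + d2 + all dummy products | d1 + d2 |

For a SNP-covariate test whose covariate belongs to the adjustment set, the
residuals are re-derived with that covariate excluded, so its main effect is
estimated inside the interaction model rather than regressed away twice.
Complete cases are taken per test; missing genotypes are never imputed for
testing (mean imputation is used only inside the PCA).

## Stage II: the three-criterion screen

A result is a *positive association* only when it passes all three
pre-determined criteria — each criterion targets a different failure mode,
and any single failure vetoes:

1. **FDR q-value < 0.30.** Benjamini–Hochberg step-up q-values computed per
   test family (the main-effect family is screened on its model p-values,
   the interaction families on their partial-F p-values). BH was chosen as
   the default estimator because it is the assumption-light baseline; a
   Storey-type null-proportion rescaling (`pi0` at `lambda = 0.5`) is
   available behind `criteria_config(storey_pi0 = TRUE)` for users who want
   the less conservative variant. The q-value literature offers both
   readings and the choice is deliberately exposed rather than hidden.
2. **Incremental CV R² > 0.005.** Ten repeats of 4-fold cross-validation;
   in each repeat the sample is randomly split into four near-equal folds,
   each fold is predicted from a fit on its complement, and the pooled
   prediction R² is `1 - SSE/SST` over all held-out predictions with SST
   about the full-sample mean. The criterion is the difference between the
   full (interaction) and reduced (main-effects) model, computed on shared
   partitions. Defining CV R² as pooled prediction R² rather than a
   squared correlation preserves sign — a model with no predictive
   information scores slightly *below* zero, and negative values are not
   truncated. The 0.5% threshold is calibrated: under a permuted-residual
   null the chance of exceeding it is below 5% (`permutation_calibrate()`
   re-derives this, and `scripts/acceptance.R` prints it).
3. **Internal replication at α = 0.10.** Two disjoint subsets are built by
   sampling one sibling per sibship without replacement, then one of the
   remaining siblings per sibship; singletons contribute only to the first
   subset. The *identical* test is re-run within each subset, with the
   adjustment residuals re-derived per subset — a full per-subset pipeline,
   including within-subset principal components at the same dimensionality
   as the full-sample analysis (capped by subset size). Associations passing
   all three criteria are additionally annotated for homogeneity across the
   subsets: concordant signs of all shared interaction coefficients plus a
   per-term two-sample z-test `(b1-b2)/sqrt(se1^2+se2^2)` at 0.05. The
   homogeneity test is an operationalization choice — direction concordance
   is strict for near-zero nuisance terms, so the verdict is reported as an
   annotation, not a fourth gate.

Because the two subsets are drawn from the same cohort, the replication
criterion is *internal*: a chance pattern strong in the full sample is
partially present in both halves, so the joint screen's false-positive rate
is higher than the naive product of the three criteria's levels. The screen
controls, but does not eliminate, false positives; the package's null
calibration tests quantify this.

## Multivariable modeling

Screened SNP-SNP interactions enter a forward-selected multivariable model.
Candidates are pooled as the 10 strongest by full-model p-value; the first
block is the candidate with the smallest full-model p-value, and each later
step adds the block (new main-effect dummies plus products; a SNP's dummies
enter at most once across blocks) with the smallest partial-F p-value
against the current model. Selection stops at 4 blocks — a fixed cap chosen
to avoid over-parameterization — or earlier when the best added-block
p-value exceeds a configurable cap (default 0.05; the cap is this package's
addition, since a fixed block count alone can force uninformative terms into
small models). Per-step accounting reports R², adjusted R², the added-block
partial-F p-value and df, and the full-model repeated-CV R².

Because siblings are correlated, the selected model is refit as a linear
mixed model with a sibship random intercept (REML via `lme4`), and each
block's interaction terms are tested jointly with a Satterthwaite
F-test (`lmerTest`). Satterthwaite F was chosen over an ML likelihood-ratio
test because it is finite-sample comparable to the fixed-model partial F
and degenerates to it exactly as the random-intercept variance goes to
zero. The output is the per-block fixed/mixed p-value pairs and their
Pearson correlation; values near 1 indicate the inferences are not driven
by familial correlation. A single sibship-level random intercept is the
minimal structure consistent with the sampling design.

## The synthetic cohort generator

No cohort of this design is publicly deposited, so the simulator is a
first-class, tested component. It emulates:

- **Sibships**: sizes 1–5 drawn from a configurable distribution; the
  default `(.25, .45, .18, .09, .03)` gives mean size 2.2, a desk-scale
  stand-in for a hypertensive sibship cohort (the default 150 sibships /
  300 SNPs stands in for ~1,300 individuals x ~1,900 SNPs; tests that need
  cohort-scale power use 590 sibships ≈ 1,300 individuals).
- **Two-way admixture**: each sibship draws an ancestry proportion
  theta ~ Beta(8, 2) (mean 0.8), shared by its members because admixture is
  a family-level confounder; the two ancestral populations sit at allele
  frequencies `p ± divergence/2` (default divergence 0.2, a typical
  continental-scale allele-frequency difference).
- **Mendelian transmission**: two unobserved parents per sibship are drawn
  in Hardy–Weinberg proportions at the family's admixed allele frequency,
  and each child inherits one uniformly chosen allele per parent, giving
  sibling genotype correlation ≈ 0.5 — the property the replication split
  must survive.
- **A 15-covariate risk-factor panel** with marginals matched to an older,
  mostly hypertensive cohort (mean age 63, 79% hypertensive, mean SBP 138).
- **A log-normal trait**: log-trait = intercept + covariate effects +
  dummy-coded SNP effects + dummy-product epistatic effects + ancestry
  effect + sibship random intercept (default SD 0.10) + Gaussian noise
  (default SD 0.25, matching a coefficient of variation ≈ 0.3 around a
  160-gram trait). Generating on the log scale and exponentiating makes the
  pipeline's log transform exactly correct on synthetic data. Missingness
  (default 2%) is masked only in the released genotype matrix; effects are
  evaluated on the complete matrix so injected signals are well defined.

`pure_epistasis_effects()` constructs the adversarial case the pipeline
exists for: a dummy-product effect combined with compensating main effects
equal to minus the least-squares projection of the product indicator on the
main-effect dummies, computed from the realized genotypes. The genetic term
is then orthogonal to both SNPs' codings — single-SNP scans see exactly
null signal — and the product coefficient `gamma` is calibrated so the
interaction's incremental R² against the unexplained trait variance hits a
target (default 3%).

What the simulator does **not** emulate: linkage disequilibrium between
SNPs (columns are independent given ancestry), multi-generation pedigrees,
X-chromosome dosage, genotyping error, or non-Gaussian measurement error.
Passing tests therefore demonstrate the pipeline's statistical behavior
under clean Mendelian sampling with admixture — not robustness to LD
structure or assay artifacts in real data.

## Numerical and degenerate-input choices

- Rank decisions use QR with tolerance `1e-8`; aliased coefficients are
  `NA` in fit output and treated as zero for out-of-sample prediction
  (intercept-plus-available-terms), with such events counted.
- Dummy reference = the more frequent homozygote, ties broken toward
  allele-count 0; monomorphic SNPs raise an error and are skipped (and
  logged) by the scan driver.
- Hardy–Weinberg testing uses the 1-df chi-square goodness-of-fit test,
  switching to the exact test (enumeration over heterozygote counts given
  allele counts, probability-ordered two-sided p) when any *observed*
  genotype class has fewer than five individuals. The exact HWE test is the
  standard exact analogue for three genotype classes.
- PCA mean-imputes missing genotypes (PCA only), drops constant columns
  with a warning, and fixes component signs by making each component's
  largest-magnitude loading positive, so results are deterministic.
- CV partitions are drawn from the criteria seed; nested models share
  partitions so the incremental CV R² isolates the interaction terms. Folds
  are individual-level by default — whether fold boundaries should respect
  sibships is a genuinely open design point; individual-level folds match
  the "divide the full sample into four equally sized groups" reading, and
  a grouped variant can be layered on `cv_partitions()` if needed.
- The permutation null permutes the *adjusted residuals*, not the raw
  trait, because the residuals are the quantity actually modeled
  downstream.
- The replication split is drawn once per run from a stated seed. With all
  sibships of size ≥ 2 both subsets have one member per sibship; singleton
  sibships make the first subset larger. (Published cohorts of this design
  report subset sizes inconsistent with any one-per-sibship scheme we could
  reconstruct; the scheme here is the stated one, exactly.)
- Admixture adjustment defaults to 20 components. When no separate marker
  panel is supplied, PCs are computed from the analysis SNPs themselves.
  This double use has a cost: with few SNPs relative to sample size the
  leading PCs absorb part of each tested SNP's own variance and the tests
  become conservative. The calibration tests therefore use unstructured
  null cohorts with `n_components = 0`, and users with an external marker
  panel should pass its `compute_pcs()` scores to
  `adjusted_residual_sets(pcs = ...)`.

## Problem sizes used by the test suite

The package's statistical tests run at deliberately chosen desk scales:
null calibration uses 20 unstructured cohorts of 100 SNPs x ~300
individuals (~99,000 pair tests pooled); permutation calibration uses one
~1,300-individual null cohort and 200 permutations; embedded-signal
recovery uses 50 replicates of a 3%-R² pure-epistasis pair at ~1,300
individuals, where the three-criterion screen is expected to pass the pair
in roughly 85% of replicates (the second, smaller replication subset is the
binding criterion — its noncentral-F power at α = 0.10 is ≈ 0.9).

## Known limitations

- All-pairs scanning is O(S²) in SNP count and runs single-threaded in R;
  ~5,000 pair tests take on the order of ten seconds at n ≈ 300.
- The screen's criteria are dependent (same sample), so their joint
  false-positive rate is not the product of their nominal levels.
- The homogeneity verdict's sign-concordance component is conservative for
  interaction terms whose true coefficients are near zero.
- Storey π₀ estimation uses a single-λ estimate rather than the smoothed
  spline variant.
- The mixed-model check tests the selected blocks only; it is a sensitivity
  analysis, not a re-screen under the mixed model.
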