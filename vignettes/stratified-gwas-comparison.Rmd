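---
title: "Comparing stratified GWAS with LD-score regression and genomic structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing stratified GWAS with LD-score regression and genomic structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratgsem)
```

## The problem

When a disorder such as autism is diagnosed in different subgroups —
males and females, or people diagnosed early versus late in life — the
subgroup GWAS define partially distinct phenotypes.  Two questions follow
naturally.  First, how genetically similar are the subgroups ($r_g$
between the stratified GWAS)?  Second, do the subgroups relate
*differently* to external traits — psychiatric disorders, cognitive
measures, social outcomes — and if so, is the divergence explained by a
shared dimension such as internalizing liability?

`stratgsem` implements the full chain of methods needed to answer these
questions from GWAS summary statistics alone:

1. **Munge-style quality control** of summary statistics (allow-list
   restriction, allele alignment, strict MAF and INFO filters, MHC
   exclusion).
2. **Multivariable LD-score regression** producing a genetic covariance
   matrix $S$ (heritabilities on the diagonal) and the full sampling
   covariance $V$ of $\mathrm{vech}(S)$ via a delete-one block jackknife,
   with liability-scale conversion for case-control traits.
3. **Structural models on $(R, V_R)$** fitted by diagonally weighted
   least squares (DWLS) with sandwich standard errors: saturated and
   equality-constrained correlation models, genetic multiple regression,
   and a common-factor residualization model.
4. **Battery orchestration**: per-trait constrained-vs-free comparisons
   (1 df each), Benjamini–Hochberg FDR across the battery, and
   adjusted-versus-unadjusted comparison tables.

Because the real stratified GWAS are access-restricted, the package
ships a **synthetic summary-statistics generator** whose generative model
is exactly the estimand of cross-trait LDSC.  Every downstream stage is
therefore testable end to end with known truth.

## The generative model

For SNP $j$ with LD score $\ell_j$, the vector of z-statistics across $k$
traits is drawn as

$$ z_j \sim \mathcal{N}_k\!\left(0,\; B + \ell_j A\right), \qquad
   A_{kl} = \frac{\sqrt{N_k N_l}\,\rho_{kl}\sqrt{h^2_k h^2_l}}{M}, $$

where $N$ is the effective (case-control) or total (continuous) sample
size, $\rho$ the genetic correlation matrix, $h^2$ the observed-scale
heritability, and $B$ the intercept matrix: unit diagonal, off-diagonal
$N_s\rho_{\text{pheno}}/\sqrt{N_k N_l}$ induced by participant overlap.
SNPs are independent given $\ell$.  Both $A$ and $B$ must be positive
semidefinite; because $\ell_j \ge 1$, this is exactly the condition for
every per-SNP covariance to be valid, and the generator refuses
infeasible configurations naming the offending trait pair.  Sampling uses
$z_j = L_B u_j + \sqrt{\ell_j}\,L_A v_j$ with independent standard-normal
$u, v$, which is fast and exact.

LD scores are i.i.d. draws from a gamma distribution shifted to a floor
of 1 (positive and right-skewed like real L2 values; mean 40, shape 2 by
default), and SNPs are partitioned into 200 contiguous blocks — the
synthetic chromosomes — matching the jackknife granularity downstream.

**What the generator does not emulate:** real LD structure (SNPs are
exchangeable given $\ell$, there are no LD blocks correlating
neighbouring test statistics), allele-frequency-dependent architecture,
population stratification, and annotation-specific enrichment.  Passing
recovery tests therefore demonstrates correctness of the estimators
under the LDSC model, not robustness to model misspecification in real
data.

### Default study conditions

The `preset_battery()` defaults mirror a sex- and age-at-diagnosis
stratified autism battery: generating correlations
$r_g(\text{male},\text{female}) = 0.81$,
$r_g(\text{early},\text{late}) = 0.42$,
$r_g(\text{late},\text{male}) = 0.99$ and
$r_g(\text{late},\text{female}) = 0.91$; iPSYCH-like case/control counts
for the sex strata (15,025/19,763 and 4,845/19,315) and effective sizes
near 33,600 and 21,800 for the age strata; liability heritability 0.2
with prevalences 0.5–2%.  The two pairs not pinned down by the published
correlations (early–male, early–female) are set to 0.45 and 0.40,
consistent with the near-unit correlation between the late and male
strata.  This raw matrix is very slightly indefinite (smallest eigenvalue
$-0.0095$), so the preset projects it to the nearest positive
semidefinite correlation matrix (eigenvalue clipping with unit-diagonal
restoration); the maximum entry-wise change is about 0.009 and is
recorded on the returned matrix.  The projected values are the generating
truth that recovery tests target.

Simulations run at $M = 2000$ SNPs.  At this scale each regression
carries a strong per-SNP signal, which keeps Monte-Carlo studies
(hundreds of full pipeline replicates) fast while preserving every
statistical property of interest; the methods themselves are
scale-free in $M$.

## Estimation choices

**Regression and weights.**  Each entry of $S$ comes from a two-step
weighted regression of $z_k z_l$ (or $\chi^2 = z_k^2$) on
$N \ell_j / M$.  Weights are inverse variances under the generative
model: $\mathrm{Var}(z_k z_l \mid \ell) = v_k v_l + v_{kl}^2$, where
$v_k = \text{intercept}_k + N_k h_k^2 \ell / M$ is the univariate
expected chi-square (so the univariate case reduces to the familiar
$2v^2$).  Preliminary univariate fits supply $v_k$; step one evaluates
the pair's own term at intercept 1 and unit slope, step two re-evaluates
at the step-one estimates with the slope clamped to
$[0, (M/N)\max\ell]$ for weighting only.  We deliberately omit the
$1/\ell$ over-counting factor used on real data: it corrects for
correlation between neighbouring SNPs in LD, which the generative model
does not have, and at desk scale it concentrates essentially all weight
on a handful of low-$\ell$ SNPs and destroys the cross-trait estimator's
precision.  Any fixed positive weights leave the estimator unbiased;
this choice is about efficiency, and the block jackknife standard errors
remain calibrated either way (verified by simulation: the empirical SD of
the null genetic correlation matches the mean jackknife SE within 25%).

**Jackknife.**  200 contiguous delete-one-block re-estimates of the full
$\mathrm{vech}(S)$ vector give
$V = \frac{b-1}{b}\sum_i (\theta_{(i)} - \bar\theta)(\theta_{(i)} -
\bar\theta)'$, which is positive semidefinite by construction.  The
half-vectorization order — columns of the lower triangle, left to right —
is shared by $V$, model Jacobians and residual vectors throughout.

**Liability conversion.**  Case-control estimates are multiplied by
$\sqrt{c_k c_l}$ with
$c = K^2(1-K)^2 / \{P(1-P)\phi(\Phi^{-1}(1-K))^2\}$.  Under the summed
effective-sample-size convention the sample prevalence is fixed at
$P = 0.5$; the generator defines observed-scale heritability as the
liability value divided by the same factor, making the round trip exact.
Conversion is applied inside every jackknife replicate so that $V$ is on
the same scale as $S$.

**Standardization.**  $R = \mathrm{cov2cor}(S)$, with $V_R$ obtained by
standardizing within each jackknife replicate and re-applying the
jackknife formula — sampling dependence between numerator and
denominator propagates exactly, and the unit diagonal carries zero
sampling variance.

## Model fitting and tests

Models are fitted to $(R, V_R)$; the unit diagonal is fixed, so only
structured off-diagonal elements enter the discrepancy
$F(\theta) = (s - \sigma(\theta))' D^{-1} (s - \sigma(\theta))$ with
$D = \mathrm{diag}(V_R)$ restricted to those elements.  The optimizer is
a damped Gauss–Newton iteration with finite-difference Jacobian, three
jittered starts (seed-controlled), and convergence at gradient
infinity-norm $10^{-8}$; purely correlational models converge in one
step because $\sigma$ is linear.  Standard errors are sandwich
estimates using the full $V_R$ sub-block.  The first factor loading is
constrained positive (sign tie-break); loadings beyond 1 in magnitude
raise a Heywood warning, and negative residual variances flag the
solution inadmissible without suppressing the estimates.

**Model chi-square.**  $T = e' \Gamma^{+} e$, where $e$ are the DWLS
residuals and $\Gamma$ is $V_R$ projected onto the residual space
(pseudo-inverse at rank = df).  For the 1-df equality constraint we also
compute the Wald contrast
$(r_1 - r_2)^2 / (\mathrm{var}_1 + \mathrm{var}_2 - 2\,\mathrm{cov})$
side by side; the two are asymptotically equivalent, coincide exactly
under equal weights, and the package asserts their agreement in tests.
Because the free model is saturated, the constrained model's chi-square
*is* the difference test — the two readings of "difference p-value"
coincide by construction, and both are implemented.

**Multiple regression.**  Standardized partial effects
$\beta = R_{xx}^{-1} r_{xy}$ with delta-method standard errors
propagating $V_R$ through the closed form.  Predictor pairs with
$|r| \ge 0.95$ are refused: with near-collinear strata (the late/male
correlation of 0.99 is the canonical case) partial effects lose
interpretability, so the fit signals rather than returning fragile
estimates.

**Factor residualization.**  One common factor (unit variance, free
loadings) over at least three indicator disorders, regression paths to
each target, and free residual covariances among targets.  Target
variances are fixed at 1, so residual variances are $1 - \beta^2$ and
the *standardized residual covariance*
$c_{st}/\sqrt{(1-\beta_s^2)(1-\beta_t^2)}$ is the adjusted association —
what remains of a genetic correlation once the shared factor variance is
removed.  The equality of two adjusted associations is tested by a Wald
contrast on their sandwich covariance.

## Battery orchestration

Traits enter the battery only with a heritability z-statistic above 4
(strict).  Difference p-values are FDR-corrected (Benjamini–Hochberg)
across the battery; per-stratum correlation p-values are corrected as a
separate family — the analysis families are distinct questions, and
pooling them would couple their error budgets.  Each trait in the
adjusted-versus-unadjusted comparison is classified by its pair of FDR
flags: `persists`, `attenuated-to-ns`, `newly-significant`, or
`stable-ns` (the fourth class completes the partition for traits
significant in neither analysis).

## A worked example

```{r example, eval = FALSE}
cfg <- preset_battery(n_external = 4, M = 2000, seed = 7)
res <- run_pipeline(cfg, strata = c("ASD_male", "ASD_female"),
                    externals = sprintf("external_%d", 1:4))
summary(res$gcov)
res$battery
```

The `battery_table` prints one row per external trait with the two
stratum correlations, the 1-df constrained-model chi-square, raw and
FDR-adjusted difference p-values, and significance flags.

## Numerical and degenerate-input behaviour

* Weight variance terms are floored at $10^{-3}$; univariate expected
  chi-squares feeding the cross-trait variance model are floored at 0.1.
* Constant LD scores make the regression rank-deficient and are refused,
  as are fewer than 2 jackknife blocks, an empty post-QC SNP set, and an
  inter-trait SNP intersection below 200.
* Sub-matrices of $V_R$ extracted for a 3-variable comparison are checked
  for positive semidefiniteness; failing traits are skipped and logged
  rather than producing unstable chi-squares.
* Traits with non-positive estimated heritability cannot be standardized
  and are reported by name.

## Known limitations

* The generator's exchangeable-SNP design cannot probe robustness to
  realistic LD, in-sample overlap between the LD reference and the GWAS,
  or attenuation from imperfect imputation.
* Only single-factor residualization is provided (the use case here);
  there is no general SEM syntax, multi-factor EFA, or partitioned
  heritability.
* Sample-overlap handling is limited to the free cross-trait intercept;
  no constrained-intercept meta-analytic correction is attempted.
* Monte-Carlo checks in the test suite run at $M = 2000$ with tens to
  hundreds of replicates; they bound bias at the precision those sizes
  afford (stated in each test), not asymptotically.
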