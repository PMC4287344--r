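---
title: "Metabolite QTL analysis in family cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite QTL analysis in family cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mqtlkit implements a complete metabolite-QTL (mQTL) workflow for
family-based cohorts of the genetic-isolate type: serum metabolites are
quantified from paired 1D NMR spectra, their heritability and shared-
household (sibship) effects are estimated under a polygenic model, a
kinship-aware mixed-model score test scans genotype dosages genome-wide with
a metabolome-wide multiple-testing correction and mode-of-inheritance
models, and sequence variants in candidate genes are fine-mapped against the
lead GWAS SNP by reciprocal conditional association. Because individual-
level cohort data of this kind is not publicly distributable, the package
ships a synthetic-data generator that reproduces the statistical structure
every stage relies on, and all validation experiments run on that generator.

This vignette explains each model, the tunable parameters and the reasoning
behind their defaults, the numerical choices, and what the synthetic
experiments do and do not demonstrate.

## 1. NMR quantification

### The two-spectrum model

Serum 1D NMR offers a trade-off: a CPMG (Carr-Purcell-Meiboom-Gill)
spectrum has high signal-to-noise but heavily convoluted peaks, while the 1D
projection of the 2D J-resolved (JRES) experiment resolves overlapping
multiplets at lower signal-to-noise. The quantification strategy combines
them: peaks are *identified and shaped* on the resolved JRES projection and
then *quantified* on the CPMG spectrum through a linear model.

Each peak is a pseudo-Voigt (mixed Gauss-Lorentz) profile

$$f(x) = A\,[\eta\,L(x; x_0, w) + (1-\eta)\,G(x; x_0, w)],$$

with unit-height Lorentzian $L$ and Gaussian $G$ sharing the full width at
half maximum $w$ (ppm), height $A$, center $x_0$ (ppm), and Lorentzian
fraction $\eta \in [0,1]$. Unit-height components with shared FWHM were
chosen as the concrete mixed-lineshape form because they give the profile
two exact, testable anchor points ($f(x_0) = A$ and
$f(x_0 \pm w/2) = A/2$ for every $\eta$) and an analytic area,
$A\,w\,[\eta\,\pi/2 + (1-\eta)\tfrac12\sqrt{\pi/\ln 2}]$.

### Deconvolution by restarted simplex

`detect_peaks()` seeds one peak per local maximum whose prominence exceeds
`min_prominence` (default 0.05, as a fraction of the maximum intensity;
initial widths from the half-maximum crossings, initial $\eta = 0.5$). A
light moving-average filter (7 points) is applied for detection only, so
noise maxima do not seed spurious peaks; the fit itself uses the raw data.

`deconvolute()` minimizes the residual sum of squares with the Nelder-Mead
simplex (standard coefficients: reflection 1, expansion 2, contraction 0.5,
shrink 0.5, via `stats::optim`). Three numerical choices make this reliable
where a single large simplex is not:

* **Windowing.** The spectrum is split wherever the signal stays below 2%
  of its maximum, and each window is fitted independently. This keeps the
  simplex dimension small (a joint fit over hundreds of peaks is
  ill-conditioned) and makes the per-sample cost linear in the number of
  spectral regions.
* **Variable projection.** At every simplex evaluation the peak amplitudes
  are profiled out by linear least squares; the simplex only searches
  centers, log-widths and mixing fractions. Amplitude-width-eta trade-offs
  are the worst-conditioned directions of the joint problem, and removing
  them lets the simplex converge to parameter errors below $10^{-3}$
  relative on noiseless fixtures instead of stalling at a few percent.
* **Block-coordinate restarts.** Each restart first runs a 3-parameter
  simplex per peak (holding the others fixed), then a joint simplex over
  all nonlinear parameters, until the objective stops improving (relative
  improvement below $10^{-3}$ between restarts, or residual below
  $10^{-11}$ of the spectrum's total power; at most 20 restarts with
  convergence tolerance $10^{-10}$ and $200 \times \text{dim}$ iterations
  per run). Soft quadratic penalties keep centers inside the window,
  widths between the grid step and the window span, and $\eta$ in
  $[0, 1]$; restarts always keep the best evaluated vertex, so the
  returned residual can never exceed the residual at the initial
  parameters.
* **Residual-driven insertion.** When two overlapping peaks are merged by
  the detector (common at separations near $1.5 w$ under noise), the fit
  leaves a localized residual well above the noise floor; a peak is then
  added at the residual maximum and the window refitted (at most twice per
  window, only kept if the residual improves).

Non-convergence within the restart cap is flagged on the result, not raised
as an error.

### CPMG quantification

`quantify_cpmg()` models the CPMG spectrum as
$c(x) \approx \sum_k a_k\,s_k(x) + \text{baseline}$, where $s_k$ are the
JRES-fitted peak shapes re-broadened by a single multiplicative width
factor per batch (estimated by 1-D minimization of the pooled least-squares
residual, default search interval 1-8; the JRES projection resolves peaks
at roughly one third of the CPMG linewidth in the simulated data, and the
estimator recovers that factor). Coefficients are non-negative by default
(concentrations cannot be negative) via non-negative least squares; the
polynomial baseline columns (default degree 1) enter unconstrained. Plain
least squares is available with `nonneg = FALSE`. This linear-model
construction, the re-broadening link and the QC criteria below are explicit
stand-ins: the upstream wet-lab protocol they emulate is not publicly
specified in detail.

`group_peaks()` assigns peaks to candidate metabolites by single-linkage
clustering of the across-sample Pearson correlation at threshold
`r_threshold = 0.8`: peaks that belong to one compound rise and fall with
its concentration and correlate near 1, while peaks of different compounds
correlate only through biological covariation. The threshold is
deliberately high so that biologically correlated but distinct metabolites
are not merged; with very few samples the correlation estimate is noisy,
hence the hard minimum of 3 samples.

`qc_spectrum()` flags spectra whose signal-to-noise ratio (maximum
baseline-corrected intensity over a robust noise estimate from first
differences) falls below `min_snr = 10` or whose fitted linear baseline
drifts across the axis by more than 20% of the maximum intensity.

## 2. Phenotype preparation

Traits are prepared in a fixed, logged order — exclude flagged samples
(e.g. lipid-lowering medication), remove outliers, rank-transform:

* **Outlier rule.** Values more than 4 SD from the mean are set missing,
  with mean and SD computed *once* over the non-missing values. The pass is
  deliberately single-shot: re-estimating after removal is a different
  (iterative) procedure. A constant trait has SD 0 and the rule is vacuous.
  Outliers are removed before any covariate adjustment; whether adjustment
  should come first is genuinely ambiguous, and the package records the
  choice in the transformation history.
* **Rank transform.** Non-missing values are replaced by ranks $1..m$ with
  average ranks for ties; missing values stay missing and consume no rank.
  Plain ranks (not inverse-normal scores) are the primary transform;
  inverse-normal is easy to apply downstream for sensitivity analysis.
* **Partial correlations** between metabolites and clinical risk factors
  are Pearson correlations of residuals after linear regression on the
  covariates, with $t$-based p-values on $n - q - 2$ df. The estimator
  behind the published correlations is not stated; Pearson-on-residuals is
  the documented assumption here.

## 3. Heritability and household effects

The polygenic model for a prepared trait $y$ is

$$y \sim N(X\beta,\; \sigma^2_g\,2\Phi + \sigma^2_c\,H + \sigma^2_e\,I),$$

with $\Phi$ the kinship matrix (computed from the pedigree by the recursive
tabular method; marker-based kinship is out of scope because the synthetic
pedigree is known exactly), $H$ the 0/1 household-sharing matrix, and age
and sex as fixed covariates. Heritability is
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_c+\sigma^2_e)$ and the household
effect $c^2$ analogously. Households are defined as full sibships (children
of the same parent couple); whether a residence-based definition would
differ is untestable here and the sibship choice is stated, not inferred.

`reml_fit()` maximizes the *restricted* likelihood (REML), the convention
of pedigree variance-component analysis, with these numerical choices:

* The model is rotated into the eigenbasis of $2\Phi$ (computed once per
  pedigree and shared across all metabolites). Without a household term
  every likelihood evaluation is then $O(n)$.
* With a household term, the covariance in the rotated basis is diagonal
  plus a low-rank household part; a Woodbury/Cholesky identity reduces each
  evaluation to one $O(nq^2)$ product and $O(q^3)$ factorization
  ($q$ = number of households).
* The residual scale is profiled analytically, leaving a bounded
  derivative-free search over log variance *ratios*: Brent's method alone
  in the one-ratio case, and a nested Brent search (outer genetic ratio,
  inner household ratio, with the expensive pieces cached per outer step)
  in the two-ratio case. Preset starting points are probed afterwards as a
  safeguard; if one beats the nested optimum, a Nelder-Mead refinement is
  run from it. A component that converges below $10^{-6}$ of the total
  variance is refit at the 0 boundary.
* Standard errors come from the numerical Hessian of the unprofiled
  restricted likelihood at the optimum (central differences), with the
  delta method for the ratios.

Two degenerate designs are detected and flagged rather than silently fit:
identity kinship (only $\sigma^2_g + \sigma^2_e$ is identifiable) and an
all-singleton household design ($H = I$, so $\sigma^2_c$ and $\sigma^2_e$
are jointly unidentifiable; the household component is dropped).

## 4. Mixed-model score-test GWAS

`null_model()` fits the polygenic null once per trait; every variant is
then tested by the family-based score test: with $\hat V$ the fitted null
covariance, $r$ the GLS residuals, and $\tilde g$ the coded genotype
centered at its $\hat V^{-1}$-weighted mean,

$$U = \tilde g^\top \hat V^{-1} r, \qquad
\chi^2_1 = \frac{U^2}{(\tilde g^\top \hat V^{-1} \tilde g)\,\hat\sigma^2_r},
\qquad \hat\beta = U / (\tilde g^\top \hat V^{-1}\tilde g),$$

with $\hat\sigma^2_r = r^\top \hat V^{-1} r/(n-p)$. This avoids a
mixed-model refit per SNP; under identity kinship it reduces exactly to the
classical OLS score test. The GWAS null covariance excludes the household
component by default, matching the two-stage polygenic-null practice
(household enters heritability estimation only); `include_household = TRUE`
is the documented divergence knob. The vectorized scan (`run_gwas()`)
computes all statistics from a single rotation of the genotype matrix into
the kinship eigenbasis and is exactly equal to the per-variant test.

One property of this statistic is worth knowing when judging calibration
experiments: all 10,000 null tests share one realized trait, so the
*empirical* type-I rate fluctuates around 0.05 from trait draw to trait
draw slightly more than the binomial standard error of independent tests
would suggest (about $\pm 0.004$ rather than $\pm 0.002$ at $n \approx
2000$). Averaged over trait draws the test is calibrated, and the naive OLS
scan on the same family data is grossly inflated (type-I $\approx 0.14$).

Other pieces:

* **Mode-of-inheritance scan**: additive $\{0,1,2\}$, dominant
  $\{0,1,1\}$, recessive $\{0,0,1\}$ and over-dominant $\{0,1,0\}$ codings
  of hard-called genotypes; dosages farther than 0.1 from an integer are
  set missing before calling. The best model is the smallest p-value;
  codings that collapse to a constant are skipped with a reason.
* **Metabolome-wide threshold**: the genome-wide level divided by the
  number of unique metabolites, $5\times10^{-8}/42 = 1.19\times10^{-9}$.
  The division result is authoritative; both common printed renderings
  ($1.2\times10^{-9}$ and $1.10\times10^{-9}$) are two-significant-figure
  roundings of convenience.
* **Explained variance**: $R^2 = 100\,\hat\beta^2\,\mathrm{Var}(g_{\rm
  coded})/\mathrm{Var}(y_{\rm resid})$, in percent.
* **Analytic power**: a two-sided 1-df chi-square test with non-centrality
  $n\,2\,\mathrm{maf}(1-\mathrm{maf})\,\beta^2$, where $\beta$ is the
  per-allele effect in phenotypic SD units on a unit-variance trait (the
  "effect size" unit is assumed to be per-allele SD; it is not defined
  more precisely in the source material). At the cohort design
  ($n = 2482$, MAF 0.30, metabolome-wide $\alpha = 1.1\times10^{-9}$) this
  gives 67% power at $\beta = 0.2$ and ~100% at MAF 0.15, $\beta = 0.4$.

No genomic-control correction is applied; the inflation factor
$\lambda = \mathrm{median}(\chi^2)/0.4549$ is reported only.

## 5. Conditional fine-mapping

For each sequence variant against the lead GWAS SNP, `conditional_pair()`
reports the marginal p-value, the variant adjusted for the lead, and the
lead adjusted for the variant, plus the dosage (composite) LD $r^2$.
Variants observed in fewer than 5 minor-allele carriers are removed first
("observations" is read as non-missing minor-allele carriers; a variant
with exactly 5 is retained).

The conditional tests refit the GLS fixed effects with the conditioning
genotype included (variance components kept from the null fit, not a
residual-on-residual regression) and residualize the *tested* genotype on
the full fixed-effect set under the $\hat V^{-1}$ inner product. This
projection matters: with a tag at $r^2 = 0.9$, centering alone would
overstate the score variance by roughly $1/(1-r^2)$ and make the
conditional test an order of magnitude too conservative, which would
misclassify genuinely causal variants as adding nothing.

Classification at defaults $\alpha_{\rm keep} = 10^{-3}$,
$\alpha_{\rm drop} = 0.05$ (configurable; the published selection rule
names the adjusted p-value but no thresholds):

| pattern | call |
|---|---|
| variant survives adjustment, lead collapses | `explains_lead` |
| both survive | `independent` |
| variant adds nothing ($p \ge \alpha_{\rm drop}$) | `tagged_by_lead` |
| $r^2 > 0.999$ | `indistinguishable` |
| otherwise | `indeterminate` |

The rule is monotone: lowering the variant-adjusted p-value can never
demote a variant to `tagged_by_lead`.

## 6. The synthetic-data generator

The generator produces data with exactly the structure the analyses
assume — and nothing more. What it emulates, and its defaults:

* **Pedigree**: founder couples plus descendants over a set number of
  generations; children per couple are zero-truncated Poisson (mean 2.8 in
  the reference studies) so every couple stays connected — an untruncated
  couple with a married-in spouse would orphan that spouse; children of
  non-final generations marry new unrelated founders. Households are full
  sibships; founders get singleton households. The cohort-scale reference
  pedigree uses 120 founder couples and 2 descendant generations,
  giving $n \approx 2000$, the scale of a genotyped isolate cohort.
* **Genotypes**: founder haplotypes drawn per LD block from a small
  "ladder" pool whose haplotype frequencies reproduce each variant's
  target MAF exactly and induce strong positive within-block $r^2$
  (nested carriers); transmission by gene dropping with free recombination
  between blocks and none within. Target MAFs span 0.02-0.50, the range
  of reported mQTL variants. Coalescent realism is out of scope; the pool
  construction is sufficient to control MAF and $r^2$, which is all the
  downstream methods consume.
* **Phenotypes**: $y = \sum_j \beta_j g_j + a + c + e$ with
  $a \sim N(0, h^2\,2\Phi)$, $c$ shared within household
  ($\mathrm{Var} = c^2$), independent residuals, standardized to unit
  total variance in expectation; each QTL contributes
  $2p(1-p)\beta^2$. Defaults $h^2 = 0.4$, $c^2 = 0.05$ sit in the middle
  of the reported metabolite heritability range (0.10-0.52) and household
  effects (0-0.08). Age ($N(48, 14^2)$ truncated to 18-90 years), a
  BMI-like covariate ($N(26.3, 4.2^2)$), and a medication flag
  (12% prevalence, matching 298/2416) are drawn independently of the
  trait — exclusion is exercised as plumbing, not as confounding.
* **Spectra**: per-sample CPMG and JRES-projection spectra as sums of
  concentration-weighted signature peaks on a 0.5-4.5 ppm axis at
  $10^{-3}$ ppm resolution, with linewidths 0.012 ppm (CPMG) versus
  0.0035 ppm (JRES) and noise levels chosen so the JRES projection is
  relatively noisier — the resolution/SNR trade-off the two-spectrum
  strategy exploits. The 2D JRES experiment itself is not modeled: the
  computation starts at its 1D projection. Acquisition physics, phasing,
  water suppression and chemical-shift referencing are not simulated.

Because the generator satisfies the model assumptions by construction,
passing recovery experiments demonstrate *correctness of the estimators
under their assumed model*, not robustness to real-data pathologies
(non-Gaussian traits, genotyping error, peak-position drift between
samples, baseline artifacts beyond a linear ramp).

## 7. Reference studies and problem sizes

`study_*()` functions run the standard validation experiments; the sizes
below are the package's reference conditions:

* `study_heritability_recovery()`: 10 pedigrees of $n \approx 2000$,
  $h^2 = 0.4$, $c^2 = 0.05$; mean absolute errors of $\hat h^2$ and
  $\hat c^2$ (typically ~0.03 and ~0.025).
* `study_score_calibration()`: one heritable trait ($h^2 = 0.4$) and
  10,000 null variants gene-dropped on a cohort-scale pedigree; type-I
  error at $\alpha = 0.05$, $\lambda$, the inflated naive-OLS comparison,
  and exact OLS-oracle agreement at $K = I$ over 50 variants.
* `study_deconvolution_recovery()`: a noiseless three-peak fixture with
  overlap at $1.5w$ (parameter recovery), and 20 noise replicates at
  signal-to-noise 100 (amplitude recovery).
* `study_endtoend_quantification()`: 30 samples, 5 metabolites, full
  pipeline at signal-to-noise ~50; per-metabolite correlation between
  quantified intensity and true concentration.
* `study_finemap_recovery()`: 100 loci of $n = 2000$, alternating
  causal-plus-tag ($\beta = 0.6$, MAF 0.2, tag $r^2 \approx 0.85$) and
  two-independent-causal ($\beta = 0.4$ each) architectures; fraction
  classified correctly. The causal-and-tag effect sizes are chosen so the
  *conditional* non-centrality ($\propto n(1-r^2)\beta^2$) gives the
  adjusted test comfortable power at $\alpha_{\rm keep}$ — with weaker
  effects the bottleneck is power, not the classifier.
* `study_moi_recovery()`: 100 recessive traits (two-copy carriers shifted
  by 0.7 SD, MAF 0.3, $h^2 = 0.3$ background) on a cohort-scale pedigree;
  fraction of scans in which the recessive coding wins. The shift is
  typical of the large coding-variant effects that motivate recessive
  modeling; at 0.7 SD the recessive coding's non-centrality roughly
  doubles the additive coding's, which is what makes the scan decisive.

All studies derive every replicate seed from one base seed, so each is
reproducible from a single integer.

## 8. Known limitations

* Kinship is pedigree-based; marker-based kinship estimation is not
  implemented.
* Dominance and epistatic variance components, bivariate genetic
  correlations, X-chromosome models, imputation and meta-analysis are out
  of scope.
* The NMR module does not perform library-based metabolite
  identification; peak groups are *candidate* metabolites.
* The conditional classifier assumes a single lead SNP per locus;
  multi-signal stepwise conditioning is not implemented.
* The score test's empirical type-I rate on a single trait realization
  carries the extra trait-level dispersion described in Section 4; studies
  that need tighter control should average over trait draws.
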