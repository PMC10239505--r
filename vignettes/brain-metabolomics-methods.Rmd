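---
title: "Statistical methods for targeted brain metabolomics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for targeted brain metabolomics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurometab)
```

## The analysis problem

Post-mortem brain metabolomics cohorts for Parkinson's disease (PD) pose a
combination of statistical difficulties that no single off-the-shelf tool
covers: samples are assayed on multiple plates with multiplicative batch
effects; many low-abundance analytes hover near the limit of detection;
disease groups (controls, PD cognitively normal, PD with mild cognitive
impairment, PD with dementia) have visibly unequal variances; all PD
subjects are on chronic levodopa medication whose *acute* presence at
death perturbs many metabolites, differently in demented and non-demented
subjects; and brain region coverage is unbalanced by design (no dementia
putamen tissue). `neurometab` implements a complete pipeline for this
setting, together with a synthetic cohort generator that makes every stage
testable by parameter recovery against a known ground truth.

## Plate normalization

Cortex samples are spread over two plates. A plain median normalization
(scale each plate so that its median matches) is biased when the group
composition differs between plates, because the groups themselves differ.
The pipeline instead pre-scales a *copy* of every sample by its own group
median, and uses all of these pre-normalized values as reference samples.
For analyte $m$ with value $x_s$ of sample $s$ in group $g_s$ on plate
$p_s$:

$$r_s = x_s \big/ \operatorname*{median}_{t \,:\, g_t = g_s}(x_t), \qquad
  q_p = \operatorname*{median}_{t \,:\, p_t = p}(r_t) \big/
        \operatorname*{median}_{t}(r_t), \qquad
  y_s = x_s / q_{p_s}.$$

Quality control (QC) replicates participate as their own group, so every
sample on a plate informs its quotient $q_p$. With a single plate
$q \equiv 1$ and the data are untouched. The implementation is pinned to a
literal, loop-based evaluation of these three steps at $10^{-10}$ in the
test suite, and is exactly scale-equivariant.

One property worth stating precisely: a *second* application of the
normalization is not exactly the identity. The references $r$ are
recomputed from the already-normalized values with new group medians, so
the second-pass quotients deviate from 1 by the sampling error of a median
ratio, $O(n^{-1/2})$ — about $10^{-2}$ at this cohort's size. In the
special case of a single reference group the second pass is an exact
global rescale (both plates receive the identical quotient), so the
*relative* plate correction never moves again. The batch correction is
therefore "converged after one pass" in the relevant sense, but users
should not expect machine-precision idempotence.

## Detection limits, zeros, and indicators

The limit of detection (LOD) of an analyte is twice the median signal of
the blank samples. An analyte is dropped only when *every* subject group
has strictly more than 50% of its values below LOD; values below LOD that
survive are kept unadjusted — they remain the best available estimate, and
substituting them would bias group contrasts. Exact zeros (which break the
log-family transforms and are biologically implausible) are replaced by
half the analyte's minimal non-zero value; an all-zero analyte has no
defined replacement and is flagged out.

Metabolic indicators — sums and ratios of measured metabolites serving as
synthesis or enzyme-activity proxies — are computed from pre-normalization
values and then plate-normalized themselves (the default; computing them
from already-normalized metabolites is available via
`indicators_from = "normalized"`, and the two differ only through the
non-linearity of ratios of medians). Ratios with a zero denominator are
treated as missing rather than infinite. An indicator inherits the
flow-injection (FIA) stratum if any constituent analyte is FIA — the
conservative assignment, since FIA measurements are noisier.

## Transformation and standardization

Each analyte is Box-Cox transformed with the exponent $\lambda$ maximizing
the profile log-likelihood over $[-3, 3]$ (one-dimensional smooth
optimization, tolerance $10^{-4}$; no shift parameter is needed because
zero interpolation guarantees positivity). Remote outliers are then
*adjusted to* the Tukey fences $Q_1 - k\,\mathrm{IQR}$ and
$Q_3 + k\,\mathrm{IQR}$ with $k = 3$ rather than removed: this caps the
influence of extreme values on group means without the variance loss of
outright removal. Finally values are standardized to the control samples
of the same brain region, so that every regression coefficient downstream
is expressed in units of one control standard deviation.

The stage order — quantify, LOD filter, zero interpolation, indicators,
plate normalization, Box-Cox, Tukey fencing, standardization — is fixed in
`preprocess()`; later stages assume guarantees of earlier ones (Box-Cox
needs positivity, fencing operates on the transformed scale where the
quartile geometry is meaningful, standardization defines the coefficient
units). Both brain regions are processed completely separately: group
medians, control quantiles, and standardization statistics are all
within-region, matching the separate per-region model families.

All quantiles in the package (Tukey quartiles, the DOPA threshold below)
use linear interpolation between order statistics (type 7), the common
default; the choice is configurable and documented here because no
external convention pins it.

## Acute levodopa classification

All PD subjects took levodopa chronically; whether the drug was *acutely*
present at death is inferred from the brain DOPA level. Per region, the
physiological threshold is the 95% quantile of the controls' normalized
(pre-standardization) DOPA values; a PD sample is L+ when its DOPA
strictly exceeds the threshold, with ties going to L−. Because Box-Cox is
monotone increasing, classifying on normalized rather than fully
transformed values is equivalent. With $n$ controls the interpolated
threshold leaves at most $\lceil 0.05\,n \rceil$ controls above it — for
35 controls that is 2 of 35, i.e. 5.7%, slightly above the nominal 5%;
this is a property of any finite-sample quantile, not of the
implementation.

## The heteroscedastic linear model

The working model, `hetlm()`, is a multivariable linear regression fitted
by iterative feasible generalized least squares without assuming equal
residual variance across subject groups: ordinary least squares residuals
give per-group variance estimates, weighted least squares with weights
$1/\hat\sigma^2_g$ refits, and the steps iterate to a scaled coefficient
change below $10^{-8}$ (at most 50 iterations; a fit that is still moving
is flagged, reported, and carried with its last iterate — near-degenerate
small-group variances occasionally produce slow geometric convergence).

Two inferential choices matter and were validated by simulation at the
cohort's exact group sizes (36/14/19/32):

* **Variance degrees of freedom.** The per-group denominators are
  $n_g - \mathrm{tr}(H)_g$, the group size minus the summed weighted-fit
  leverages of the group's rows. Group indicators and interaction terms
  consume their leverage *inside* their own group, so a proportional
  allocation of the model degrees of freedom under-corrects precisely for
  the small groups and makes the levodopa-interaction tests
  anticonservative (near 0.10 at nominal 0.05 in our null simulations,
  versus 0.05–0.08 with the leverage charge).
* **Reference distribution.** Wald $t$ statistics use per-coefficient
  Satterthwaite degrees of freedom — each coefficient's variance is a
  known weighted sum of the group variance estimates, and the weights give
  the effective df. A global $n - p$ reference (available as
  `df_method = "residual"`, as is the normal approximation) is too light-
  tailed for coefficients that lean on a 14-subject variance group.

Confidence intervals use the same df. The model object carries the usual
accessors (`coef`, `vcov`, `confint`, `summary`, `predict`, `residuals`,
`simulate`), and `wald_test()` provides the joint heteroscedastic ANOVA
used by the cohort characteristics table.

## Differential and progression analyses

`run_differential()` fits one model per analysis-ready analyte and region:
group indicators (each PD cognitive group against controls, or one all-PD
indicator), acute levodopa presence separately in non-demented and
demented PD (the interaction whose omission can mask medication effects),
and the fixed covariates — age, sex, education, BMI, four comorbidity
flags, and log-transformed post-mortem collection interval and freezer
storage time (logs capture time-related exponential decay). Putamen models
structurally lack the dementia rows and term. Coefficients are in control-
SD units.

`run_progression()` replaces the group and levodopa terms with a PD
indicator plus one regressor per progression score (disease duration,
motor score, Lewy body stage, cognitive screening, plaque and tangle
densities), equal to the PD-standardized score for PD subjects and zero
for controls: controls sharpen the covariate estimates without
contributing to the score effect. The reported coefficient is therefore
*two-way standardized* — control SDs of the analyte per PD-SD of the score
— and exactly invariant to affine rescaling of the raw score. PD subjects
missing a score are dropped from that score's models only, so each
coefficient uses the maximal available sample.

Missing BMI and education are imputed by the mean conditional on group and
sex (falling back to group, then overall, each logged); no other field is
ever imputed, and analyte values are never imputed beyond the zero rule.

## False discovery rate control

Each coefficient family (each group term, each levodopa term, each score)
is FDR-controlled separately with Storey q-values, stratified by the four
disjoint assay strata {LC, FIA} x {measured, calculated} — the arms differ
in precision and in effective test count, and pooling them would let the
well-behaved stratum set the threshold for the noisy one. $\hat\pi_0$
comes from spline-smoothing $\hat\pi_0(\lambda)$ over
$\lambda = 0.05, \dots, 0.95$ (df 3, evaluated at 0.95, clipped to
$(0,1]$); with fewer than 20 tests in a stratum $\hat\pi_0$ is fixed at 1,
making the procedure exactly Benjamini-Hochberg there — an identity the
test suite pins. Significance is declared at $q \le 0.05$.

## Metabolite-set enrichment

Pathway-level analysis follows the covariate-adjusted set enrichment idea:
because the inputs are the *p-values of the main regression models*, the
covariates are already accounted for, which standard over-representation
tools cannot do. Measured analytes map into every set containing any of
their possible isoforms (many-to-many), a custom microbial-metabolite set
can be appended, and sets with fewer than 4 mapped members are dropped.
Each set's member p-values are tested against uniformity with the
one-sided Kolmogorov-Smirnov statistic $D^+ = \max_i (i/n - p_{(i)})$
(right-continuous empirical CDF, so ties resolve to the largest index).
The tail probability uses the exact Birnbaum-Tingey formula for
$n \le 10$ and the asymptotic $\exp(-2 n D^{+2})$ above; the two agree
within 15% relative near the null mode for $n \ge 50$, and the null
rejection rate at 0.05 is calibrated to $[0.03, 0.07]$ in the acceptance
suite. Set results carry the mean absolute member coefficient as an effect
size and are themselves FDR-controlled with q-values.

## Dementia discrimination

`auc_delong()` computes the area under the ROC curve as the Mann-Whitney
probability (ties half-credited) with DeLong's placement-value variance,
orientation-corrected to AUC >= 0.5 and with the 95% CI clipped to
[0, 1]. `best_discriminator()` ranks analytes by AUC for demented versus
non-demented PD (mild cognitive impairment counts as non-demented) in
three strata — all PD, L+ only, L− only — because a discriminator that
works through a levodopa interaction is visible only within a medication
stratum. Ties in AUC break by narrower CI, then analyte id.

## The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes:
group sizes 36/14/19/32 in cortex and 35/14/19/0 in putamen (no dementia
putamen tissue), two cortex plates with per-analyte log-normal
multiplicative factors (SD 0.15) and stratified plate assignment, QC
replicates per plate, log-normal abundances with per-analyte baseline and
scale, per-group residual-SD multipliers, covariates drawn near the
cohort's characteristics table, and blanks positioned so that the LOD sits
at a configured quantile of each analyte's values (default 0.02 — most
analytes comfortably above detection, as in targeted assays).

Planted effects — group shifts, levodopa-state interactions, covariate and
progression-score slopes — are expressed in control-SD units *on the log
scale*, so that Box-Cox (whose fitted $\lambda$ is then near 0)
linearizes them and downstream recovery is interpretable in the same units
the models report. Acute levodopa status is assigned by a coin flip
independent of the progression scores, mirroring the design assumption
that acute medication presence at death is a random process; the DOPA
marker is drawn 4 control-log-SDs high for L+ subjects, and L− PD
subjects sit 1 SD *below* the control mean — endogenous striatal DOPA is
reduced by nigrostriatal degeneration — which keeps both arms away from
the threshold. Each analyte draws from its own deterministic RNG
sub-stream derived from the cohort seed, so any analyte regenerates
bit-identically without replaying the cohort.

What the generator does *not* emulate: between-analyte correlation
(analytes are independent given the design; real lipid classes are
strongly correlated, so set-enrichment power on real data will differ),
within-plate drift, censoring mechanisms other than a sharp LOD, and
non-log-normal abundance shapes. Passing recovery tests therefore
demonstrate the *estimators'* correctness under the stated generative
assumptions, not robustness to everything real data can do.

## Validation and problem sizes

The acceptance suite (and `scripts/acceptance.R`, which recomputes the
same quantities from scratch at a user-supplied seed) checks: exact
agreement of the plate normalization with a literal evaluation of its
defining steps; type-I error of the dementia contrast within
$[0.035, 0.065]$ at $\alpha = 0.05$ over 1000 null analytes at the
cohort's group sizes with an SD ratio of 2, and exact reduction to OLS
under constrained equal variances; recovery of a planted 1.0 control-SD
effect with bias below 0.1 and CI coverage in $[90\%, 99\%]$ over 200
pipeline replicates (coverage runs near 92% rather than 95%: the control-
SD standardization divisor is itself estimated from 36 controls, adding
multiplicative uncertainty the model SE does not carry); detection of a
planted +2 control-SD levodopa-dementia interaction at $q \le 0.05$, and
first-place AUC ranking of the planted analyte in the L+ stratum, in at
least 90 of 100 replicates; exact Benjamini-Hochberg equivalence and
brute-force agreement of the q-values; KS null calibration over $10^4$
sets; exact brute-force agreement of the AUC; and levodopa classification
agreement with generator truth of at least 95%. Recovery replicates use
6–17 analytes per cohort — the estimators are per-analyte, so analyte
count affects only the FDR strata, and small counts keep the
200-replicate studies fast.

## Known limitations

* Second-pass plate normalization deviates from the identity by median
  sampling error (see above).
* The levodopa-interaction tests remain mildly anticonservative (about
  0.06–0.08 at nominal 0.05) because variance-estimate noise from the
  14- and 19-subject groups is only approximately captured by the
  Satterthwaite reference.
* CI coverage in control-SD units is structurally below nominal (about
  92%) for the reason given above; inference on the *presence* of effects
  (type-I error, FDR) is calibrated.
* Regions are modeled independently; subjects contributing both cortex
  and putamen tissue induce a cross-region dependence the per-region
  models ignore (as does the design they implement).
* The q-value $\hat\pi_0$ smoother is unstable below a few dozen tests;
  the automatic fallback to $\pi_0 = 1$ is conservative.
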