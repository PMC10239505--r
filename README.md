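# neurometab

Statistical analysis of targeted post-mortem brain metabolomics cohorts in
Parkinson's disease (PD), for analysts who need the full path from raw
plate measurements to publishable effect tables: batch correction,
detection-limit handling, per-analyte regression with honest inference
under unequal group variances, acute-levodopa interaction modeling,
progression-score associations, stratified FDR control, covariate-adjusted
metabolite-set enrichment, and AUC-based dementia discrimination. A
synthetic cohort generator with known planted effects makes every stage
verifiable by parameter recovery.

## The statistics at the core

**Group-median plate normalization.** For analyte $m$, sample $s$ in group
$g_s$ on plate $p_s$:

$$r_s = \frac{x_s}{\operatorname{median}_{t \in g_s}(x_t)}, \qquad
  q_p = \frac{\operatorname{median}_{t \in p}(r_t)}
             {\operatorname{median}_t(r_t)}, \qquad
  y_s = \frac{x_s}{q_{p_s}}.$$

Pre-scaling every sample by its group median lets *all* samples (including
QC replicates, as their own group) serve as references for the plate
quotients, so unequal group allocation across plates does not bias the
batch correction.

**Heteroscedastic regression.** Each analyte's standardized values are
modeled as

$$y = \beta_0 + \sum_k \beta_k\,\mathbb{1}[\text{group}_k]
      + \beta_{L^+\!,ND}\,\mathbb{1}[L^+\!, \text{PD-ND}]
      + \beta_{L^+\!,D}\,\mathbb{1}[L^+\!, \text{PD-D}]
      + \gamma' z + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2_{g}),$$

fitted by iterative feasible GLS with per-group variances (leverage-
corrected denominators, Satterthwaite df). Coefficients are in units of
one control SD. $L^+$ (acute levodopa presence) is classified per region
from brain DOPA exceeding the controls' 95% quantile. Two-tailed p-values
are converted to Storey q-values separately within each assay stratum
{LC, FIA} x {measured, calculated}; metabolite sets are tested by the
one-sided Kolmogorov–Smirnov statistic $D^+$ over member p-values against
uniformity; discrimination is summarized by the Mann–Whitney AUC with
DeLong confidence intervals.

## Worked example

Simulate a cohort with a +2 control-SD homocysteine (Hcy) effect planted
in acutely levodopa-positive dementia subjects, run the whole pipeline,
and inspect the Hcy results:

```r
library(neurometab)
cfg <- run_config(seed = 42, out_dir = "run1",
  sim = list(n_analytes_lc = 10, n_analytes_fia = 20,
             levodopa_effects = data.frame(analyte = "Hcy",
                                           pd_class = "PD-D", effect = 2)))
res <- run_pipeline(cfg)

print(res$prep$levodopa)
#> Acute levodopa classification
#>   cortex: threshold 1.686 (95% control quantile); L+ 37 / L- 28
#>   putamen: threshold 1.898 (95% control quantile); L+ 16 / L- 17

subset(res$differential, analyte_id == "Hcy" & region == "cortex",
       select = c(term, beta, ci_low, ci_high, p, q))
#>          term    beta ci_low ci_high        p        q
#> 1   grp_pd_cn  0.1303 -0.757   1.018 7.68e-01 0.929583
#> 2  grp_pd_mci -0.3924 -1.214   0.429 3.42e-01 0.751883
#> 3    grp_pd_d  0.0395 -0.694   0.773 9.15e-01 0.914516
#> 4 ldopa_pd_nd  0.5079 -0.256   1.272 1.85e-01 0.572743
#> 5  ldopa_pd_d  1.7852  0.976   2.595 9.23e-05 0.000508

subset(res$auc, stratum == "L+ only" & rank <= 3)
#>    analyte_id stratum   auc ci_low ci_high n_pos n_neg rank
#> 63        Hcy L+ only 0.899  0.792   1.000    16    21    1
#> 64     FIA001 L+ only 0.702  0.529   0.875    16    21    2
#> 65     FIA011 L+ only 0.667  0.477   0.857    16    21    3
```

Reading the output: the planted levodopa-dementia interaction is recovered
at `ldopa_pd_d` = 1.79 control SDs (95% CI 0.98–2.60, q = 5e-4) while the
null group contrasts stay null; Hcy ranks first for discriminating
dementia among L+ subjects with AUC 0.90. The run directory contains every
stage's CSV plus a JSON manifest (seed, config, hash) that makes the run
bit-reproducible.

Real data enter the same way through `read_analyte_table()`,
`read_sample_meta()`, `read_indicator_defs()` and `read_gmt()`, with
`config$inputs` pointing at the files.

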