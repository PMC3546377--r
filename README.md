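# mvhet — heterogeneity statistics for multivariate meta-analysis

`mvhet` is an R package for meta-analysts who pool several correlated
outcomes per study (for example two clinical endpoints, or sensitivity and
specificity of a diagnostic test) and want to know not only the pooled
effects but *how much between-study heterogeneity matters* for them —
jointly, per outcome, or for any contrast of interest.

## The model and the statistics

Each of *n* studies contributes an estimate vector **Y**ᵢ for the outcomes
it observed, with a known within-study covariance matrix **S**ᵢ. Under the
random-effects model

  **Y**ᵢ ~ N(**μ**, **Σ** + **S**ᵢ),

the between-study covariance **Σ** captures heterogeneity; **Σ** = 0 is the
fixed-effects model. `mvhet` fits both: **Σ** by REML (or ML) over an
unconstrained triangular square-root, the pooled coefficients by GLS,

  **μ̂** = (Σᵢ XᵢᵀVᵢ⁻¹Xᵢ)⁻¹ Σᵢ XᵢᵀVᵢ⁻¹**Y**ᵢ,  Vᵢ = **Σ** + **S**ᵢ,

with missing outcomes handled through each study's observed marginal
distribution, and study-level covariates through per-outcome design blocks
Xᵢ (meta-regression). The covariance of **μ̂** is available in two
conventions: the GLS expression above (`model`) or the inverse observed
Fisher information over *all* parameters (`obsinfo`, the default), which
propagates the uncertainty in **Σ̂**.

The impact of heterogeneity is quantified by comparing the random- and
fixed-effects fits:

- **R** = (det **C**_R / det **C**_F)^(1/2p) — the inflation of the volume
  of the confidence ellipsoid for any p selected coefficients (a subset or
  linear contrast), with **C**_R, **C**_F the two coefficient covariance
  matrices. Univariately this is the ratio of standard errors.
- **I²_R** = (R² − 1)/R² — the proportion of the (geometric-mean) variance
  under random effects that heterogeneity explains.
- **Q_s** = Σᵢ (**Y**ᵢ − **Ŷ**ᵢ)ᵀ**S**ᵢ⁻¹(**Y**ᵢ − **Ŷ**ᵢ) — a scalar
  multivariate Cochran statistic from the fixed-effects residuals, χ²_v
  under homogeneity with v = (total estimates) − (coefficients);
  **H²** = Q_s/v and **I²_H** = (H² − 1)/H².
- per-outcome **I²** statistics: the classical Higgins–Thompson forms
  (Q-based and τ²-based, with the typical within-study variance s²) and the
  analogous ratio Σ̂ⱼⱼ/(Σ̂ⱼⱼ + s²ⱼ) using the multivariate Σ̂.

## Worked example: periodontal therapy

Five trials compare surgical vs non-surgical periodontal treatment on two
outcomes (mm improvement in probing depth and attachment level), with known
within-study covariances. The dataset ships with the package.

```r
library(mvhet)
d <- berkey_periodontal()
re <- reml_fit(d)                 # REML + observed-information covariance
re
#> Multivariate meta-analysis fit (reml, cov = obsinfo)
#>                  estimate     se
#> probing_depth      0.3534 0.0612
#> attachment_level  -0.3392 0.0893
#> Between-study covariance matrix:
#>                  probing_depth attachment_level
#> probing_depth           0.0117           0.0119
#> attachment_level        0.0119           0.0327

heterogeneity_report(d, re)
#> Multivariate heterogeneity report (covariance convention: obsinfo)
#>   Q_s = 128.227 on v = 8 df;  H2 = 16.028;  I2_H = 0.938
#> R / I2_R by selection:
#>         selection   kind p     R  I2_R convention
#>     probing_depth subset 1 2.141 0.782    obsinfo
#>  attachment_level subset 1 4.791 0.956    obsinfo
#>               all subset 2 3.100 0.896    obsinfo
#> Per-outcome univariate statistics:
#>           outcome n tau2_reml tau2_dl       Q  I2_Q I2_tau I2_white s2_typical
#>     probing_depth 5     0.012   0.010  12.821 0.688  0.719    0.717      0.005
#>  attachment_level 5     0.033   0.057 112.081 0.964  0.940    0.939      0.002
```

Surgery improves probing depth by ≈ 0.35 mm but worsens attachment level by
≈ 0.34 mm. Heterogeneity is substantial: the random-effects confidence
interval for probing depth is 2.1× longer than the fixed-effects one
(4.8× for attachment level, 3.1× on average jointly), and over 90% of the
joint variation is attributable to between-study differences.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/mvhet.R het --input inst/extdata/berkey1998.csv --format wide
Rscript inst/cli/mvhet.R simulate --config null.yaml --reps 2000 --out cal.json
```

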