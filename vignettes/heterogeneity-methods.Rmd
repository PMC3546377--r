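---
title: "Quantifying heterogeneity in multivariate meta-analysis with mvhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heterogeneity in multivariate meta-analysis with mvhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvhet)
```

## The model

A multivariate meta-analysis pools $n$ studies that each report estimates
of up to $p$ outcomes. Study $i$ contributes an observed subvector
$\mathbf{Y}_i$ (length $k_i$) together with its within-study covariance
matrix $\mathbf{S}_i$, estimated inside the study but treated as fixed and
known when pooling — the standard convention, which makes the
fixed-effects coefficient covariance a deterministic function of the data.
The random-effects model places the true study effects around a common
mean:

$$\boldsymbol\theta_i \sim N(\boldsymbol\mu, \boldsymbol\Sigma), \qquad
  \mathbf{Y}_i \mid \boldsymbol\theta_i \sim
  N(P_i\boldsymbol\theta_i, \mathbf{S}_i),$$

so that marginally $\mathbf{Y}_i \sim N(P_i\boldsymbol\mu,\;
P_i\boldsymbol\Sigma P_i^\top + \mathbf{S}_i)$, where $P_i$ selects the
outcomes study $i$ observed. Missing outcomes are represented by absence —
the study simply enters through its observed marginal — rather than by the
alternative device of inflating notional within-study variances; both are
valid, but the marginal form is exact and numerically stable. Missingness
is assumed (and, in the generator, simulated) completely at random.
Setting $\boldsymbol\Sigma = 0$ gives the fixed-effects model. With
study-level covariates, $P_i\boldsymbol\mu$ generalises to $X_i\beta$ with
per-outcome intercepts and covariate effects; all machinery below treats
the two cases identically.

## Estimation

Coefficients are estimated by generalised least squares at a given
$\boldsymbol\Sigma$; $\boldsymbol\Sigma$ itself is estimated by REML
(default) or ML. Numerical choices that matter:

* **Parameterisation.** $\boldsymbol\Sigma = LL^\top$ with $L$ lower
  triangular and *unconstrained* entries. The positive-semidefinite
  boundary is attainable: diagonal entries of $L$ may pass through zero,
  so singular $\hat{\boldsymbol\Sigma}$ and between-study correlations of
  $\pm 1$ — which occur in real datasets — are regular points of the
  search space. Structured alternatives (`diagonal`, `scaled_identity`)
  use the same square-root device.
* **Optimiser.** Nelder–Mead followed by a BFGS polish (Brent in one
  dimension), from two starting points (a DerSimonian–Laird moment start
  and a shrunken copy), keeping the lower objective; relative objective
  tolerance $10^{-10}$, 500 iterations per polish stage. Derivative-free
  first, quasi-Newton second: robustness matters more than speed at the
  small parameter counts involved. Pathological parameter values return a
  large penalty ($10^{10}$) instead of failing, so the optimiser can
  traverse them. Non-convergence is flagged, warned about, and excluded
  from simulation summaries — never silent.
* **Coefficient covariance.** Two conventions are provided.
  `model` is the GLS expression
  $(\sum_i X_i^\top V_i^{-1} X_i)^{-1}$ with
  $V_i = P_i\hat{\boldsymbol\Sigma}P_i^\top + \mathbf{S}_i$ held fixed.
  `obsinfo` (default) inverts the observed Fisher information of the
  *unrestricted* likelihood in all parameters — coefficients and
  covariance parameters jointly — at the fitted values, by central-difference
  Hessian (step $\max(10^{-5}, 10^{-4}|\theta|)$ per parameter). The
  finite-sample cross-information between the two blocks makes `obsinfo`
  standard errors larger than `model` ones; on the periodontal data they
  match the published two-decimal values (0.061, 0.089), which is the
  accuracy one should expect of a numerical Hessian — agreement to about
  two decimals, not bit-exactness. When there are no variance parameters
  (fixed-effects fit) the two conventions coincide exactly.

## The heterogeneity statistics

Let $\mathbf{C}_R$ and $\mathbf{C}_F$ be the coefficient covariance
matrices under the random- and fixed-effects fits. For any $p$ selected
coefficients (submatrices $D_R, D_F$; for a contrast $A\beta$, the
transforms $ACA^\top$):

$$R = \left(\frac{\det D_R}{\det D_F}\right)^{1/(2p)}, \qquad
  I^2_R = \max\!\left(0, \frac{R^2 - 1}{R^2}\right).$$

$R$ is the factor by which the volume of the $p$-dimensional confidence
ellipsoid inflates when heterogeneity is acknowledged — equivalently the
geometric mean of the per-axis interval inflations in the principal-axis
frame. Determinants are computed as log-determinant differences via
Cholesky factorisation of each submatrix, never by cofactor expansion, for
stability when $\mathbf{C}$ is near-singular. If the `model` convention is
used for both fits, $R \ge 1$ for every subset (the GLS covariance at a
PSD $\boldsymbol\Sigma$ dominates the fixed-effects one), so no truncation
occurs; under `obsinfo` — the convention used for reported results, since
it reflects the full model fit — truncation of $I^2_R$ at zero is applied
where needed and is rare. Full-dimension $R$ is invariant under any
invertible linear reparameterisation of the outcomes, since the Jacobian
determinants cancel.

From the fixed-effects residuals alone:

$$Q_s = \sum_i (\mathbf{Y}_i - X_i\hat\beta_F)^\top \mathbf{S}_i^{-1}
       (\mathbf{Y}_i - X_i\hat\beta_F), \qquad
  H^2 = Q_s / v, \qquad I^2_H = \max(0, (H^2-1)/H^2),$$

with $v$ = (number of univariate estimates) − (number of coefficients);
with missing outcomes each study contributes its observed block and $v$
counts observed estimates only. $Q_s$ is $\chi^2_v$ under homogeneity and
reduces to Cochran's $Q$ univariately, as $H^2$ and $I^2_H$ reduce to
their classical forms. Because the sampling behaviour of $Q_s$ restricted
to outcome subsets is not well characterised, $H^2$/$I^2_H$ are reported
for the full coefficient set only, while $R$/$I^2_R$ serve subsets and
contrasts.

Per outcome, the report gives both classical univariate $I^2$ flavours —
the $Q$-based $\max(0,(H^2_u-1)/H^2_u)$ and the variance-based
$\hat\tau^2/(\hat\tau^2 + s^2)$ with $s^2 = (n-1)\sum w_j /
((\sum w_j)^2 - \sum w_j^2)$ the typical within-study variance — plus the
analogous ratio $\hat\Sigma_{jj}/(\hat\Sigma_{jj} + s^2_j)$ built from the
*multivariate* $\hat{\boldsymbol\Sigma}$. The two $\tau^2$-based columns
are labelled separately (`I2_tau`, `I2_white`) because they answer
different questions (univariate vs multivariate fit); the $Q$-based column
(`I2_Q`) is also exposed since the two conventions can differ noticeably
(0.69 vs 0.72 on the periodontal first outcome). For the multivariate
per-outcome ratio, $s^2_j$ is computed over the studies observing outcome
$j$; with complete data this is the standard choice, and with incomplete
data it is a documented convention of this package (the original
formulation ties $s^2$ to coefficients of multivariate estimating
equations that admit more than one implementation).

Users who construct random-effects intervals with $t$ rather than normal
quantiles can scale $R$ by $t_{v,\alpha}/z_\alpha$ (`t_scaled_R`).

## The synthetic-data generator

`simulation_spec()`/`simulate_dataset()` draw datasets from exactly the
two-stage model above: per-study within-study variances uniform on a
range (default $[0.01, 0.05]$, a realistic spread of study precisions for
continuous outcomes on the scale of the worked example), a common
within-study correlation, true effects from $N(\mu, \Sigma)$, and MCAR
masking per outcome. Within-study covariances are drawn once and then
treated as known, mirroring the estimation assumption. Draws that leave a
study with no outcomes or an outcome with fewer than two observing studies
are rejected and redrawn. What the generator deliberately does *not*
emulate: estimated (noisy) within-study covariances, informative
missingness, small-study effects or publication bias. Passing calibration
and recovery tests therefore validates the estimators under the model's
own assumptions — not robustness to their violation in real data.

Default study-condition sizes used by the test suite: null calibration of
$Q_s$ with $p = 2$, $n = 10$, 2000 replicates (mean within
$3\sqrt{2v/N}$ of $v$, 95th-percentile exceedance within 3 binomial SEs
of 0.05); REML parameter recovery with $n = 200$, 200 replicates (bias of
$\hat\mu$ within 3 Monte-Carlo SEs of zero). These run in seconds thanks
to a vectorised closed-form likelihood path for complete bivariate
intercept-only data; the generic path handles every other case.

## Degenerate inputs and tie-breaks

Rank-deficient designs (e.g. a constant-zero covariate) are detected by QR
factorisation of the stacked design and reported as errors, never silently
dropped. A saturated mean model ($v < 1$) is refused. An outcome observed
by fewer than two studies yields `NA` for its per-outcome statistics
rather than an error. Negative moment estimates of $\tau^2$ are truncated
at zero. When restarts reach different optima, the lowest objective wins;
ties within tolerance prefer the interior solution.

## Limitations

Confidence intervals for the heterogeneity statistics are not provided
(bootstrap would be the natural route); the statistics are descriptive.
Shared-coefficient constraints across outcomes, Bayesian estimation, and
borrowing-of-strength summaries are out of scope. The observed-information
covariance relies on a numerical Hessian, so standard errors inherit
$\sim 10^{-4}$ relative noise; for exactly reproducible covariances use
`cov_method = "model"`.
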