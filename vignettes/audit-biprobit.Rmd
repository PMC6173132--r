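---
title: "Auditing paired-organ visualisation with a random-effects bivariate probit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing paired-organ visualisation with a random-effects bivariate probit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ultrasound screening programmes monitor sonographers partly through their
self-reported ovary visualisation rate (VR): the share of examinations in
which they report having seen the ovaries. Self-reports can be audited by
having experts re-review the stored scan images and judge, per examination,
whether the left ovary (LO) and the right ovary (RO) were correctly
identified. `ovaudit` implements the statistical machinery for such audits:
a bivariate probit model with correlated scan-level random intercepts, its
post-estimation quantities (population-averaged margins, joint "both ovaries
confirmed" probabilities, intraclass and tetrachoric correlations, empirical
Bayes effects), a synthetic data generator that emulates the audit design,
and a pipeline that turns a long-format review file into report tables.

The design it targets — the one used for the UKCTOCS sonographer audit — has
seven audited sonographers (A–G) with 51 scans sampled from each (357
scans), and eight expert reviewers split into review groups of sizes 3/3/2.
Each group reviews 119 scans, every expert in a group reviews all of its
scans, so each expert sees 17 scans per sonographer and each scan is judged
by two or three experts. A review may record only one ovary's outcome; rows
with neither outcome carry no information and are dropped.

## The model

For scan $i$ reviewed by expert $j$, two binary outcomes $y^{L}_{ij}$,
$y^{R}_{ij}$ arise from latent variables

$$
y^{L*}_{ij} = x_{ij}'\beta^{L} + b^{L}_i + \varepsilon^{L}_{ij}, \qquad
y^{R*}_{ij} = x_{ij}'\beta^{R} + b^{R}_i + \varepsilon^{R}_{ij},
$$

with $y = 1$ iff $y^* > 0$. The covariates are categorical: sonographer and
either expert, expert qualification (gynaecologist / radiologist /
sonographer; experts are fully nested in qualification so the two cannot be
included together), or neither — the three `variant`s of `model_spec()`. The
scan intercepts $(b^L_i, b^R_i)$ are bivariate normal with free covariance
$\Sigma_b = [\sigma^2_L, \sigma_{LR}; \sigma_{LR}, \sigma^2_R]$, shared by
all reviews of scan $i$; the errors are standard bivariate normal with free
correlation $\rho_e$ within a review and independent across reviews. Both
covariances matter: $\Sigma_b$ captures that experts agree more on the same
scan than across scans, $\rho_e$ that a reviewer who confirms one ovary
tends to confirm the other.

A review with both outcomes observed contributes
$\Phi_2(s_L \eta_L, s_R \eta_R;\; s_L s_R \rho_e)$ given $(b_L, b_R)$, where
$s = 2y - 1$ and $\eta$ is the linear predictor including the intercepts; a
single-outcome review contributes the univariate $\Phi(s\,\eta)$. The scan's
marginal likelihood integrates the product of its review terms over the
bivariate normal intercepts.

## Estimation choices

**Quadrature.** The integral is evaluated by tensor-product Gauss–Hermite
quadrature after the Cholesky substitution $b = \sqrt{2} L z$, with 12 nodes
per dimension by default. At the variance scales these audits produce
($\sigma^2 \approx 0.7$–$1.3$) and with at most three reviews per scan the
integrand is close to a recentred Gaussian and the non-adaptive rule is
already converged: doubling 12 → 24 nodes moves the full-data log-likelihood
by less than $10^{-4}$ relative (asserted in the tests, together with a
brute-force Monte-Carlo oracle on toy data). The non-adaptive rule also
admits an exact analytic gradient, which dominates both speed and the
quality of the numerically differentiated observed information. An adaptive
rule (`adaptive = TRUE`) that recentres the grid per scan at the mode of the
integrand with curvature rescaling is provided for verification and for
data with larger variances; it is value-only (finite-difference gradients)
and therefore slower, which is why the non-adaptive rule is the default.

**Bivariate normal CDF.** $\Phi_2$ uses the Drezner–Wesolowsky/Genz scheme:
Gauss–Legendre quadrature on the $\operatorname{asin}(\rho)$ integral for
$|\rho| < 0.925$ and the high-correlation expansion beyond, with absolute
error near machine precision (checked against an independent implementation
and against $\Phi_2(0,0;\rho) = 1/4 + \operatorname{asin}(\rho)/2\pi$ to
$10^{-10}$). Inside the likelihood the quadrature table for the only two
correlations that occur ($\pm\rho_e$) is precomputed once per evaluation.

**Parameterisation.** The optimiser works on an unconstrained vector:
$\beta^L$, $\beta^R$, the log-Cholesky factor of $\Sigma_b$ (log diagonal,
free off-diagonal) and $\operatorname{atanh} \rho_e$. Every unconstrained
point maps to a positive semi-definite $\Sigma_b$ and $|\rho_e| < 1$, so the
search needs no constraints and reported Table-style quantities are always
valid. Starting values are univariate probit fits per equation,
$\Sigma_b = 0.5 I$, $\rho_e = 0$.

**Convergence and uncertainty.** `nlminb` with relative log-likelihood
tolerance $10^{-8}$ and at most 500 iterations; the fit records
`converged = FALSE` rather than throwing. The covariance of the estimates is
the inverse observed information, obtained by finite differences of the
analytic gradient. Confidence intervals for variance components,
correlations, ICCs and predicted probabilities are symmetric on the natural
scale via the delta method (the audit's published tables print symmetric
natural-scale intervals; a transformed-scale alternative would not match
them). Joint hypotheses use Wald chi-square tests on the natural scale,
including cross-equation (LO vs RO) block equality.

**Degenerate inputs.** Factor levels absent from the data are dropped with a
warning; a level whose observed outcomes are all 0 or all 1 triggers a
separation warning naming the level; a rank-deficient design is an error
listing the aliased columns; scans with conflicting sonographer labels are
rejected rather than silently resolved.

## Post-estimation

Population-averaged margins use the probit-normal identity
$\int \Phi(\eta + b)\,\phi(b;\sigma^2)\,db = \Phi(\eta / \sqrt{1+\sigma^2})$
(no numerical integration; equivalence to a 50-node quadrature is asserted
in the tests), averaged over the estimation sample. For a factor level the
level is forced for every record and other covariates stay as observed —
the convention of Stata's `margins`, chosen because the audit design is
nearly balanced so predictions then sit next to the raw proportions. With
`average = "stratum"` the average is instead taken over the records observed
at that level, the convention under which share-weighted stratum margins
reproduce the overall margin exactly; the two differ only through design
imbalance.

The joint probability that both ovaries are confirmed is
$\Phi_2\!\big(\eta_L/\sqrt{1+\sigma^2_L},\; \eta_R/\sqrt{1+\sigma^2_R};\;
\rho^*\big)$ with
$\rho^* = (\sigma_{LR} + \rho_e)\big/\sqrt{(1+\sigma^2_L)(1+\sigma^2_R)}$ —
the combined latent (tetrachoric) correlation of the LO/RO pair for one scan
and occasion. `latent_correlations()` exposes the formula family:
$\rho^*$, the random-effect correlation
$\sigma_{LR}/\sqrt{\sigma^2_L \sigma^2_R}$ (undefined, reported `NA`, when a
variance is zero) and the ICCs $\sigma^2/(\sigma^2+1)$, the share of latent
variance attributable to the scan. ICCs from the no-expert variant measure
inter-rater agreement after removing each expert's general propensity to
confirm.

Empirical Bayes means $E[b \mid y]$ are posterior expectations under the
fitted parameters, by the same quadrature. `tetrachoric()` gives the 2×2
maximum-likelihood latent correlation (thresholds at the margin quantiles;
a zero cell puts the estimate on the boundary ±1 with a warning), and
`standard_biprobit()` the no-random-effects model whose single latent
correlation is the fixed-effects-adjusted counterpart of the raw
tetrachoric.

## The synthetic generator

`generate_audit_dataset()` simulates exactly the model above on a
configurable layout; `nominal_study_design()` is the audit layout (7×51
scans, groups 3/3/2 randomised within sonographer so every expert sees 17
scans per sonographer). Default truth (`study_parameters()`) is the fitted
values from the motivating audit, reference-coded against sonographer A and
expert 1. Missingness is per-outcome, completely at random, at rates 12/952
(LO) and 21/952 (RO) chosen to mimic the observed assessment counts (≈940 LO
and ≈931 RO assessments per 952 reviews); the audit did not report a
missingness mechanism, so MCAR is an assumption. Volunteer-level repeats (a
handful of women contributed two exams) are not simulated — the model's
intercepts are per scan, so the duplication does not enter the likelihood.
Real data may depart from all of this (reviewer drift over time, informative
missingness, image-quality covariates), so passing recovery tests show the
estimator works under the model's own assumptions, not that the model is
true.

## Validation scale and determinism

The test-suite problem sizes are chosen to give informative checks at
interactive runtimes: the coverage study uses 100 replicates of the full
357-scan design at 12 quadrature nodes (Wald 95% intervals for every
variance/correlation parameter must cover in 88–99% of replicates);
consistency is checked on 8 replicates of a ~5000-scan design (mean estimate
within 10% of truth; the Monte-Carlo error of that mean is about 2–7% per
parameter, so the check probes bias, not noise); delta-method standard
errors are compared against a
100-replicate cluster bootstrap of a 175-scan design. Recovery fits start at
the generating values — the maximiser is unchanged, the search is just
shorter. All simulation is seed-deterministic: the generator restores the
caller's RNG state, replicate $i$ of a study uses seed $\text{seed}+i$ (so
studies are resumable), and identical seeds give byte-identical datasets and
pipeline CSVs.

## Known limitations

* Two outcome equations only; no third organ or ordinal confidence scores.
* No Bayesian estimation and no GEE alternative.
* The adaptive rule lacks an analytic gradient and is impractical for large
  refits; it is a verification tool here.
* Delta-method intervals for variance components are symmetric and can cross
  zero in small samples; profile-likelihood intervals are not implemented.
* The audit's "15 ineligible reviews" exclusion rule is upstream data
  cleaning and is not modelled; rows with both outcomes missing are simply
  dropped and counted.

## A worked run

```{r}
library(ovaudit)

cfg <- run_config(synthetic = TRUE, seed = 7, out_dir = "audit-run")
res <- run_audit(cfg)

fit <- res$fits$expert
fit
correlation_summary(fit)
joint_marginal_prediction(fit)          # the "both ovaries confirmed" rate
head(margins_table(fit))

# validation study at the audit's scale
rec <- run_recovery_study(n_replicates = 100, seed = 1)
rec[rec$parameter %in% c("var_left", "var_right", "cov_lr", "rho_err"), ]
```
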