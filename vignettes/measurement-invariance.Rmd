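---
title: "Multi-group CFA and measurement invariance with mgcfa: models, decisions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-group CFA and measurement invariance with mgcfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the model, the identification and decision rules, the
synthetic-data calibration, and every numerical choice a maintainer might
want to second-guess. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The model

For `p` observed items and `m` factors, each group `g` follows a
mean-and-covariance structure CFA with simple structure (each item loads
on exactly one factor):

$$\Sigma_g = \Lambda_g \Phi_g \Lambda_g' + \mathrm{diag}(\Theta_g),
  \qquad \mu_g = \nu_g + \Lambda_g \kappa_g .$$

With the optional second-order layer the first-order factor covariance is
structured as $\Phi = \Gamma \phi_2 \Gamma' + \mathrm{diag}(D)$. Items are
treated as continuous and multivariate-normal working assumptions are
used; this mirrors the common practice of running ML on 4-point Likert
scores, and is an acknowledged approximation (see Limitations).

Estimation minimizes the multi-group ML discrepancy over per-group
summary statistics $(S_g, \bar x_g, n_g)$:

$$F = \sum_g w_g F_g, \quad w_g = \frac{n_g - 1}{N - G}, \quad
  F_g = \ln|\Sigma_g| + \mathrm{tr}(S_g \Sigma_g^{-1}) - \ln|S_g| - p
        + (\bar x_g - \mu_g)' \Sigma_g^{-1} (\bar x_g - \mu_g),$$

with $\chi^2$ statistic $T = (N - G)\,F$. **Convention warning:** SEM
programs differ in whether they use $n$ or $n-1$ weights and in the
"minimum fit function" versus "normal theory" chi-square; values of `T`
from different software on the same data can differ by fractions of a
percent to a few percent. Degrees of freedom, by contrast, are
convention-free, which is why the test suite pins the df ladder exactly
but treats chi-square-derived indices only through deltas and decision
rules.

## Identification and the anchor policy

*Latent scale.* Marker-variable scaling: the first item listed for each
factor has its loading fixed to 1 (for the CES-D four-factor model:
Bothered, Blues, Good, Unfriendly). An alternative `"variance"`
identification (factor variances fixed to 1, all loadings free) is
available for single-group/configural fits; both give identical df, which
the tests verify.

*Latent means.* Factor means are fixed to 0 in every group below the
scalar level (the intercepts absorb all mean information). At scalar and
above, the reference group's means stay fixed at 0 and the other groups'
are free; the df arithmetic of the scalar step is therefore
$\Delta df = p - m$ relative to metric (20 intercepts equated minus 4
means freed).

*Anchors.* Marker loadings are fixed parameters and can never be released
from cross-group equality — there is nothing to release. For intercepts
the actual identification requirement is weaker than "never touch the
marker": the non-reference factor means are identified as long as **at
least one intercept per factor remains equated**. The package therefore
allows releasing any intercept, including a marker item's, and only
refuses to empty a factor's equated-intercept set. This matters in
practice: in the CES-D calibration the non-invariant intercepts are
`Failure` and `Good`, and `Good` *is* the positive-affect marker. A
policy that protected marker intercepts could never reproduce the
published partial-scalar model (df 358).

*Second order.* The second-order layer is identified by fixing the
second-order factor variance to 1 with all four second-order loadings and
all four disturbances free. For a single group this gives df = 166 for
the 20-item model. Published tables sometimes print 167 for this model;
that count corresponds to some additional fixed parameter that the
original software's setup does not state, so the package documents its
own convention and does not chase the printed value.

## The invariance ladder and its decisions

`run_invariance()` fits configural, metric, scalar and uniqueness models
in order. Each step after the first is compared against the previous
*accepted* (possibly partial) model:

* $\Delta\chi^2 = T_r - T_f$ and $\Delta df$ (reported with a p value,
  but **never** used for decisions — with thousands of respondents the
  chi-square difference is essentially always significant);
* $\Delta\mathrm{CFI} = \mathrm{CFI}_f - \mathrm{CFI}_r$ and
  $\Delta\mathrm{RMSEA} = \mathrm{RMSEA}_r - \mathrm{RMSEA}_f$, accepted
  when $\Delta\mathrm{CFI} < 0.01$ **and** $\Delta\mathrm{RMSEA} < 0.015$
  (both cutoffs configurable; `require_both = FALSE` switches to
  either-suffices).

The configural step has no parent and is judged on absolute fit
(CFI ≥ 0.90, RMSEA ≤ 0.08). A rejected step triggers the partial search;
a step that stays rejected ends the ladder.

*Partial search.* Exact refits, not modification-index approximations:
for every currently-equated parameter of the failing class the model is
refit with that single constraint released (warm-started from the failing
fit), the release with the largest chi-square gain is made permanent, and
the loop repeats until the deltas against the previous accepted model
satisfy the cutoffs or candidates run out. Models of this size refit in
~0.1 s, so the exact search is affordable and fully reproducible; ties in
the gain are broken by battery item order and the whole candidate trail
is stored in the report. Exemptions accumulate down the ladder, and items
whose intercepts were released at the scalar level are also exempted from
uniqueness equality at the next rung (their uniquenesses were estimated
freely per group in the calibration source as well; this inheritance is
what produces the 376/373 df models).

## Fit indices

* `RMSEA` uses the multi-group $\sqrt{G}$ convention,
  $\sqrt{G}\sqrt{\max(T - df, 0)/(df\,(N-G))}$, switchable via
  `group_multiplier`; the 90% CI inverts the noncentral chi-square tail
  conditions $P(\chi^2_{df,\lambda} \le T) = 0.95$ (lower) and $0.05$
  (upper) by root-finding on `pchisq`, with bounds clamped at 0.
* `CFI` uses the guarded incremental definition
  $1 - \max(T-df,0)/\max(T_b-df_b,\,T-df,\,0)$ against the per-group
  independence baseline with free means and variances, whose solution is
  closed-form: $T_b = \sum_g (n_g-1)(-\ln|R_g|)$, $df_b = G\,p(p-1)/2$.
* `NNFI` is reported unclipped (it may exceed 1) and is flagged undefined
  when the baseline is no worse than saturated.
* `AIC = T + 2q`. AIC columns in published tables often follow
  program-specific conventions that cannot be reconstructed from the
  printed chi-squares; AIC is therefore used only for *ranking* models on
  the same data, where any affine convention agrees.

## Latent means, Hancock's d, omega

After (partial) scalar invariance, the non-reference factor means
$\hat\kappa$ are estimated directly; standard errors come from the
inverse Hessian (below) and the test statistic is reported as a
large-sample z (the calibration sample sizes are in the thousands, where
z and t are indistinguishable). The effect size is Hancock's d with the
model-estimated latent SDs $\sqrt{\Phi_{jj}}$ per group and
$(n-1)$-weighted pooling — the weighting is not cosmetic: the published
worked values (−0.589, −0.506, −0.361, −0.650) reproduce to ±0.001 under
$(n-1)$ weights and do not under unweighted pooling. McDonald's omega is
computed per factor per group as $(\Sigma\lambda)^2\phi /
((\Sigma\lambda)^2\phi + \Sigma\Theta)$; it is invariant to the latent
scaling convention, which the tests check.

## The synthetic generator: what it emulates, what it does not

`default_cesd_params()` encodes the published two-group calibration:
unstandardized loadings (equal across groups), intercepts (equal except
`Failure` 0.57/0.30 and `Good` 1.54/0.68), uniquenesses (equal except
`Depressed` 0.30/0.13, `Failure` 0.41/0.09, `Fearful` 0.31/0.14, `Good`
1.20/0.72, `Dislike` 0.23/0.08), latent means (0 vs −0.261, −0.259,
−0.125, −0.323) and latent SDs (0.482, 0.570, 0.354, 0.574 vs 0.324,
0.318, 0.329, 0.184), with group sizes 4903 and 1903.

Two generator parameters are *not* published and are package choices:

* **Latent correlations.** The default matrix puts 0.70 between somatic
  complaints and depressive affect, 0.60 between positive affect and
  interpersonal problems, and 0.30–0.35 across those blocks. All pairs
  are positive (items are generated in analysis orientation, i.e. the
  positive-affect items already reversed). The matrix is deliberately
  **not** equicorrelated: a uniform correlation matrix is exactly
  rank-one, which would make the second-order model true with fewer
  parameters and the four-factor model unrecoverable as the best
  structure by AIC. The chosen block pattern keeps the four-factor model
  the identifiable generating truth, consistent with the calibration
  source where the second-order model fit far worse. Configurable via
  `factor_cor`; never to be read as an empirical estimate.
* **Likert thresholds.** With `likert = TRUE` responses are cut at the
  quartiles of each item's implied marginal distribution in the first
  group, mapping to the 1–4 scale. Continuous generation is the default
  because the ML analysis treats items as continuous; discretization
  compresses group differences and uniqueness gaps, which is useful for
  robustness exercises but not for parameter-recovery checks.

Missingness is MCAR at 1% by default (capped at 5%), matching the "< 1%,
inconsequential" situation the pipeline assumes; summaries use
pairwise-available-case means/covariances with the group's row count as
the fit-function n. What the generator does **not** emulate: the ordinal,
bounded, skewed nature of real 4-point item scores (continuous normal
default), non-normal latent distributions, MNAR mechanisms, response
styles, and survey design effects. Passing recovery tests on this
generator therefore shows the estimator and decision machinery are
correct under their own assumptions — not that those assumptions hold for
any real survey.

## Numerical choices

* **Parameterization.** Variances (uniquenesses, factor variances on the
  Phi diagonal, second-order disturbances) are optimized on the log
  scale; loadings, intercepts, factor covariances and means are
  unconstrained. `nlminb` (quasi-Newton with box constraints) does the
  minimization with analytic gradients assembled by the chain rule from
  $\partial F/\partial\Sigma = \Sigma^{-1}(\Sigma - S - dd')\Sigma^{-1}$
  and $\partial F/\partial\mu = -2\Sigma^{-1}d$; the gradient is verified
  against central differences in the test suite.
* **Heywood handling.** Log-scale variances carry a hard floor of 1e-6;
  a variance pinned at the floor is reported in the fit's `heywood`
  diagnostics. No post-hoc constraint juggling.
* **Start values.** Markers 1; other loadings from marker-covariance
  ratios $s_{im}/s_{mm}$; intercepts at observed means; uniquenesses at
  half the observed variances; Phi from marker covariances; means at 0.
  Ladder steps and search refits warm-start from the previous accepted or
  failing fit (shared parameters take weight-averaged values), which is
  what keeps the exact partial search cheap.
* **Convergence.** `rel.tol = 1e-10`, up to 500 iterations; the final
  gradient norm is recorded in the convergence block. Non-PD trial
  covariances return a large objective value and the optimizer backs off.
* **Standard errors.** Central-difference Jacobian of the analytic
  gradient of $(N-G)/2\,F$ at the optimum (cost: 2q gradient
  evaluations), symmetrized, inverted (pseudo-inverse fallback), and
  mapped to the variance scale by the delta method. Whether published
  standard errors used expected or observed information is generally
  unstated, so z statistics are property-tested (an intercept SE in a
  near-saturated model matches $\sqrt{\Sigma_{ii}/n}$) rather than
  matched to any printed value.
* **Degrees of freedom.** The df counter and the estimator are driven by
  the same parameter template, so the analytic ladder
  (164/167/170 single-group; 328/344/360/358/376/373 two-group) and the
  fitted models cannot disagree.

## Problem sizes used in the tests

The test suite exercises the pipeline at the sizes the analysis is about:
parameter and effect-size recovery at the calibration sample sizes
(4903, 1903); planted-shift detection and localization over 100
replicates at (2000, 2000) with ±0.5 intercept shifts on a random item;
null calibration over 200 replicates at (500, 500) requiring < 10% false
rejection per rung. The acceptance script runs reduced replicate counts
(30/60) of the same designs so a full from-scratch reproduction stays
around a minute.

## Known limitations

* **Sampling error vs recovery bands.** The positive-affect marker
  (`Good`) has reliability ≈ 0.10 under the calibration (λ = 1,
  φ = 0.354², Θ = 1.20), so the unstandardized loadings of the other
  positive-affect items carry Monte-Carlo SEs of 0.07–0.09 even at
  n = (4903, 1903). Any fixed-seed recovery band tighter than ~±0.2 for
  those three parameters is a coin flip by construction; the package
  reports the realized maximum errors rather than hiding them.
* **Greedy partial search.** Releasing constraints by largest gain until
  adequacy is a data-driven procedure open to chance capitalization, and
  it stops at adequacy rather than at truth: mild non-invariance can stay
  constrained, and the resulting misspecification is absorbed by
  group-specific parameters (visible in the README example, where the
  still-constrained `Dislike` uniqueness shrinks the Dutch
  interpersonal-factor variance and its omega). Released sets should be
  replicated before being interpreted.
* **Ordinal items as continuous.** No WLSMV/polychoric support; with
  4-point scales the ML-on-continuous treatment attenuates loadings and
  distorts intercept differences, which is exactly why the generator's
  Likert mode is kept out of the recovery checks.
* **Missing data.** Pairwise-available-case only, defensible below ~1%
  missingness; no FIML or multiple imputation.
* No Satorra–Bentler corrections, no bootstrap SEs, no cross-loadings or
  correlated uniquenesses, no alignment-based approximate invariance.
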