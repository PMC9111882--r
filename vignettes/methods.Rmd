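---
title: "Methods: pooling paired-proportion change scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooling paired-proportion change scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drinkshift)
```

## The effect size

Surveys of drinking behaviour during the pandemic typically asked current
drinkers whether their alcohol use increased, decreased, or stayed the
same. Because the "increase" and "decrease" proportions come from the
same respondents, the natural study-level summary is a difference of
paired proportions, the **change score**

$$d = \frac{n_{inc} - n_{dec}}{n},$$

where $n$ is the number of current drinkers, and $n_{inc}$, $n_{dec}$
the numbers reporting increases and decreases. Treating
$(n_{inc}, n_{dec}, n - n_{inc} - n_{dec})$ as one multinomial draw, the
delta method gives the closed-form standard error

$$SE(d) = \frac{1}{n}\sqrt{n_{inc} + n_{dec} -
  \frac{(n_{inc} - n_{dec})^2}{n}},$$

implemented in `change_score()`. A $d$ of $-0.05$ reads as: the share of
drinkers cutting down exceeds the share drinking more by five percentage
points. The same formula applied to starters/stoppers (or, when only
marginal prevalences are available, its proportion-scale analogue
$\sqrt{(p_{during} + p_{before} - d^2)/n}$) yields the before/during
difference in the prevalence of alcohol use (`prevalence_difference()`).
The marginal-prevalence route ignores the before/during covariance and
is therefore flagged `approx = TRUE` wherever it is used; with positive
dependence between waves it overstates the variance, so it is a
conservative substitution.

Two degenerate cases have $SE = 0$: nobody changed, or everybody changed
in the same direction. Inverse-variance machinery cannot use such
estimates; they are excluded from pooling with a warning rather than
silently perturbed, since any continuity correction here would be an
undeclared change of estimand.

## Data preparation

Study tables rarely arrive analysis-ready; `read_studies()` validates a
CSV/TSV against an explicit schema (`study_schema()`) and the
preparation helpers encode three fixed rules:

* **Denominator reconstruction** (`estimate_drinker_n()`): when a study
  reports only its total sample size, the drinker denominator is
  `n_total * prop_drinkers`, further multiplied by the share of
  women/men for gender-stratified rows; when the drinker proportion is
  unknown, the total sample size itself is used. Reconstructed
  denominators are rounded half-up — counts must stay integers for the
  SE formula, and half-up is the least surprising deterministic rule;
  at survey sample sizes the choice of rounding rule moves $d$ by less
  than $10^{-3}$.
* **Starter/stopper folding** (`fold_start_stop()`): respondents who
  started or stopped drinking enlarge the denominator and count as
  increases/decreases respectively. Folding is applied one-sidedly when
  only one of the two counts is reported, and originals are kept in a
  `"prefold"` attribute.
* **Period averaging** (`average_periods()`): monthly waves collapse to
  one record per pandemic period (P1 = March–June 2020,
  P2 = July–September 2020, P3 = October 2020 onward) by unweighted
  averaging of the monthly proportions; a study whose fieldwork spans a
  period boundary is classified by the midpoint of its window
  (`pandemic_period()`), a deterministic rule chosen because fieldwork
  intensity within the window is unknown.

`build_subsets()` then groups general-population records by indicator
(overall use, frequency, quantity, heavy episodic drinking, prevalence
of use) and stratum, and flags a subset eligible for pooling only when
at least five **independent studies** contribute — estimates from the
same study count once toward that gate. Gender-stratified rows of a
study enter the total-sample analysis as separate estimates; this
mirrors common practice in this literature but treats them as
independent, a simplification discussed under limitations.

## The random-effects model

`meta_change()` fits

$$d_i = x_i'\beta + u_i + e_i,\qquad u_i \sim N(0, \tau^2),\quad
  e_i \sim N(0, se_i^2),$$

by weighted least squares with weights $w_i = 1/(se_i^2 + \tau^2)$.
With `d ~ 1` this is the usual random-effects pooled mean; with a
categorical moderator it is a mixed-effects meta-regression.

**$\tau^2$ estimation.** The default is REML, computed by Fisher
scoring on the restricted log-likelihood with step-halving, convergence
tolerance $10^{-8}$ on $\tau^2$, at most 200 iterations, and the
estimate constrained to $[0, \infty)$; if scoring fails to converge the
profile restricted likelihood is maximised by golden-section search,
and in either case the boundary value $\tau^2 = 0$ is accepted whenever
it attains at least the restricted likelihood of the interior
candidate. The DerSimonian–Laird moment estimator (`method = "DL"`) is
kept both for speed and as a cross-check; the two coincide at the
boundary for equal-precision estimates, but under unequal $se_i$ REML
may legitimately return a small positive $\tau^2$ where DL truncates
to zero — the boundary conditions of the two estimators are not
equivalent.

**Inference.** Coefficients carry Wald $z$ statistics and
normal-theory 95% intervals ($\pm 1.959964\,se$); no Knapp–Hartung
adjustment is applied, matching the default behaviour of the standard
meta-analysis software this workflow is meant to interoperate with.
Wald intervals are slightly liberal at small $k$; the simulation below
quantifies the effect at $k = 40$.

**Heterogeneity.** Cochran's $Q$ is the fixed-effect weighted residual
sum of squares, referred to $\chi^2_{k-p}$. $I^2$ is reported in its
$\tau^2$-based form $100\,\tau^2/(\tau^2 + s^2)$ with
$s^2 = (k-p)/\mathrm{tr}(P)$ the typical within-study variance (this
generalises the familiar $(k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$
to moderator models); the $Q$-based form $\max(0, 100(Q - df)/Q)$ is
also returned as `I2_Q`. The two differ noticeably only at small $k$.

**Moderators.** `fit_meta_regression()` fits one moderator at a time —
study timing, age oversampling (at least half the sample ≤ 35 or
≥ 50 years), use of sampling weights, and European sub-region — with
dummy coding against fixed reference levels (P1, general age profile,
unweighted, Western Europe; P1 because the earliest period is the
natural comparison and the best-populated cell, Western because it
contributes the most studies). The omnibus test QM is a Wald chi-square
on the non-intercept coefficients. Because four models interrogate the
same estimates, QM is judged against the Bonferroni-corrected threshold
$\alpha/m = 0.05/4 = 0.0125$ (`bonferroni_alpha()`). Per-level means
are linear combinations of $\hat\beta$ and are invariant to the
reference-level choice.

**Small-study bias.** `egger_test()` regresses $d_i$ on $se_i$ inside
the mixed-effects model, with $\tau^2$ re-estimated under the bias
model (re-estimation, rather than fixing $\tau^2$ from the main fit, is
the internally consistent choice: the bias model changes the mean
structure and hence the residual heterogeneity). The statistic is
$t = \hat\beta_1/SE(\hat\beta_1)$ on $k - 2$ degrees of freedom. The
classical precision-variant (regressing $d_i/se_i$ on $1/se_i$ and
testing the intercept) is available for cross-checks. A positive slope
means small studies report more positive change scores.
`funnel_data()` exports the points and the $\pm 1.959964\,se$
pseudo-confidence contour for plotting.

**Influence.** `leave_one_out()` refits the pooled model $k$ times and
flags any omission that moves the pooled estimate outside the
full-model CI or flips its significance at $\alpha = 0.05$.

## The synthetic-data generator

Published extraction tables are rarely redistributable, so every stage
is exercised on synthetic data with the same statistical structure
(`synthetic_config()` / `generate_studies()`). Study $i$ receives a
true change score $\theta_i = \mu + \text{moderator shifts} +
N(0, \tau^2)$, split symmetrically around half the churn rate:

$$p_{inc,i} = \tfrac{1}{2}(\text{churn} + \theta_i),\qquad
  p_{dec,i} = \tfrac{1}{2}(\text{churn} - \theta_i),$$

so $p_{inc} - p_{dec} = \theta_i$ exactly and $p_{inc} + p_{dec}$ (the
share of drinkers changing at all) stays at the configured churn.
Counts are a single multinomial draw per study. This is the minimal
generative model consistent with the multinomial assumptions behind the
SE formula. Configurations must satisfy
$|\mu| + 3\tau + \max|\text{shift}| \le \text{churn}$ so that implied
probabilities stay in the simplex; rare excursions up to 0.01 are
clipped with a warning, anything larger rejects the configuration
outright rather than silently distorting the tails.

Defaults: $k = 40$ studies, $\mu = -0.05$, $\tau = 0.05$, churn $= 0.4$,
study sizes log-uniform on 200–5000 drinkers, three-quarters of studies
in P1 and 45% weighted — magnitudes in line with published European
pandemic drinking surveys, where pooled change scores of a few
percentage points, a large first-wave cluster, and very heterogeneous
study sizes are typical. Optional features: expected starter/stopper
fractions, and a `selection_bias(d, se)` retention function for
funnel-asymmetry experiments.

What the generator deliberately does **not** emulate: dependence
between estimates of one study, non-multinomial measurement error in
self-report, convenience-sample selection on the outcome, and the
extreme $I^2$ (98–99%) seen in the real literature, which would require
heterogeneity far beyond the simplex constraint at realistic churn.
Passing simulation checks therefore validates the estimation machinery,
not the substantive robustness of any real-data conclusion.

## Simulation evidence

`recovery_experiment()` wires generation and estimation together with
per-replicate sub-seeds. The problem sizes below were chosen to give
Monte-Carlo standard errors comfortably below the quantities of
interest while keeping the checks quick to re-run:

* the closed-form SE agrees with the empirical SD of $10^5$ multinomial
  replicates to well under 2% relative error across 50 random designs
  with $n \ge 100$;
* Fisher-scoring REML matches a brute-force restricted-likelihood grid
  search ($10^{-6}$ resolution on $\tau^2$) to about $10^{-5}$ on both
  $\hat\mu$ and $\hat\tau^2$ over 100 random small meta-analyses;
* at $k = 40$, $n = 1000$, $\mu = -0.05$, $\tau = 0.05$ (500
  replicates) the pooled estimate is unbiased to within $\pm 0.005$ and
  the 95% CI covers at 92–97%;
* under a null moderator the QM rejection rate at the 0.0125 threshold
  stays near nominal, and Egger's test rejects a symmetric funnel at
  3–7% for $\alpha = 0.05$.

These same checks run in the test suite and in
`scripts/acceptance.R`.

## Worked example

```{r example}
cfg <- synthetic_config(k = 12, seed = 42)
records <- generate_studies(cfg)
effects <- compute_effects(records)
fit <- pool_changes(effects)
summary(fit)
egger_test(fit)
head(leave_one_out(fit), 3)
```

## Known limitations

* Estimates from one study (e.g. women and men rows) are pooled as if
  independent; no multilevel or cluster-robust variance is fitted.
* Wald inference is anticonservative for $k \lesssim 10$; the subset
  eligibility gate (five studies) limits but does not remove this.
* The marginal-prevalence SE substitution is approximate and flagged,
  not corrected.
* $I^2$ comparisons across subsets inherit all the usual caveats of
  $I^2$ as a relative measure: it grows with study precision even at
  fixed $\tau^2$.
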