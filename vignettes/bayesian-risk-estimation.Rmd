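---
title: "Bayesian posterior risk estimation from cross-sectional case series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian posterior risk estimation from cross-sectional case series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postrisk)
```

## The model

A cross-sectional screening study yields two kinds of summary: among the
$n$ cases of a disease $D$, the proportion exhibiting each level of a
categorical determinant ($P(RF \mid D)$ — age group, gender, education,
comorbidities), and, from an external reference, the proportion of the
general population exhibiting that level ($P(RF)$). Bayes' theorem converts
these into the quantity of clinical interest, the probability of disease
given the determinant level:

$$P(D \mid RF) \;=\; \frac{P(RF \mid D)\, P(D)}{P(RF)}.$$

`posterior_risk()` is this formula; `build_risk_table()` applies it to every
level of a case series joined against a population reference. The model is
strictly per-level and univariate: no adjustment, no interactions, no joint
structure. That is a modelling *assumption*, and the package's job is to
make its consequences (including its failure modes) inspectable rather than
to improve on it.

Three invariants follow algebraically and are enforced by the test suite:
the map is exactly linear in the prior $P(D)$; it is invertible
(`implied_prior()` recovers $P(D)$ from a posterior to machine precision);
and for a determinant whose levels partition both the cases and the
reference population, $\sum_i P(D \mid RF_i) P(RF_i) = P(D)$
(`total_probability_diagnostic()`).

## Calibrating an unstated prior

The packaged case study ships a published posterior table whose prior is
nowhere stated. Because each row implies a prior by inversion,
`calibrate_prior()` inverts every row and returns the median together with
the maximum absolute deviation. On the packaged table the 14 rows agree to
within about $10^{-4}$, i.e. the table was computed with a single common
prior of 0.0560:

```{r calibrate}
cases <- hail_case_series()
pop <- hail_population_reference()
rt <- build_risk_table(cases, pop, prior = "auto",
                       published = hail_published_posteriors())
attr(rt, "prior")
```

That calibrated prior is interesting in itself: it differs from the
cohort's own observed prevalence (200/9407 = 0.0213) and is close to, but
not equal to, the 5.7% regional figure the study cites as its expected
prevalence. The package deliberately exposes all three choices
(`prior = "auto"`, `"observed"`, or an explicit number) so the sensitivity
is a one-line experiment: with the observed prevalence the 60–69-years
posterior drops from 0.434 to 0.165. Because the posterior is linear in the
prior, a prior misspecified by a factor $c$ inflates *every* posterior by
exactly $c$ — `recovery_experiment()` demonstrates this end to end.

Posteriors above 1, which arise whenever the three inputs are mutually
inconsistent, are tagged `infeasible` and logged, never clamped or
rejected: they are a diagnostic about the inputs, not a numerical accident.

## Confidence intervals and rendering

The per-level proportions among cases carry Wald intervals
($p \pm z\sqrt{p(1-p)/n}$, clipped to $[0,1]$) by default because that is
the method that reproduces, at one-decimal percent rendering, every printed
interval of the packaged tables (27 rows); the method was identified by
matching, since the source does not name it. Wilson and Clopper–Pearson
intervals are available behind `binom_interval(method = )` for small
counts; the test suite validates all three against a brute-force
exact-binomial coverage oracle. One printed interval — the cohort
prevalence, 1.7–2.5% — is *not* Wald-consistent (the computed interval is
1.8–2.4%); the package reports the computed interval and the fixture test
asserts the discrepancy rather than encoding the unreproducible number.

All percent rendering uses round-half-up (`round_half_up()`), which matches
the published tables (e.g. 0.335% → "0.3"); the risk table additionally
trims trailing zeros ("6.3", "15.4") as its source does. Internally
everything is a fraction in $[0,1]$; percentages exist only at I/O
boundaries, which removes a whole class of double-scaling bugs in tables
that mix percent columns.

`rank_top_factors()` orders levels by posterior, breaking ties
lexicographically on the label. The published top-7 summary is not strictly
sorted (35.52 printed before 37.33); we impose a deterministic order and
compare as a set.

`daniel_sample_size()` implements the precision-based survey formula
$n = \lceil z^2 p(1-p)/d^2 \rceil$ with optional loss-to-follow-up
inflation. The precision $d$ has **no default**: the case study's stated
sample size (9323) is not reproducible from its stated inputs with any
round value of $d$ (its text also mentions a study power, which does not
appear in a precision-based formula), so the package refuses to guess.

## Bootstrap uncertainty

The source tables carry no uncertainty on the posteriors.
`bootstrap_posterior()` propagates sampling variation parametrically:
case counts are resampled from a multinomial (exhaustive factors) or
binomial (overlapping comorbidity flags) at the observed proportions, the
posterior is recomputed per replicate, and percentile intervals are
returned (percentile rather than BCa: the simplest defensible choice for
smooth functions of proportions; point estimates stay at the non-resampled
values). All sampling runs under one seed via `withr::with_seed`, so
results are reproducible and the caller's RNG state is untouched.

The prior is held fixed by default — in the model it is an external
constant. When the prior is the *observed* prevalence of the same cohort,
its own sampling variability belongs in the interval:
`resample_prior = TRUE` additionally draws the case total from its
screened-cohort binomial. A delta-method calculation shows why this
matters: with the observed prior the per-level estimate reduces to the
empirical conditional frequency $k_l/m_l$, whose variance is
$r(1-r)/m_l$; the fixed-prior bootstrap instead produces variance
$r(1-q)/m_l$, where $q$ is the level's share among cases. Since $q$
typically exceeds the conditional risk $r$, the fixed-prior bootstrap
*undercovers* (≈92% at this design), while prior resampling yields
$r(1-pq)/m_l$, slightly conservative (≈95–96%). The coverage experiment in
the acceptance suite therefore uses `resample_prior = TRUE`. An optional
Dirichlet perturbation of the reference proportions
(`perturb_population = TRUE`) is provided for sensitivity analysis; a fully
Bayesian conjugate treatment is out of scope.

## The synthetic cohort generator

`generate_cohort()` simulates the kind of data the pipeline assumes:
independent categorical determinants sampled from configured marginals,
overlapping binary comorbidities, and disease status drawn Bernoulli with a
**multiplicative** risk: baseline × product of the individual's level
ratios. The multiplicative link was chosen over a logistic one because it
keeps the generative truth available in closed form
(`true_conditional_risks()`), which is exactly what parameter recovery
needs; the cost is that a configuration whose worst reachable level
combination exceeds risk 1 must be rejected at construction (it is, with
the offending combination named).

`hail_like_config()` is the default study-conditions generator: reference
marginals from the packaged population column (age renormalized over the
adult groups it covers), overall prevalence fixed at the study's 2.1%, and
ratios that mirror the published risk gradient qualitatively — risk rising
about fourfold across age groups, doubled for illiteracy and cataract, 2.5×
for diabetes, mildly protective associations for hypertension, asthma and
cardiovascular disease as the published table implies. The ratios are
deliberately milder than the published posteriors suggest: transplanting
the full gradient into a multiplicative model would push the worst
combination past probability 1. What the generator does **not** emulate:
age–comorbidity correlation (factors are independent by design, since the
univariate model has no joint structure to validate against), continuous
age, diagnostic misclassification, or longitudinal progression. Passing
recovery tests therefore demonstrate estimator consistency *under the
model's own assumptions*, not robustness to their violation.

`recovery_experiment()` closes the loop: generate → summarize →
`build_risk_table(prior = "observed")`, then bias and RMSE against the
closed-form truth. With the observed-prevalence prior the estimator is the
empirical conditional frequency and recovers the generative risks without
bias; the experiment also quantifies the systematic inflation from a
misspecified fixed prior.

## Problem sizes and numerical choices

The validation experiments use 100 replicate cohorts of 200,000
individuals for bias and 500 cohorts of 50,000 (400 bootstrap replicates
each, pooled over the five age levels) for coverage — sizes at which
binomial noise is far below the ±0.005 bias band while the whole suite
stays desk-scale (under a minute for the experiment). Percentile bounds
use R's default quantile definition; bootstrap replicates that draw zero
cases under prior resampling are floored at one case (a replicate with no
cases has no case table). Label matching is exact string equality after
Unicode NFC normalization, so composed and decomposed accents (and the
en-dashes in age labels) cannot silently fail a join. CSV is the only
input format: comma-separated, UTF-8, header required.

## Known limitations

* The reference-population proportions are taken as exact constants; only
  `perturb_population` acknowledges their uncertainty, and the
  year/geography behind them is not modelled.
* The univariate model double-counts correlated determinants by
  construction; nothing in the package corrects for that, by design.
* Percentile intervals are first-order accurate; for very small counts
  prefer the Wilson or exact intervals on the input proportions.
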