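---
title: "Rasch measurement for clinical ordinal scales: models, diagnostics, key forms and change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch measurement for clinical ordinal scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Clinical instruments such as activities-of-daily-living (ADL) scales and
neurobehavioral impairment-impact scales produce ordinal ratings: a higher
category means *more* of the attribute (more independence, or more
impairment impact), but the steps between categories are not equal
intervals. Summing such ratings and treating the total as a measure is not
defensible arithmetic. The Rasch model family converts ordinal ratings into
interval-scaled *logit* measures: the log-odds scale on which person
ability/severity and item difficulty live.

`raschkey` implements the computational core of that workflow for scales
whose items may carry different numbers of rating categories: calibration,
validation diagnostics, score-to-measure conversion, key forms, missing-data
imputation, and pre-post change testing.

## The model

For person $n$ with measure $\theta_n$ and item $i$ with difficulty
$\delta_i$ in category-count group $g(i)$ with Rasch-Andrich thresholds
$\tau_{g(i),1}, \dots, \tau_{g(i),m-1}$, the probability of rating
$j \in \{0, \dots, m-1\}$ is

$$P(X_{ni} = j) \;=\; \frac{\exp \sum_{k=1}^{j} (\theta_n - \delta_i -
\tau_{g(i),k})}{\sum_{l=0}^{m-1} \exp \sum_{k=1}^{l} (\theta_n - \delta_i -
\tau_{g(i),k})}, \qquad \sum_{k=1}^{0} (\cdot) \equiv 0 .$$

A threshold $\tau_k$ is the point on the logit axis where categories $k-1$
and $k$ are equally probable — the "50/50" boundary drawn as `:` on printed
key forms. Four variants differ only in how thresholds are shared:

* **dichotomous** — two categories per item; the single threshold is 0 by
  convention and the model reduces to the logistic
  $P(X=1) = 1/(1+e^{-(\theta-\delta)})$;
* **rating scale** — one threshold set shared by every item;
* **partial credit** — one threshold set per item;
* **group** — one threshold set per *category-count group* of items (the
  model used for mixed 2/3/4-category clinical scales; the other three are
  special cases, which the package exploits by regrouping and running a
  single code path).

Identification: item difficulties are mean-centered within the scale and
thresholds are mean-centered within each group; both conventions are stored
with every calibration and enforced (tolerance 1e-9) at construction.

## Estimation

`rasch()` uses joint maximum likelihood (JMLE): alternating damped
Newton-Raphson sweeps over persons, items and thresholds, solving the
score equations $r_n = \sum_i E_{ni}(\theta_n)$,
$s_i = \sum_n E_{ni}$, and (for thresholds) observed = expected counts of
ratings $\ge k$. JMLE is chosen because the reference measures this toolkit
is meant to agree with were produced by software of that family; the
well-known finite-sample spread inflation (roughly $I/(I-1)$ on item
difficulties) is therefore *not* corrected by default.
`rasch_control(bias_correction = TRUE)` applies the first-order $(I-1)/I$
shrinkage for users who prefer it.

Numerical choices:

* convergence when the largest absolute parameter update is below 1e-4
  logits, with a 200-iteration cap; both are recorded in the result;
* Newton steps clamped to 1 logit per sweep and parameters to ±12 logits;
* after each sweep the centering constraints are restored by exact
  compensating shifts that leave the likelihood unchanged;
* person measures are solved by a bracketed Newton iteration on the test
  characteristic curve (residual below 1e-9 score units), which makes the
  raw score manifestly sufficient: identical raw score on an identical
  answered-item set gives an identical measure and SE.

Persons with all-minimum or all-maximum raw scores carry no information
about items; they are excluded from calibration, and their measures are
estimated from a raw score pulled 0.3 score units into the interior
(configurable via `extreme_score_adjustment`) and flagged. Items answered
only by extreme persons are dropped with a warning. A rating category never
observed in a group stops calibration with an error directing the user to
the category diagnostics, since an unobserved category cannot anchor its
thresholds and usually calls for collapsing.

## Validation diagnostics

`validate_scale()` runs the screening sequence in the order a scale
developer would: rating-category diagnostics, point-measure screening with
one-at-a-time removal and refit, item-fit screening with one-at-a-time
removal honoring a 5%-of-items-by-chance allowance, residual PCA, then
separation and reliability. Defaults live in `validation_criteria()`:
point-measure threshold 0.12; misfit rule MnSq $\ge$ 1.4 together with
ZSTD $\ge$ 2; category criteria of 10 observations, monotone average
measures, category outfit $\le$ 1.5, ordered thresholds advancing $\ge$ 1.4
logits; first residual contrast $\le$ 10% of residual variance; person
separation $\ge$ 2 and reliability $\ge$ 0.8. Misfit removals take the worst
outfit MnSq first, ties broken by worse ZSTD then item id; the pipeline
refuses to shrink a scale below `min_items` (default 10) and reports an
aborted run instead.

Fit statistics follow the standard mean-square forms: with standardized
residual $z_{ni} = (x_{ni}-E_{ni})/\sqrt{W_{ni}}$, outfit is the plain mean
of $z^2$ and infit the information-weighted $\sum(x-E)^2 / \sum W$; ZSTD is
the Wilson-Hilferty cube-root transform using the model variance of the
mean square built from the fourth central moment $C_{ni}$. All of these are
checked against literal double-loop oracles in the test suite.

One deliberate definition: *category* outfit is reported as the ratio of
observed to model-expected sums of squared standardized residuals over the
responses in a category. The naive conditional mean of $z^2$ has expectation
$(1-\bar p)/\bar p$ for a rarely used category — for a cohort sitting ~2
logits below the items it exceeds 5 even when the data fit perfectly — so it
cannot carry a fixed 1.5 screening bound. The ratio form has expectation 1
under the model for every category, which is what the bound presumes.

Residual PCA decomposes the pairwise-complete correlation matrix of
standardized residuals with `eigen()`; the first contrast is reported both
in item units (eigenvalue) and as a percentage of total residual variance,
the form in which the $\le 10\%$ criterion is stated.

Separation statistics: $RMSE = \sqrt{\mathrm{mean}(SE^2)}$, true SD
$= \sqrt{\max(SD_{obs}^2 - RMSE^2,\, 0)}$, separation $G = SD_{true}/RMSE$,
reliability $R = G^2/(1+G^2)$, strata $(4G+1)/3$. Extreme persons are
excluded by default ("real"-style), configurable.

## Conversion tables, key forms, imputation

For a complete answered-item set the raw score is sufficient, so scoring
reduces to a table: `conversion_table()` inverts the test characteristic
curve per raw score (residual < 1e-8 score units), with extreme rows
adjusted and flagged, SEs from test information. `keyform()` lays the item
category boundaries ($\delta_i$, or $\delta_i + \tau_{g,k}$) along the
logit axis, items ordered by difficulty with the most frequently impacted
items first; `plot()` draws the familiar banded chart and can overlay a
person's measure with SE whiskers.

`impute_and_measure()` handles up to four missing ratings (more are refused
with an explicit count). Two provisional-measure methods are exposed:

* `anchored_ml` (default): maximum-likelihood measure from the answered
  items;
* `keyform_L1`: the key-form "vertical line" reading — the measure
  minimizing $\sum_i |x_i - E_i(\theta)|$ over answered items on a
  0.001-logit lattice, a flat minimizing interval resolving to its
  midpoint.

Each missing item then takes its most probable category at the provisional
measure (an exact tie resolves to the lower, less-impact category), and the
final measure and SE are re-estimated from the completed vector with the
imputed cells flagged.

A caution on `keyform_L1`: minimizing score-space L1 distance balances the
*information* of low-scored against high-scored items rather than the
expected-score total, so for persons away from the scale center it sits
systematically 0.5–1.5 logits below the ML measure. It is provided because
the distance-minimizing vertical line is how key-form reading is described;
`anchored_ml` is the statistically standard choice and the default. Because
the final measure is always re-estimated from the completed vector, the
imputation-calibration property (post-imputation measure within 1 model SE
of the complete-data measure for $\ge 90\%$ of persons with up to 4 masked
cells) holds for both methods.

## Change and agreement

`significant_change()` implements the clinical sum-of-SEs rule: a change is
significant when $|m_2 - m_1| > SE_1 + SE_2$, strictly; direction is
polarity-aware (on an impairment-impact scale a decrease is an
improvement). The rule is equivalent to a $|z| > \sqrt 2$ cut on the
difference (whose SD is $\sqrt{SE_1^2+SE_2^2}$), i.e. roughly an 84%
confidence criterion, *not* a 5% test: under the null it fires with
probability $2(1-\Phi(\sqrt 2)) \approx 15.7\%$. The z statistic is reported
alongside for transparency. `compare_measure_sets()` performs the
external-validity analysis (per-person absolute differences against a
0.5-logit criterion plus a two-tailed paired t-test), and
`outcome_summary()` tallies significant-change shares for a cohort.

## The synthetic generator

No patient-level data accompany the published analyses, so
`simulate_responses()` plus two canonical fixtures stand in for them:

* `cva_scale_fixture()` — a 49-item impairment-impact scale in three
  category-count groups (31 dichotomous of which 18 pervasive-type, 8
  three-category, 10 four-category; 2+3+4 = 9 category labels; maximum raw
  score 77). Any split $(a,b,c)$ with $a+b+c=49$, $b+2c=28$ matches the
  published totals; 31/8/10 is the recorded canonical choice. Thresholds
  are ordered with advances of 1.6 logits — comfortably above the 1.4-logit
  screening criterion, so that estimation noise at the study size does not
  generate false alarms against the fixture's own design. Generating
  difficulties
  span about $-2.8$ to $+1.1$ logits with the four motor-type items at the
  most frequently impacted extreme. The upper end is deliberately short of
  the cohort-offset-plus-3-logits sometimes quoted for item banks: the
  default cohort sits 1.8 logits below the item mean, and an item 4–5
  logits above that cohort would be endorsed a handful of times in 300 —
  its point-measure correlation and category counts could not meet the
  screening criteria that the real instrument demonstrably met, so such an
  item cannot be part of a fixture meant to represent a validated scale.
* `adl_scale_fixture()` — a 20-item ADL scale, one rating-scale group with
  4 effective categories (five labels with one documented collapse),
  difficulties evenly spread over ±2.5 logits.

Default simulated cohort: $\theta \sim N(-1.8,\ 1.0)$, echoing the
first-evaluation stroke cohort mean of the study conditions the generator
emulates (ADL examples in the tests use $N(0.12,\ 1.2)$ likewise). Ratings
are drawn cell-wise from the model probabilities; missingness is injected
either as an exact per-person count (capped at 4, the imputation limit) or
as an independent cell rate, touching only the targeted cells; everything
is reproducible from the mandatory seed.

What the generator does **not** emulate: rater effects, longitudinal
correlation between evaluations, diagnosis subgroups, local item
dependence, or real clinicians' missingness patterns (cells are masked at
random). Passing tests on these simulations therefore demonstrate that the
algorithms are correct under the stated model, not that the model fits any
particular clinic's data.

## Problem sizes and test design

The test suite and the acceptance script use cohorts of 300 persons (the
published calibration used 222; 300 keeps per-category counts comfortable
at the same order of magnitude), 10 replicate seeds for stochastic
properties, 500 persons for imputation calibration, 2000 for distributional
checks, and 10,000 pairs for the null behavior of the change rule. Exact
algebraic identities are tested at tolerances 1e-9 to 1e-12; lattice-search
oracles at their lattice resolution (1e-3 logits); simulation-based
properties at bounds stated with the property.

## Known limitations

* JMLE estimates are finite-sample biased (uncorrected by default, see
  above); CMLE/MMLE estimators are out of scope.
* Standard errors are model-based information SEs; no uncertainty is
  propagated from item calibration into person measures, and imputation is
  single, not multiple.
* The residual PCA uses pairwise-complete correlations, which can make the
  matrix slightly indefinite under heavy missingness; eigenvalues are
  reported as computed.
* Many-facet models (raters), differential item functioning and equating
  across scales are not implemented.
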