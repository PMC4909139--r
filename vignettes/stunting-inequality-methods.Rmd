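---
title: "Measuring wealth-related inequality in child stunting across repeated surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wealth-related inequality in child stunting across repeated surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stuntineq)
```

## The problem

National averages of child stunting (height-for-age z-score, HAZ, below −2)
hide how the burden is distributed across the wealth gradient within a
country. Repeated national household surveys (DHS, MICS) make it possible to
ask two distinct questions: is prevalence falling, and is the gap between
poor and rich children closing? Those questions can have opposite answers,
because absolute and relative inequality can move in different directions
while overall prevalence declines.

The canonical illustration: if the poorest quintile falls from 50% to 30%
and the wealthiest from 10% to 5%, the absolute drop is larger for the poor
(20 vs 5 percentage points) while the relative drop is larger for the rich
(50% vs 40%) — and the poor-to-rich rate ratio worsens from fivefold to
sixfold. Any serious monitoring exercise therefore needs both an absolute
and a relative whole-distribution measure, not just the Q1/Q5 extremes.

```{r worked}
change_measures(50, 30)   # poorest quintile
change_measures(10, 5)    # wealthiest quintile
simple_measures(50, 10)$value   # early difference and ratio
simple_measures(30, 5)$value    # late difference and ratio
```

## The two summary measures

Children (or quintiles of children) are ordered by household wealth and
given **weighted fractional ranks**: group g, with weighted population share
$s_g$ and cumulative share $C_{g-1}$ below it, sits at the midpoint rank
$r_g = C_{g-1} + s_g/2$. Five equal quintiles sit at 0.1, 0.3, …, 0.9, and
the weighted mean rank is always 1/2.

**Slope index of inequality (SII).** A weighted logistic regression of the
stunting indicator on the fractional rank,
$\mathrm{logit}\, p(r) = a + b r$, yields
$$\mathrm{SII} = 100\,\{\mathrm{expit}(a+b) - \mathrm{expit}(a)\},$$
the model-predicted prevalence difference, in percentage points, between the
top (rank 1) and bottom (rank 0) of the wealth scale. The logistic link —
rather than the textbook linear regression on midpoint ranks — keeps the
extrapolated endpoint prevalences inside [0, 1]. SII = −20 means prevalence
among the wealthiest is 20 points lower than among the poorest. Its standard
error is the delta-method image of a cluster-robust sandwich covariance of
$(a, b)$.

**Concentration index (CIX).** The relative measure, in its uncorrected
form:
$$\mathrm{CIX} = 100 \cdot \frac{2\,\mathrm{cov}_w(y, r)}{\bar y_w},$$
twice the weighted covariance between the indicator and the rank over mean
prevalence, on a −100..100 scale. It equals twice the area between the
concentration curve (cumulative case share vs cumulative population share,
poorest first) and the diagonal; `cix_trapezoid()` implements that second
route and the two agree to 1e−10 on grouped data, which the test suite
asserts. Negative values mean the burden concentrates among the poor. Its
standard error is a delete-one-cluster jackknife, a design-consistent choice
that needs no analytic linearization of the ratio-of-moments form.

Deliberate non-goals: Wagstaff/Erreygers corrections of the CIX (the
uncorrected relative form is the estimand here) and decomposition analyses.

## Design-based estimation

Surveys are two-stage clustered samples with unequal weights, so all
prevalences use the weighted ratio estimator with Taylor-linearized
variance under the with-replacement-cluster approximation: per-cluster
totals of $w_i(y_i - \hat p)$, between-cluster variance within strata, no
finite-population correction. This is the convention of the major survey
programs. Single-cluster strata are collapsed into a neighbouring stratum
with a warning; a survey with a single cluster gets a flagged, undefined SE.
The linearization is implemented directly in the package and is checked in
the tests against a hand-computed oracle in the self-representing case
(every child its own cluster), where it must equal the closed-form
simple-random-sample expression to 1e−12.

## Wealth index

When precomputed wealth scores are absent, households are scored by the
first principal component of their standardized asset indicators, computed
per survey; constant indicators are dropped with a warning, and the
component sign is fixed so that the score correlates positively with the
simple asset count (higher score = wealthier, deterministically). When the
input already carries scores — as original survey teams provide — they are
used as-is.

Quintile cutpoints are the 20/40/60/80 weighted percentiles of the score.
Open choices, and what this package does:

* **Reference population.** Cutpoints default to the child-level weighted
  distribution (quintiles of children, the de facto population analysed);
  `reference = "household"` switches to household-level cutpoints. Both
  conventions circulate in survey practice.
* **Ties.** A score equal to a cutpoint falls in the lower quintile —
  deterministic and order-independent.
* **Rank granularity.** `fractional_ranks()` defaults to grouped
  quintile midpoint ranks, matching grouped-data practice; a continuous
  per-score mode is available and is what the large-sample validation uses.
* PCA is not weighted by household size; a household contributes once.

## Trends

Each indicator (national, Q1 and Q5 prevalence, SII, CIX) is regressed on
survey year by unweighted OLS, one point per survey, and the slope is
reported as change per 10-year interval. Significance comes from a two-sided
test contrasting the earliest and latest surveys,
$z = (x_L - x_E)/\sqrt{se_E^2 + se_L^2}$, referred to the standard normal —
survey standard errors carry large effective degrees of freedom, so a
finite-df t reference would add a spurious tuning knob. With exactly two
surveys the OLS slope has no residual degrees of freedom; the
earliest-vs-latest test is then the only significance statement, and the
two can disagree in sign for non-monotone series with three or more points.
Associations between countries' rates of decline use Spearman correlations
(average ranks for ties, t-approximation p-values). Polynomial trends are
deliberately not fitted: a mean annual change is only comparable across
countries if every country gets the same linear summary.

The country filter mirrors standard repeated-survey practice: at least two
surveys at least 10 years apart. In reporting, the paired-change table
multiplies CIX changes by −1 so that positive values mean improving equity;
stored estimates never carry that flip.

## The synthetic cohort

`simulate_cohort()` emulates the statistical structure the estimators must
handle, with known truth:

* households carry a latent wealth $w \sim N(0,1)$ driving both binary
  asset indicators (logistic loadings, defaults 0.5–2.0) and HAZ;
* HAZ = $\beta_0 + \beta_1 F(w) + \gamma (year - year_0) + b_c + \varepsilon$,
  where $F(w)$ is the within-survey fractional wealth rank, $b_c \sim
  N(0, \tau^2)$ is shared by a sampling cluster and $\varepsilon \sim
  N(0, \sigma^2)$;
* sampling weights differ by stratum (clusters alternate between two strata
  with weights 1.0 and 2.5), non-informatively, so weighting exercises the
  estimators without shifting the estimands.

Wealth enters through the fractional rank precisely so the truth aligns
with the estimand: the true prevalence at rank r is
$p(r) = \Phi\{(-2 - \mu(r))/\sqrt{\sigma^2+\tau^2}\}$, the true SII is
$100\{p(1) - p(0)\}$, and the true CIX follows by numeric quadrature of the
concentration integral (`cix_quadrature()`, an independent oracle for the
sample-based estimators). The shared cluster intercept is deliberate: it
makes naive binomial standard errors anticonservative, giving the
design-based variance code something real to detect — the suite requires
the design SE to exceed the naive SE in at least 95% of 200 clustered
replicates.

Default parameters place national prevalence in the 10–60% band typical of
repeated-survey series in high-burden settings: four countries with
$\beta_0$ from −1.7 to −1.0, wealth gradients $\beta_1$ of 0.6–1.3 z,
secular improvements $\gamma$ of 0.01–0.03 z/year, $\tau = 0.25$,
$\sigma = 0.95$, 40 clusters × 12 households per survey, one country
restricted to under-3s and one with only two surveys a decade apart.

What the simulator does **not** emulate: real weighting and nonresponse
adjustment, age- and sex-specific HAZ structure (age and sex are simulated
but carry no HAZ signal), survey-team quintile idiosyncrasies, and
country-specific asset menus. Passing recovery tests therefore demonstrate
estimator correctness under a clustered, weighted, wealth-graded data
generating process — not robustness to every artefact of real microdata.

## Numerical choices

* Stunting is strictly HAZ < −2; HAZ is accepted directly, or computed from
  height via the LMS transform $z = \{(h/M)^L - 1\}/(LS)$ (log form at
  L = 0) against a user-supplied reference table.
* Records with missing HAZ are retained but flagged and excluded from all
  estimators; |HAZ| > 6 is treated as implausible (configurable), the usual
  anthropometric screen. Both counts appear in the run manifest, which must
  reconcile input = analysed + dropped per survey.
* Complete separation in the SII fit (e.g. all cases in one quintile) falls
  back to a ridge-penalized fit (penalty 1e−6), flagged, with no SE rather
  than a misleading one. A constant outcome returns SII 0 with undefined SE.
* A zero-prevalence subgroup leaves the CIX undefined and flagged; a
  wealthiest-quintile prevalence of zero leaves the Q1/Q5 ratio undefined
  and flagged (this fragility of extreme-quintile ratios is one reason the
  whole-distribution measures exist).
* Survey year is a real-valued fieldwork midpoint, so multi-year surveys
  enter trends at their temporal centre of mass.

## Validation problem sizes

The checked-in validation uses: a 200,000-child sample for the SII
semantics check (endpoint prevalences 30%/10%, recovered within 3
Monte-Carlo SEs of −20 pp); a six-point recovery grid crossing wealth
gradients $\beta_1 \in \{0.6, 1.2\}$ with baselines $\beta_0 \in \{-0.6,
-1.3, -2.0\}$ at ~3,700 children per survey, each estimate required to sit
within 3 SEs of its closed-form truth; and 200 replicates of a 30-cluster
survey for the variance-detection property. Recovery runs rank children on
the simulator's own household scores (the precomputed-score path), so it
isolates estimator error from asset-proxy measurement error; the PCA proxy
is validated separately by requiring rank correlation above 0.8 with latent
wealth.

## Limitations

Country-level results from the original multi-country analyses require the
restricted survey microdata and are out of scope; this package validates
the estimators and reproduces the analysis pipeline on synthetic cohorts.
The SII's logistic functional form is itself an estimand choice: on data
whose true prevalence curve is probit-shaped the logistic endpoint
difference is a close but not exact match, which is why recovery tolerances
are Monte-Carlo based rather than exact. Jackknife CIX standard errors
assume enough clusters (dozens) to be stable; with a handful of clusters
they are reported but fragile.
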