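---
title: "Combining GP registry counts: models, standardization and stochastic league tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining GP registry counts: models, standardization and stochastic league tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbrank)
```

## The problem

Several general-practitioner registration networks (GPRNs) each report
aggregated disease counts — incident cases with person-years of exposure,
and prevalent cases with the registered population at a reference date —
broken down by sex and 5-year age class (18 classes, 0–4 up to 85+).
The networks differ systematically: coding systems, case definitions,
episode- versus problem-based registration, practice populations. The task
is to combine them into one national estimate of cases per 1,000, to be
honest about how much the networks disagree, and to quantify what that
disagreement does to a "league table" that ranks diseases by incidence or
prevalence.

`morbrank` implements that chain end to end: a random-intercept
generalized linear mixed model per disease and measure, BIC selection of
the age/sex fixed-effect structure, direct standardization to an
average-registry rate per 1,000 with two kinds of uncertainty interval,
and a Monte Carlo stochastic league table of rank-position probabilities.

## The model

For disease $d$ and registry $r$, the count in cell $i$ (a sex × age-class
combination) is modelled as

* incidence: $y_{ri} \sim \mathrm{Poisson}(E_{ri}\, e^{\eta_{ri}})$ with
  $E_{ri}$ person-years (log link, offset $\log E_{ri}$);
* prevalence: $y_{ri} \sim \mathrm{Binomial}(N_{ri},
  \mathrm{logit}^{-1}(\eta_{ri}))$ with $N_{ri}$ registered persons;

and linear predictor

$$\eta_{ri} = \mathbf{x}_i'\boldsymbol\beta + u_r, \qquad
  u_r \sim N(0, \sigma_u^2).$$

The single random intercept $u_r$ absorbs all systematic level differences
between registries on the link scale. $\mathbf{x}_i$ contains an
intercept, orthogonal polynomials of age, optionally a sex indicator
(female is the reference), and sex-by-age interaction polynomials.
Orthogonal rather than raw polynomials keep the design well conditioned at
the high degrees that prevalence curves sometimes need.

Age enters through one representative value per 5-year class: the class
midpoint (2.5, 7.5, …, 82.5). The open-ended 85+ class has no midpoint;
we use 90 years by default (configurable). Diseases that are only
relevant at older ages are modelled on a restricted grid
(`restrict_age_range()`), and the orthogonal basis is rebuilt per disease
on its included midpoints — a global basis would be undefined across
different age restrictions.

### Likelihood and quadrature

The marginal likelihood integrates each registry's intercept out
numerically. With a single scalar random effect the integral is
one-dimensional, so we use adaptive Gauss–Hermite quadrature (AGHQ): for
each registry the integrand is recentred at the posterior mode of $u_r$
(found by a damped Newton iteration with analytic first and second
derivatives) and rescaled by the posterior curvature, then a 15-node
Gauss–Hermite rule is applied on the transformed axis. Fifteen nodes are
converged far beyond test tolerances here: doubling to 30 nodes changes
the log-likelihood by less than $10^{-8}$ on the scenario data, and the
test suite checks the AGHQ value against brute-force trapezoid
integration with 20,001 nodes over $\pm 8\sigma_u$ to $10^{-8}$.

The likelihood is implemented directly rather than delegated to a mixed-
model package, because the average-registry transformation, the interval
construction and the Monte Carlo ranking all need to share one coherent
parameter object (coefficients, their covariance, and $\sigma_u$) on the
link scale; `lme4` and `glmmTMB` remain available as independent
cross-checks but are not in the estimation path.

Optimisation is quasi-Newton (BFGS) over $(\boldsymbol\beta, \log
\sigma_u)$ with central-difference gradients; the variance is
parameterised on the log scale so the search is unconstrained. Starts are
centred on the pooled ($\sigma_u = 0$) solution, which we compute with our
own Newton iteration, with deterministic jitter for the restarts (3 by
default). Estimates with $\hat\sigma_u < 10^{-4}$ are flagged
"effectively zero" and their coefficient covariance is computed with the
variance direction profiled out, since the observed information
degenerates at the boundary. The coefficient covariance is otherwise the
fixed-effect block of the inverse observed information (numerical
Hessian).

### Model selection

The fixed-effect structure — age degree, sex main effect, sex-by-age
interaction degree — is chosen by fitting **every** admissible candidate
and taking the smallest BIC; an exhaustive criterion-based search avoids
the path dependence of stepwise selection. Two conventions had to be
fixed because they are genuinely underdetermined:

* the BIC sample size $n$ is the number of aggregated (registry, sex,
  age-class) cells, not the number of registered persons (configurable via
  `bic_n = "exposure"`); aggregated cells are the units the likelihood is
  evaluated on;
* the parameter count includes the variance parameter ($p =
  \mathrm{len}(\beta) + 1$) whenever $\sigma_u$ is estimated.

Exact BIC ties (within $10^{-9}$) go to the candidate with fewer
parameters, then lower age degree, then fewer sex terms.

## From model to cases per 1,000

### The average registry

Predictions target the *average* registry on the outcome scale: the
expectation of the inverse-link transform over the random-intercept
distribution,
$$\mathrm{rate}(\mathbf{x}) = E_u\!\left[g^{-1}(\mathbf{x}'\boldsymbol\beta
  + u)\right],$$
which is **not** the same as setting $u = 0$ when the link is nonlinear.
For the log link this is the lognormal-mean closed form
$\exp(\mathbf{x}'\boldsymbol\beta + \sigma_u^2/2)$, strictly above the
median-registry rate; for the logit link the expectation is computed by
Gauss–Hermite quadrature. Extrapolation outside the fitted age range is
an error, never silent.

### Standardization

Cell rates are weighted by a standard population's age/sex counts and
reported per 1,000. Age classes excluded from a disease's model
contribute zero cases but **stay in the denominator**, so "per 1,000"
always means per 1,000 of the whole population and diseases with
different age restrictions are comparable in one league table.

### Two intervals

Uncertainty is propagated by simulation: 5,000 draws of
$\boldsymbol\beta^* \sim \mathrm{MVN}(\hat{\boldsymbol\beta},
\widehat{\mathrm{vcov}})$ on the link scale, each standardized per 1,000,
with the interval taken as the empirical 2.5th/97.5th percentiles. 5,000
draws reproduce closed-form interval endpoints to within about 2% in the
test suite, which is why that is the default.

* the **fixed-only** interval applies the average-registry transform to
  each $\boldsymbol\beta^*$ draw, so it reflects coefficient uncertainty
  around the average-registry prediction (and is centred on the point
  estimate);
* the **total** interval additionally adds a fresh registry shift
  $u^* \sim N(0, \hat\sigma_u^2)$ to each replicate's linear predictor, so
  it also reflects how much an actual registry may deviate.

The point estimate is always the plug-in transform of the MLE, not the
mean of the draws. Uncertainty in $\hat\sigma_u$ itself is *not*
propagated — draws use the fixed estimate — and with few registries
$\hat\sigma_u$ is noisy, so the total interval should be read as "given
the estimated heterogeneity" rather than as a full accounting.

## The stochastic league table

For each of 5,000 draws, every disease's standardized rate is drawn as
above (coefficients and a fresh registry shift; redrawing $u^*$ per
replicate is the natural reading of "including the between-registry
variance", and we adopt it), and the diseases are ranked in descending
order — rank 1 is the largest. The rank-probability matrix $P[d,k]$ is
the fraction of draws in which disease $d$ took rank $k$; because every
draw assigns each rank exactly once, $P$ is doubly stochastic, which the
code asserts.

Design choices:

* **Independence across diseases.** Each disease draws from its own
  random sub-stream, derived deterministically from the master seed and
  the disease id (`sub_seed()`), so adding a disease never perturbs
  another's draws and tables are auditable. Correlated diseases (shared
  risk factors, causal links) are out of scope; dependence would change
  the rank probabilities but not the machinery.
* **Ties** are broken uniformly at random; with continuous draws this is
  a measure-zero event.
* **Display threshold.** The rank span — how many positions a disease
  occupies with non-negligible probability — counts entries with $P \ge
  0.005$, i.e. those that would print as at least 0.01 in a two-decimal
  table. Configurable.
* Row maxima (the modal rank of each disease) and column maxima (the
  most likely occupant of each rank) are annotated and rendered bracketed
  and bold respectively by `format_league_table()`.

Two published 18-disease league tables (Dutch GP networks, 2007) are
shipped as transcribed two-decimal fixtures under `inst/extdata/` and are
used only as inputs to these table-summary operations — e.g. the
arthritis row spans 12 rank positions with modal rank 1 despite point
rank 4, and multiple sclerosis spans 2 — never as fitting targets.

## The synthetic-data generator

The original multi-network counts are not public, so validation runs on
simulated registries. The generator draws one intercept shift per
registry and then Poisson or binomial cell counts; there is no extra
cell-level overdispersion, matching the fitted model. The truth is
expressed on a *raw* polynomial basis in age/100 while fitting uses
orthogonal polynomials, so simulator and fitter communicate only through
data and share no basis code. Registry exposures follow a plausible
pyramid — near-uniform to age 60, then declining 0.72× per class — so
standardization is exercised non-trivially.

The scenario library fixes the study conditions:

* **flat** — age-constant rates (incidence 5/1,000 person-years,
  prevalence 5%), 10 registries of 100,000 persons, $\sigma_u = 0.3$;
  used for coverage and variance-recovery checks (200 replicates; Wald
  coverage of the intercept is required to land in [0.88, 0.99]).
* **diabetes-like** — a quartic age curve peaking near age 75 with a
  modest male excess and small $\sigma_u$ (0.08 incidence, 0.05
  prevalence), on five registries of 12,000–350,000 persons, mirroring
  the realistic mix of one large and several small networks.
* **arthritis-like** — a quadratic age curve with a female excess and
  large $\sigma_u$ (0.8 incidence, 0.5 prevalence) on four registries:
  the regime where the total interval dwarfs the fixed-only interval.

What the simulation does *not* emulate — and what passing tests therefore
do not establish about real registry data: diagnostic misclassification,
registration-length effects on the incident/prevalent distinction,
between-cell overdispersion, and correlation between diseases. The
generator validates the estimation chain, not the registries.

Problem sizes in the tests and scripts (10 registries × 100,000 persons
for recovery runs; degree-4 selection spaces; 2,000–5,000 Monte Carlo
draws) were chosen as the smallest sizes at which the statistical
behaviour of interest is clearly visible; the methods scale to larger
inputs unchanged.

## Known limitations

* With 2–5 registries, $\hat\sigma_u$ is estimated from as few points as
  there are registries; expect large sampling variability (the
  arthritis-like scenario routinely yields $\hat\sigma_u$ between half
  and twice the truth at 4 registries) and occasional boundary estimates.
* BIC's sample-size convention materially affects how aggressively sex
  interactions are pruned; both conventions are exposed.
* The average-registry expectation for the logit link is a quadrature
  approximation (15 nodes), adequate to $10^{-8}$ here but not exact in
  the closed-form sense of the log link.
* Rank probabilities inherit Monte Carlo error of order
  $\sqrt{p(1-p)/5000} \approx 0.007$; second-decimal differences in a
  league table are not meaningful.
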