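---
title: "Methods: severity modelling, stability testing, and cost-based evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity modelling, stability testing, and cost-based evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

crashsev analyses injury severity in multi-vehicle crashes on three ordered
levels — property damage only (PDO), injury (I), and fatal injury (FI) —
and evaluates severity classifiers by the economic consequences of their
errors rather than by raw accuracy alone. This vignette is the package's
account of the underlying methods: the models, their assumptions, the
tunable parameters, the synthetic data generator used for validation, and
the numerical choices that a maintainer would otherwise have to
reverse-engineer.

## The severity model

Each crash $i$ carries a propensity for each severity level $k$,

$$V_{ki} = X_{ki}'\beta_k + \varepsilon_{ki},$$

where $X_{ki}$ collects binary indicators in four groups (driver, roadway,
crash, and occupant characteristics) and $\varepsilon_{ki}$ is iid type-I
extreme value (Gumbel). The recorded severity is the level with the highest
propensity, which yields multinomial-logit choice probabilities. One level —
PDO by default, configurable in `model_spec()` — is the base: all of its
parameters are normalised to zero, since only propensity differences are
identified.

Crashes differ in ways the indicators cannot capture (vehicle structure,
impact energy, occupant physiology), so coefficients are allowed to vary
across crashes. A random coefficient follows

$$\beta = \bar\beta + \delta' Z + \sigma \exp(\omega' W)\,\nu,
\qquad \nu \sim N(0, 1),$$

so its mean shifts with observed covariates $Z$ (heterogeneity in the
mean) and its standard deviation scales multiplicatively with covariates
$W$ (heterogeneity in the variance). The mixing distribution is normal for
every random coefficient; alternative mixing densities are out of scope.
Mixing is at crash level — one disturbance per crash per random
coefficient, not per occupant.

The sign of $\sigma$ is not identified (only $\sigma^2$ enters the
likelihood), so it is estimated unconstrained and reported as $|\sigma|$ by
`tidy()`. A fitted $\sigma$ collapsing towards zero means the data do not
support randomness in that coefficient; the fit emits a message and the
model effectively reduces to a fixed coefficient there.

The interpretive quantity for a fitted random coefficient is its sign
split: `share_negative(mean, sd)` returns $\Phi(-\bar\beta/\sigma)$, the
fraction of crashes for which the realised coefficient is negative.

## Simulated maximum likelihood over Halton draws

The mixed-logit probability is an integral over $\nu$ with no closed form.
It is approximated by averaging the logit kernel over $R$ draws, and the
simulated log-likelihood

$$\mathcal{L} = \sum_i \log \frac{1}{R} \sum_r P_i(k_i \mid \beta_r)$$

is maximised. Draws are Halton sequences rather than pseudo-random
uniforms: the base-$b$ radical inverse fills $(0,1)$ with low discrepancy,
so the simulation error shrinks faster in $R$ than Monte Carlo and — more
importantly for estimation — the likelihood surface is deterministic, so
optimisation, standard errors and cross-fit comparisons are exactly
reproducible. The parameters that matter:

* `n_draws` (default 500): draws per observation. 500 is the count used
  for all headline fits; reduced counts (100–150) are adequate for
  replicated simulation studies.
* `primes` (default 2, 3, 5, ...): one base per random dimension, assigned
  in specification order.
* `burn` (default 10): initial sequence points discarded; the first few
  Halton points are strongly patterned.
* `antithetic` (default off): mirrors the second half of each
  observation's draws, halving the distinct points.

One long sequence per dimension is chopped into per-observation blocks and
mapped through the standard-normal quantile function. There is no hidden
random-number-generator state anywhere in the draw path: `halton_draws()`
is a pure function of its configuration.

Setting every $\sigma$, $\delta$, $\omega$ to zero makes every draw
identical, and the simulated log-likelihood equals the closed-form
multinomial-logit log-likelihood to machine precision; the test suite
asserts agreement to 1e-12. This nesting is also used for starting values:
`fit_rpl()` warm-starts the means from `fit_mnl()` with $\sigma = 0.1$ and
all heterogeneity terms at zero.

### Optimisation and uncertainty

The likelihood and its analytic gradient are computed in vectorised form
(per-level $n \times R$ utility matrices, row-wise max subtraction before
exponentiation so large propensities cannot overflow). Optimisation is
BFGS; convergence is declared when the gradient max-norm falls below 1e-5
(within 500 iterations). Because quasi-Newton line searches stall on
round-off before that norm is reached on large samples, the fit finishes
with up to five Newton steps using the numerical Hessian — the same matrix
that supplies the standard errors (inverse observed information). Fits
that end at the iteration cap, or with a coefficient beyond $|15|$
(the symptom of perfect separation or an empty outcome cell — with
three-level severity and rare fatal crashes, small samples hit this
easily), are flagged `converged = FALSE` with a warning, and partial
results are returned rather than discarded.

If a simulated probability underflows it is floored at 1e-300 with a
warning before taking logs; the floor exists to keep a pathological
parameter vector from producing `-Inf` mid-line-search, and is never
active at a well-behaved optimum.

## Temporal-stability likelihood-ratio tests

Whether one model can serve several years of data is tested by parameter
transferability. The pairwise statistic, in both directions,

$$\chi^2 = -2\left[LL(\beta_{y_1 y_2}) - LL(\beta_{y_1})\right],$$

compares the log-likelihood of year-1 data under year-2's converged
parameters against year 1's own fit. The transferred evaluation is a pure
evaluation — no re-estimation — which makes the statistic provably
nonnegative; `evaluate_fixed_params()` regenerates draws from the fit's
Halton configuration at the new data's size, so a fit evaluated on its own
data reproduces its log-likelihood exactly. Degrees of freedom equal the
number of estimated parameters of the transferred model; when per-year
specifications differ (they are configurable), the two directions of a
pair have different degrees of freedom, which is why such tables are
asymmetric in both statistic and df. The joint test compares a pooled fit
against the sum of per-year fits, with df the difference in total
parameter counts.

Results are reported as confidence levels — the $\chi^2$ CDF at the
statistic, `chi2_confidence()` — rather than p-values, so a large
statistic maps to a value near 100% and "stability rejected" means
confidence above a threshold (0.95 by default in `stability_matrix()`).
The test suite validates the CDF against direct numerical integration of
the $\chi^2$ density.

One statistical caveat deserves emphasis. The transferred-parameter
statistic carries the sampling noise of *both* fits: writing the common
truth as $\beta^*$, the statistic decomposes into
$-2[LL(\hat\beta_{y_2}) - LL(\beta^*)] + 2[LL(\hat\beta_{y_1}) -
LL(\beta^*)]$ on year-1 data, each term approximately $\chi^2_p$ under the
null, so for equal year sizes the statistic's null mean is close to $2p$
rather than $p$ — simulation over 200 same-truth year pairs confirms the
mean, with a right tail somewhat heavier still than $\chi^2_{2p}$ in
moderate samples. Referred to $\chi^2_p$ (the field's reporting
convention, which this package follows for its df column), the test
therefore systematically over-rejects a true null at equal sample sizes:
its confidence levels should be read as a graded measure of parameter
instability, not as a size-calibrated hypothesis test. Referring the
statistic to `chi2_confidence(chi2, 2 * df)` removes most, though not
all, of that over-rejection.

## The random-forest baseline

The machine-learning comparator is a bagged ensemble of classification
trees: each tree is grown on a bootstrap resample of the training data
(same size, with replacement), considering a random subset of features at
every split. The subset size follows the square-root rule,
$\lfloor\sqrt{p}\rfloor$, the standard classification default; an explicit
count can be set instead. Feature subsetting per split is the convention
adopted here; tree growing itself is delegated to the randomForest
package, while the vote aggregation, tie rule, tuning and
cross-validation protocol are this package's own and are what the tests
pin down:

* every tree votes with equal weight; `majority_vote()` takes the mode;
* ties break toward the less severe level, the same rule the logit
  classifiers use at equal probabilities (a deliberately conservative
  choice for imbalanced data is not attempted — see limitations);
* the ensemble is deterministic given `forest_config()`'s seed.

Trees use Gini impurity, unlimited depth, minimum leaf size 1. No class
weighting or resampling is applied by default: class imbalance is treated
as a property of the data to be reported, not corrected away silently.

Model assessment uses stratified 10-fold cross-validation: folds are dealt
round-robin within class from one continuing stream, so fold sizes differ
by at most one and each fold's class shares track the global shares as
closely as integer counts allow; every row is predicted exactly once
out-of-fold and the pooled predictions define the cross-validated
confusion matrix. A class with fewer members than folds degrades
stratification and triggers a warning — unavoidable with six-figure PDO
counts and single-digit fatal counts. The number of trees is tuned on the
cross-validated learning curve (`tune_n_trees()`), selecting the accuracy
argmax and preferring the smallest count on ties.

## Cost-based evaluation

A confusion matrix $P_{ij}$ (actual $i$, predicted $j$) summarises a
classifier, and overall accuracy $\sum_i P_{ii} / \sum_i N_i$ is its usual
headline number. With 68% PDO crashes, accuracy is nearly maximised by
predicting PDO everywhere, and it prices a missed fatality the same as a
missed fender-bender. The cost framework corrects both defects. Each level
carries a comprehensive unit cost $CCC_i = ECC_i + QALYCC_i$: observable
economic losses plus the monetised quality-adjusted-life-year loss. The
default table (2017 USD) is PDO 12,456 + 0; injury 46,132 + 97,535; fatal
588,738 + 3,173,900. Re-basing to another price year is a user-supplied
multiplication, not re-derived here. Then

$$AOCC = \sum_i N_i \, CCC_i, \qquad
  POCC = \sum_j \Big(\sum_i P_{ij}\Big) CCC_j,$$

are the actual and predicted overall costs of the evaluation set — row
totals versus column totals, weighted by the actual and the predicted
level's cost respectively — and the error indicators are

$$OPMAE = \frac{|AOCC - POCC|}{N}, \quad
  OPAPE = \frac{|AOCC - POCC|}{AOCC}, \quad
  OPRMSE = \frac{|AOCC - POCC|}{\sqrt N}.$$

These satisfy exact identities ($OPMAE \cdot N = OPRMSE \cdot \sqrt N =
|AOCC - POCC|$; $OPAPE$ invariant to rescaling all unit costs), which the
property suite asserts on randomised matrices. All computation is in raw
USD at full precision; rounding happens only in formatting.
`compare_models(style = "printed")` reproduces the conventional printed
layout: percentages to two decimals, overall costs truncated to integer
USD millions, mean absolute error truncated to integer USD, and the
root-mean-squared error in thousands of USD — such tables are sometimes
labelled "USD millions" for the RMSE column even though their printed
magnitudes correspond to thousands, so the printed style states its units
explicitly and the full-precision style remains the numerical reference.
The truncation (rather than rounding) in the printed style is deliberate:
it is the only convention consistent with published tables of this form,
e.g. an actual overall cost of 209.92 million printing as 209.

A caution when comparing classifiers evaluated on different prediction
sets (say, an out-of-fold cross-validation versus a held-out evaluation):
their actual-cost baselines $AOCC$ differ, so only within-model
indicators, not cross-model cost totals, are comparable.

## The synthetic-data generator

Real multi-vehicle crash extracts from state databases cannot be
redistributed, so every estimator here is validated against synthetic data
drawn from exactly the process the model family assumes: covariates
Bernoulli(prevalence), per-crash coefficient realisations from the
heterogeneity structure, Gumbel propensity errors, severity recorded as
the argmax propensity. Because the truth is known, validation is parameter
recovery, not goodness-of-fit.

`preset_paper_like()` emulates the structure of a two-year state extract:

* about 13,000 crashes over two years (6,500 per year by default);
* thirteen binary covariates in the four characteristic groups; all
  prevalences default to 0.5 — covariate prevalences of real extracts are
  not public, so these are deliberately uncalibrated — except occupant
  restraint use at 0.85, since restraint use is high in practice;
* heavy class imbalance: population shares 68.3% PDO, 31.55% injury,
  0.15% fatal, matching the marginal structure of such extracts;
* one random coefficient (occupant restraints on the injury level, mean
  −1.5, sd 1.0) with a mean shifter (sudden-slowing, $\delta = -0.55$) and
  a variance shifter (middle-aged driver, $\omega = -0.3$); effect sizes
  elsewhere are modest ($|\beta| \le 1.5$), with one strong crash-type
  effect (rear-end, +1.5 on injury) so that the injury level is modal for
  part of covariate space and classifiers have signal to find.

The level constants are not hand-set: `calibrate_constants()` solves for
them deterministically so the population shares implied by the truth hit
the imbalance targets exactly, enumerating all covariate patterns with
their Bernoulli weights and integrating the random coefficient by
Halton-normal quadrature (`expected_shares()`). Multi-year data uses
disjoint random substreams per year, so adding a year never changes an
earlier year's realisations, and per-year additive parameter shifts are
the mechanism for inducing temporal instability — the simplest mechanism
that the pairwise test should detect.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: occupant-level nesting (real extracts have one
row per occupant; the preprocessing module collapses that structure, but
the generator starts at crash level), correlation between covariates,
continuous covariates, spatial correlation, misclassification of severity
by reporting officers, and any non-logit error structure. Recovery results
certify the estimator, not the model's adequacy for any particular
jurisdiction's data.

## Preprocessing conventions

Raw extracts are vehicle-level. The pipeline keeps crashes with at least
`min_vehicles` vehicles — the default is 2, following the convention that
a multi-vehicle crash involves two or more vehicles; analysts using a
stricter three-plus definition set the flag — drops rows missing required
fields (missing tokens configurable; empty string and NA by default, with
police sentinel codes opt-in), keeps the first vehicle's row per crash
(minimal `vehno`, first occurrence on duplicates, with a warning) to avoid
duplicated crash-level information, and collapses five-level police
severity codes to the three analysis levels (O to PDO; C, B, A to I; K to
FI by default — the mapping is explicit and must cover every observed
code). The composition is idempotent and leaves exactly one row per crash.

## Problem sizes used in validation

The shipped test suite validates at sizes chosen to exercise the methods
meaningfully on one CPU: one full-scale recovery fit at n = 10,000 with
500 Halton draws (every mean-structure parameter and the random
coefficient's mean and standard deviation recovered within three standard
errors); a 20-replicate bias study at n = 2,000 with 100 draws (mean bias
of the coefficient means below 0.1); 200-replicate null calibration of the
pairwise stability test at n = 2,000 per year; and forest cross-validation
on the full 13,000-crash preset, required to beat the majority-class
share out-of-fold. Published confusion-matrix counts and the 2017 cost
table are carried as package data, and all printed indicators derived from
them are recomputed exactly by the evaluation functions.

## Known limitations

* Ordered-response and alternative mixing densities are out of scope; the
  mixing density is normal everywhere.
* Specification search (which covariates enter which level, which are
  random) is the analyst's task; nothing is automated.
* The forest baseline does not correct for class imbalance, and with a
  handful of fatal crashes it will typically predict none — visible in
  its all-zero fatal row and in the cost indicators, which is precisely
  the phenomenon the cost framework is designed to expose.
* Standard errors come from the inverse observed information of the
  simulated likelihood; they ignore simulation noise from finite draw
  counts (negligible at 500 Halton draws, but a sandwich correction is
  not implemented).
* Fatal-level parameters are weakly identified in samples with very few
  fatal crashes; expect boundary warnings when fitting small subsets of
  heavily imbalanced data.
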