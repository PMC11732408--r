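---
title: "Models and methods for primate reproductive-ageing demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for primate reproductive-ageing demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senodemog)
```

# The setting

`senodemog` analyses longitudinal event records of wild female primates:
who was observed from when to when, which infants were born and what
became of them, and when males took over social units. Three features of
such data shape every method in the package:

* **Staggered entry (left truncation).** Females enter observation at
  birth or at the onset of their group's study, whichever is later, so
  risk time before entry must not be counted.
* **Right censoring.** Observation ends at death or at study end; final
  interbirth intervals and infant fates are often unresolved.
* **Induced dependence between fertility and infant survival.** An
  infant's death shortens its mother's time to the next birth, so
  intervals following dead infants measure infant mortality, not
  maternal pace.

All calendar arithmetic uses ISO-8601 dates and a fixed 365.25-day year.
Partially known birth dates are carried as point values (flagged
`birth_date_known = FALSE`); propagating their uncertainty is out of
scope.

# Event-processing rules

**Interbirth intervals.** One record per consecutive birth pair (closed)
or per final birth (censored at the mother's departure). An interval is
used only if its opening infant survived the interval: to the subsequent
birth for closed intervals, or to age one for censored ones. The
censored-interval horizon is a design choice — the survival requirement
has to stop somewhere for intervals that never close, and age one is the
dependency window used everywhere else in the package. Mothers enter
each interval's risk set only at the population's minimum observed
closed-interval duration (`entry_offset`), which makes the risk set
honest: no mother can close an interval faster than the fastest interval
ever observed, so earlier "risk time" is vacuous and would dilute the
hazard.

**Cause attribution.** Deaths in the first year are classified by a
deterministic precedence rule: maternal death (death within 90 days
after the mother's disappearance), then infanticide (observed or
inferred male attack for chacma-style populations; death within 180 days
after a takeover of the infant's unit for gelada-style populations),
then injury/illness (signs observed within the 30 days before death),
then unknown. The precedence order follows the order in which the
criteria are conventionally listed; conflicts between windows are rare
and the simulator's ground truth lets users measure how often precedence
(rather than evidence) decides a case.

# Life tables

Yearly age classes `[x, x+1)`. The risk denominator is the number of
females under observation at any point in the class (individual-count
convention); a person-years variant is available via
`convention = "person_years"`, in which case `q_x` and `m_x` become
occurrence–exposure rates. The count convention is the default because
it matches the "proportion of females in each yearly age class" reading
of per-class fertility and keeps the hand-checkable integer identities
(at risk = deaths + censored + continuing) that the tests verify.
Classes with nobody at risk carry `NA` rates, never zero: absence of
evidence is not survival. Survivorship is the cumulative product
`l_{x+1} = l_x (1 - q_x)`, `L_x = (l_x + l_{x+1})/2` (trapezoid), and
the table is truncated at the oldest observed class with no parametric
tail.

Unlike the interval analysis, the life table counts **all** births,
including those hastened by a previous infant's death — the life table
describes realized fertility, not intrinsic pace.

Age-class regressions (`fit_ageclass_glm`) standardize age to mean 0,
sd 1 over represented classes before the quadratic expansion. Because
the published analyses of such data do not state their scaling, raw
coefficient magnitudes are not comparable across implementations; signs
and shapes (e.g. the negative age² term of inverted-U fertility) are the
replicable content.

# Post-reproductive representation

PrR = `T_M / T_B`: post-reproductive person-years over adult
person-years, both expectations taken over the life table. Boundary
conventions, fixed once and verified by an independent enumeration in
the tests: cumulative lifetime fertility `F(x)` uses
survivorship-weighted fertility `l_x m_x` (cohort fertility — a raw
`m_x` weighting is available); adulthood `B` is the first class with
`F ≥ 0.05`; the last reproductive class `M` is the first with
`F ≥ 0.95`; post-reproduction starts at the lower bound of `M + 1`; and
`T_x = Σ_{a ≥ x} L_a`. On the documented toy table
(`make_fixture("prr-toy")`) these conventions give PrR = 1/3 exactly.

**The simulated null.** Observed PrR > 0 is expected even without a
biologically meaningful post-reproductive stage, because fertility and
survival both decline. The null model makes that precise: after the
class of peak fertility, the null birth probability declines in
proportion to survivorship, `m*_x = m_peak · l_x / l_peak`. Each
replicate simulates `n_females` lifespans from the observed `q_x`,
draws births from `m*` among survivors, rebuilds the life table and
recomputes PrR; the p-value is the proportion of replicate PrR values
strictly above the observed one. Degenerate replicates (no fertility, no
adult survivor) score PrR = 0 and are kept.

One estimation detail matters for calibration. If `m_peak` is taken as
the raw maximum of the noisy per-class estimates, it is biased upward —
the argmax of noisy quantities overstates the true maximum (a
winner's-curse effect) — so the null schedule declines from too high a
peak, simulated PrR runs small, and the test rejects too often. In a
calibration experiment with cohorts of 150 females sampled from an
exactly parallel-declining world, the raw-argmax construction rejected
at roughly twice its nominal 5% level, while replicates drawn from the
true schedule were calibrated — isolating peak selection as the cause.
The default therefore estimates the peak level as the exposure-weighted
mean of `m_x` over the argmax class and its two neighbours
(`peak_estimate = "window"`), which restored the nominal rate in the
same experiment; the literal construction remains available via
`peak_estimate = "argmax"`. The null cohort size defaults to the largest
adult at-risk count, a proxy for the number of females ever observed as
adults.

Alternative null constructions can be supplied by computing a schedule
and calling `simulate_null_prr` on a modified table; the acceptance
checks use the packaged default.

# Spline-baseline hazard models

The interval and infant-survival models share one likelihood:

$$\log L = \sum_{\text{events}} \log h(t_i \mid x_i)
  - \sum_i \left[ H(t_i \mid x_i) - H(t_{0i} \mid x_i) \right],
\qquad h(t \mid x) = h_0(t)\, e^{\eta(t, x)},$$

with delayed entry `t_0i` (the interval entry offset; zero for infants).
The baseline `h_0(t) = Σ_k w_k M_k(t)` uses an M-spline basis — each
basis function nonnegative and integrating to one — so nonnegative
weights give a valid hazard and the cumulative hazard is the same linear
combination of I-splines, closed-form. Weights are log-parameterized for
unconstrained optimization.

Defaults, all configurable: cubic baseline with internal knots at the
33rd/67th percentiles of uncensored event times; support from the
smallest entry time to the largest observed time; maternal age
standardized then expanded to linear + quadratic. With time-varying
effects (`tve = TRUE`, used for interbirth intervals where
proportionality fails), each age term's coefficient becomes
`β_j(t) = Σ_l γ_{jl} C_l(t)` on a quadratic B-spline basis with one
internal knot at the median event time, and the cumulative hazard is
integrated numerically by 15-point Gauss–Legendre quadrature per record
(exact knots/weights from the Golub–Welsch eigenproblem). Without
time-varying terms the log-hazard-ratio between two covariate values is
constant in time by construction.

**Inference** is penalized maximum likelihood (MAP): normal(0, 2.5)
priors on covariate and coefficient-spline parameters, normal(0, 5) on
log baseline weights. This reproduces the posterior-mode geometry of the
weakly-informative Bayesian fits such analyses typically use, at
desk-scale runtime; posterior sampling is deliberately out of scope.
Setting a prior sd to `Inf` disables that penalty and recovers plain
maximum likelihood — the configuration in which the degree-0,
single-span model provably collapses to the exponential MLE
`ĥ = events / exposure` (verified to 1e-6 relative in the tests).

Numerical choices: multi-start BFGS (5 starts by default; the first from
a constant-hazard initializer with `Σ w_k = ĥ · span`, the rest jittered
with sd 0.5 under the fit's seed; best objective wins, ties to the
lowest start index); relative tolerance 1e-12; per-parameter `parscale`
proportional to inverse design-column scales, without which raw-age
quadratics (column scale ~10²) stall the line search. A nonpositive
hazard at an event time yields an infinite objective rather than an
error, so the optimizer simply retreats. Standard errors come from the
inverse observed-information (numerical Hessian) at the optimum;
singular information flags the affected standard errors as `NA`.

**Random intercepts** (mother, study year, unit) are Gaussian-penalized
per-group offsets, off by default. Their standard deviation is profiled
on a 10-point log-spaced grid using a Laplace-approximate marginal —
the joint objective at the mode plus half the log-determinant of the
offset-block curvature (diagonal approximation). The curvature term is
essential: the joint mode over offsets and their sd degenerates to
sd → 0 without it. A single sd is shared across grouping factors; full
crossed random-effects inference is out of scope.

# Cause-specific mortality models

Each cause is a separate MAP logistic regression (died of this cause
vs. did not) on standardized maternal age and age², restricted to
fate-known infants (deaths, or survival to age one) — censored infants
carry no cause information and would bias all four models toward zero.
Priors are normal(0, 1) on the age terms (weakly informative), with an
unpenalized intercept: penalizing the intercept would drag rare-cause
baseline rates toward 1/2 and, through the resulting misfit, leak
spurious curvature into the age terms (visible in the constant-outcome
degenerate case, which with a flat intercept correctly shrinks the age
terms to zero). Birth-year intercepts are penalized offsets profiled the
same way as the hazard models'. With `prior_sd = Inf` the fit matches
`glm`'s IRLS solution, which the tests use as an independent oracle.

The mortality decomposition assigns tertiles by maternal age over
**all** infants (not only deaths), with boundary ties going to the lower
tertile, and reports per-cause shares overall and within tertiles.

# The simulator

`simulate_population` generates the world the estimators assume, with
known ground truth: Siler (bathtub) mortality
`h(t) = a1 e^{-b1 t} + a2 + a3 e^{b3 t}` sampled exactly by inverting
the closed-form cumulative hazard; conception as a thinned Poisson
process with log-hazard quadratic in standardized age, gated by
maturation, gestation (0.5 yr) and postpartum anoestrus that is waived
the moment the infant dies; per-unit Poisson takeovers, each killing a
dependent infant (< weaning age) with probability `p_infanticide` at a
time inside the 180-day attribution window; orphaning deaths within the
90-day window with probability `p_orphan_death` when the mother dies
during the infant's first year; and competing-risk resolution by
earliest event. Event times are continuous and recorded to day
resolution. A fraction of founders enters mid-life (left truncation);
daughters born in-study are tracked recursively, so life tables have
infant classes.

The presets were calibrated once, analytically plus a Monte-Carlo check,
to land in realistic regimes: `"chacma-like"` — one large group split in
two units, frequent takeovers, first-year mortality near 35% with
roughly half of infant deaths infanticidal, minimum interval near 1.0 yr
and mean closed intervals near 2 yr; `"gelada-like"` — many small
one-male units, first-year mortality near 15%, about a third of deaths
infanticidal, minimum interval near 1.06 yr and mean near 2.5 yr.

What the simulator does **not** emulate: fetal loss after takeovers (the
Bruce effect), male life histories and dispersal, environmental
year effects, age-dependent infanticide vulnerability beyond the weaning
cutoff, unit transfers, and birth-date uncertainty. Passing tests on
simulated data therefore show the estimators are correct under the
stated generating mechanism — left truncation, censoring,
death-hastened fertility, windowed cause evidence — not that real
populations satisfy that mechanism.

# Validation scale

The checks run at sizes chosen to balance Monte-Carlo precision against
a desk-scale runtime: 50 replicate datasets of 500 intervals for
age-effect recovery (bias within three Monte-Carlo standard errors;
95% CI coverage at least 85%), 100 datasets of 150 females with 1000
null replicates each for PrR calibration (rejection between 2% and 10%
at α = 0.05), 600 records for the time-varying sign-reversal detection
(the fitted `β(t)` must cross zero between years 2 and 3 when the truth
crosses at 2.5), and three isolated-channel simulations for exact cause
attribution. `scripts/acceptance.R` recomputes all of them from scratch
under a caller-supplied seed.

# Known limitations

* Uncertainty is curvature-based (Wald); no posterior intervals or
  profile likelihoods.
* The PrR p-value inherits the finite-cohort noise of its null
  replicates; with very small populations the test is low-powered, and
  the null construction is this package's concrete instantiation of
  "parallel decline" rather than a canonical standard.
* The life-table count convention undercounts exposure for females
  observed only part of a class; the person-years variant trades that
  for rate (not probability) semantics.
* Random-intercept variances come from a coarse profile grid with a
  diagonal Laplace correction — adequate for shrinkage, not for
  inference on the variance itself.
* `m_x` can exceed 1 in yearly classes if a female gives birth twice
  within a class; the binomial age-class regression caps successes at
  the risk count and warns.
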