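---
title: "Estimating the proximate determinants of fertility from survey microdata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the proximate determinants of fertility from survey microdata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxfert)
```

## The model

The aggregate fertility model treats the total fertility rate as total
fecundity TF scaled down multiplicatively by four indices, one per
proximate determinant:

$$\mathrm{TFR} = C_m \, C_c \, C_i \, C_a \, \mathrm{TF}, \qquad
\mathrm{TF} = 15.3.$$

Each index lies in $[0,1]$; 1 means the determinant inhibits no
fertility. TF = 15.3 births is the conventional biological maximum,
derived from the highest-fertility historical populations: continuous
union from 15, no contraception, no breastfeeding, no abortion. The model
is an accounting identity once the indices are defined, which makes it
attractive for decomposition: differences in fertility between
socioeconomic groups must show up in one or more indices.

The four indices and the estimators this package uses:

* **Marriage.** $C_m = \sum_a m(a)\,g(a) \,/\, \sum_a g(a)$ over the seven
  5-year age groups, where $m(a)$ is the weighted proportion of women
  currently married (formal or consensual union pooled at ingest) and
  $g(a)$ the age-specific *marital* fertility rate. Weighting $m(a)$ by
  $g(a)$ matters because married women in the central childbearing ages
  contribute most to the TFR. The ratio TFR/TMFR is available as
  `cm_method = "ratio"`; the two coincide exactly when all fertility is
  marital ($f(a) = m(a)\,g(a)$), a property the test suite checks to
  $10^{-9}$ on schedules constructed to satisfy it. On real data they
  differ wherever nonmarital childbearing exists, and the weighted-sum
  form is the default because it remains interpretable in that case.

* **Contraception.** $C_c = 1 - 1.08\,u\,e$: $u$ is the weighted
  prevalence of *any* current method among married women and $e$ the
  weighted mean use-effectiveness over users' methods; 1.08 corrects for
  sterile women who do not contracept. Counting traditional methods in $u$
  (each at its own effectiveness) rather than modern methods only is a
  deliberate choice: every method in the mix inhibits some fertility, and
  the published national index values for the bundled worked example are
  consistent with any-method prevalence, not modern-only. The
  effectiveness schedule is not identified from survey data, so the
  package ships the standard use-effectiveness defaults (sterilization
  1.00, IUD 0.95, pill/injection/implant 0.90, condom/diaphragm/foam-
  jelly/LAM 0.70, traditional 0.50), overridable per method in the config
  file.

* **Postpartum insusceptibility.** $C_i = 20/(18.5 + i)$, $i$ the mean
  months of postpartum insusceptibility. The constants come from the
  natural birth-interval decomposition: 1.5 months minimum anovulation +
  7.5 waiting + 2 intrauterine mortality + 9 gestation = 20 months without
  breastfeeding, and $18.5 + i$ with it. The default estimator of $i$ is
  current-status prevalence/incidence: the weighted number of women
  currently amenorrheic-or-abstaining divided by mean monthly births over
  the reference window. Under a stationary birth process the expected
  number of women in a state is (entry rate) × (mean duration), so the
  ratio is a consistent estimator of mean duration without asking women to
  recall durations. A `reported_duration` alternative averages an optional
  duration column. Whether "insusceptible" means amenorrhea alone or
  amenorrhea-or-abstinence is a survey coding choice; the schema carries a
  single current-status boolean and either definition can be mapped onto
  it at ingest.

* **Abortion.** $C_a = \mathrm{TFR}/(\mathrm{TFR} + 0.4(1+u)\,TA)$, where
  $0.4(1+u)$ is the births averted per induced abortion. The default
  configuration sets the total abortion rate $TA = 0$, hence $C_a = 1$:
  in the settings this model is typically applied to, abortion data are
  absent or unreliable. The formula stays implemented and tested for
  nonzero $TA$.

## Rates from birth histories

Age-specific rates are computed from retrospective birth histories with
person-month exposure. All dates are integer month indices
(century-month codes), so exposure arithmetic is exact integer work with
no calendar edge cases. For a window of $W$ months (default 36, the
standard DHS reporting window for current fertility):

* each woman contributes 1/12 person-year × her weight to the age group of
  her completed age (floor of age in months / 12) in each of the months
  $[\text{interview} - W, \text{interview} - 1]$; months at completed ages
  outside 15–49 are dropped;
* births with lag 1 … $W$ months before interview are attributed to the
  mother's completed-age group *at the birth*;
* rates are weighted births over weighted exposure per group, TFR = 5 ×
  the group sum. Age bins are closed on the left: [15,20), …, [45,50).

Marital fertility classifies births by the mother's *current* marital
status, the standard approximation when the schema carries no marriage
histories; it misclassifies births to women who married or separated
inside the window, a known bias flagged here rather than corrected.

Degenerate inputs are handled conservatively: a zero-exposure age group
yields rate 0 with a warning (so one empty cell does not abort a stratified
run); an index outside $[0,1]$ — e.g. $C_i > 1$ when $i < 1.5$ — is
returned as-is with a warning, never clamped, because out-of-range values
are diagnostic of data problems. Undefined indices (no married women, no
births in the window, $\sum g(a) = 0$) are errors naming the cause; in a
decomposition they become per-stratum flags instead of failures.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: it
generates one-row-per-woman tables whose true parameters are known, so the
estimators can be validated end to end. Per woman it draws a 5-year age
group and a uniform age within it, current marital status from a per-group
schedule, current method use (probability `u_true` among married women,
method from `method_mix`), and independent categorical stratifiers; it
then simulates her reproductive history month by month from exact age 15
to the interview through exposed / pregnant (9 months) / postpartum
insusceptible states. Conception probability per exposed month is
`fecundability × (1 − e_method)`, scaled by `nonmarital_exposure_factor`
(default 0) for unmarried women. Insusceptible durations are geometric
(discrete, memoryless, support 0, 1, 2, …) with mean
`insusceptibility_mean` — the simplest distribution with a controllable
mean, and exactly the setting the current-status estimator assumes; the
sampler is a small internal function and could be swapped.

Defaults emulate a high-fertility East African DHS sample: the age
distribution and marriage schedule approximate the Uganda 2011 women's
sample (about 62% currently married overall), `u_true = 0.30` with an
injection-heavy method mix (mix-weighted mean effectiveness 0.78),
`insusceptibility_mean = 11.5` months, `fecundability = 0.2` per month (a
standard natural-fecundability figure for women in union), and
Uganda-2011-like stratifier marginals. Per-category overrides let an
analysis plant gradients, e.g. education-dependent prevalence.

What the generator deliberately does **not** emulate: marriage *histories*
(status is drawn once, so currently-married women are exposed from age 15
— their realised fertility is higher than any real cohort's), age-varying
fecundability and sterility, union dissolution, mortality, multi-stage
survey design (all weights are 1), and the 1.5-month anovulation floor,
the 7.5-month mean wait and spontaneous intrauterine mortality baked into
the index constants. The last point means the generator's *observed* TFR
systematically exceeds $C_m C_c C_i C_a \cdot 15.3$: with fecundability
0.2 the mean wait to conception is 5 months and there is no fetal loss, so
simulated birth intervals are shorter than the natural-fertility intervals
the constant TF = 15.3 encodes. Passing recovery tests therefore shows
that $u$, $e$, $i$ and the indices built from them are estimated
correctly from microdata of this shape — not that the model's constants
describe the generator, nor that real DHS data would behave identically
(real data add weighting, recall error, displacement and omission of
births, none of which are simulated).

## Problem sizes and tolerances

The validation suite uses cohorts of 200–800 women for exact oracle
checks (every schedule is compared to an independent per-woman per-month
brute-force loop at $10^{-12}$), 2000 women × 20 seeds for parameter
recovery (observed mean absolute errors: $u$ within 0.02, $C_c$ and $C_i$
within 0.03, $i$ within 1 month of truth), 5000 draws for the
duration-sampler mean, and 6000 women for the planted education gradient.
These sizes put Monte Carlo error well below the tolerances while keeping
the whole suite in seconds. The analysis scripts use 8000 women, the
scale of a single-country DHS women's sample.

The current-status estimator of $i$ carries a small upward finite-sample
bias here (~0.3–0.4 months at these sizes): women who turn 15 inside the
window enter exposure mid-window, so the window-average birth rate in the
denominator slightly understates the rate prevailing at interview. It is
well inside the ±1 month tolerance and vanishes as the window shrinks
relative to the reproductive span.

## Rendered output conventions

Decomposition tables print indices to 6 decimals and TFRs to 1 decimal
with half-up rounding (R's own `round()` is half-even), matching the
precision conventional in published decomposition tables; percentages in
descriptive tabulations are weighted and sum to 100 within rounding.
Education is re-binned to {none, primary, secondary+} for decomposition
while ingest keeps four levels; missing stratifier values form an explicit
`"(missing)"` category reported alongside the others.

## Limitations

Beyond the generator's simplifications above: the model omits pathological
sterility (the fifth determinant of the extended model) and the
age-specific variant; no survey-design variances or between-stratum tests
are computed; current-status marital classification biases marital
fertility where unions are unstable; and native DHS recode files (.dta,
.sav) must be exported to CSV (a `column_map` argument handles renamed
columns, but unit conversions such as the DHS weight scaling by 1e-6 are
the caller's responsibility).
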