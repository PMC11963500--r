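---
title: "Modelling maternal mortality under intervention coverage scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling maternal mortality under intervention coverage scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mmrimpact)
```

## The problem

The maternal mortality ratio (MMR, maternal deaths per 100,000 live
births) has stagnated in many low- and middle-income countries (LMICs)
since around 2015, and most LMICs are not on track for SDG Target 3.1
(MMR below 70 by 2030). A standard way to ask "what would scaling up
maternal health services buy?" is the Lives Saved Tool (LiST) family of
cohort models: deaths are split by cause, each intervention acts on the
causes it can avert with a known efficacy, and scenario-specific coverage
trajectories convert coverage gains into deaths averted.

`mmrimpact` implements that arithmetic for fourteen maternal health
interventions spanning the periconceptual period (safe abortion
services), pregnancy (tetanus toxoid, micronutrient supplementation,
hypertensive disorder case management) and childbirth (ten interventions
from clean birth environment to blood transfusion), together with the
trend analysis used to diagnose stagnation (joinpoint regression with
annual percent changes) and a seeded synthetic country-panel generator
for testing the whole pipeline.

## The impact model

For a single intervention acting on one cause the model is a literal
product:

$$\widehat{\mathrm{MMR}} = \mathrm{MMR}\,\bigl(1 - s_c\, \Delta v\, e\, f\bigr),
\qquad
L = B \cdot \frac{\mathrm{MMR}}{10^5}\, s_c\, \Delta v\, e\, f,$$

where $s_c$ is the cause's share of maternal deaths, $\Delta v$ the
intervention's coverage change relative to the 2024 baseline, $e$ its
efficacy against the cause, $f$ the affected fraction (the share of the
cause's deaths the intervention can plausibly act on), $B$ annual live
births and $L$ the additional maternal lives saved. The two formulas are
algebraically linked: $L = (\mathrm{MMR} - \widehat{\mathrm{MMR}})\,B/10^5$,
a property the test suite checks on random inputs.

**Multi-intervention combination.** The printed formulas cover one
intervention. When several interventions act on the same cause we combine
them multiplicatively on residual deaths,
$D_c^{\mathrm{res}} = D_c \prod_i (1 - e_{ic})$ with
$e_{ic} = \Delta v_i\, e_i\, f_{ic}$ — the standard residual cascade in
LiST-style models. It guarantees non-negative residuals for any registry
and is order-independent. Per-intervention attribution rescales the
independent savings $D_c\,e_{ic}$ proportionally so they sum exactly to
the cause's total deaths averted; for a single intervention this
degenerates to the printed lives-saved formula. Conservation
($\sum$ residual deaths $+$ $\sum$ lives saved $=$ baseline deaths) is
asserted to $10^{-6}$ across the whole synthetic panel.

**Background mortality.** In the scenario projections the
non-intervention component of MMR is held at its 2020 value ("coverage
changes, MMR otherwise unchanged"). Only the sensitivity mode
(`sensitivity_project()`) moves MMR along the 2015–2020 APC,
$\mathrm{MMR}_{2020}(1 + \mathrm{APC}/100)^{y-2020}$.

## Causes and interventions

The cause taxonomy is closed: antepartum, intrapartum and postpartum
hemorrhage, hypertensive disorders, sepsis, abortion, other direct and
indirect causes. Aggregate hemorrhage shares are decomposed with the
fixed 24% / 3% / 73% split (`decompose_hemorrhage()`), and replacing an
aggregate share by its components never changes the profile total.
Unknown cause labels are errors, never dropped silently, because the
model indexes deaths by cause.

The bundled intervention registry reproduces the *structure* of the LiST
effectiveness database — fourteen interventions with per-cause efficacy
and affected fraction — but its numeric values are **placeholders**
(efficacies spread over 0.5–0.9, affected fractions 1.0, plausible cause
mappings; the file is named `interventions_placeholder.json` to make this
unmissable). Published effectiveness values live in the LiST database and
are not redistributed here; substantive analyses must supply their own
config via `read_interventions()`. All shares, coverages and efficacies
are fractions in $[0,1]$ internally; percent appears only at I/O
boundaries, which removes an entire class of 100× unit bugs.

## Scenarios

Four built-in scenarios span 2024 (baseline) to 2030 (horizon):

| id | rule | parameters |
|----|------|------------|
| 0 | constant | coverage held at baseline |
| 1 | annual increment | +2 pp/year, capped at 100% |
| 2 | annual increment | +5 pp/year, capped at 100% |
| 3 | endpoint target | linear ramp to 95% coverage by 2030 |

"Increased by 2% per year" is read as absolute percentage points per
year: that is the reading under which a hard cap at 100% does binding
work, and it matches the scale-up convention of LiST-style analyses. The
relative-growth reading (`increment_type = "relative"`) is available for
sensitivity checks. Endpoint-target trajectories never *reduce* coverage:
a baseline already above 95% stays where it is, so scenario 3 coincides
with scenario 0 for such interventions. These choices give the invariants
the tests enforce: trajectories are non-decreasing in year, changes are
ordered $S_0 \le S_1 \le S_2$ and $S_3 \ge S_0$, and estimated MMR is
monotone $\mathrm{MMR}(S_3) \le \mathrm{MMR}(S_2) \le \mathrm{MMR}(S_1)
\le \mathrm{MMR}(S_0)$ for every generated country.

## Joinpoint trend analysis

`fit_joinpoint()` fits continuous piecewise-linear models of
$\ln \mathrm{MMR}$ on calendar year — the standard joinpoint
formulation — with breakpoints constrained to observed years, at least 3
observations per segment (the breakpoint year counts for both adjoining
segments) and at most 3 breakpoints, which is as much structure as 21
annual observations can support. Within each breakpoint count the
placement minimizing the residual sum of squares is found by exhaustive
enumeration, so the search itself is exact and deterministic. The annual
percent change of a segment with slope $b$ is $(e^b - 1)\cdot 100$, and
the average APC over a year range is the segment-length-weighted
geometric mean
$\mathrm{AAPC} = \bigl(\exp(\sum_s w_s b_s / \sum_s w_s) - 1\bigr)\cdot 100$.

**Breakpoint-count selection.** Selecting the *number* of joinpoints is
the delicate part. Because the likelihood is maximized over hundreds of
candidate placements, the apparent gain from one more joinpoint is the
maximum of many correlated improvements, and fixed-penalty information
criteria systematically understate it: on synthetic panels at the noise
level the generator emulates, BIC admitted spurious joinpoints on a
majority of series, and even the harsher variants that charge two or
three parameters per joinpoint stayed above a 5% spurious-selection
rate. The package instead uses a sequence of likelihood-ratio tests of
$k$ versus $k_{\max}$ breakpoints: the deviance gain
$n \log(\mathrm{RSS}_k / \mathrm{RSS}_{k_{\max}})$ is compared with a
chi-squared threshold with $2(k_{\max} - k)$ degrees of freedom,
Bonferroni-corrected for the number of placements searched and the
number of tests in the sequence (test size $\alpha = 0.05$). Two details
matter:

* Testing against $k_{\max}$ rather than $k+1$ avoids the stepwise blind
  spot where two opposite-direction slope changes nearly cancel in any
  single-knot model, which makes a purely sequential $k$ vs $k+1$
  procedure stop too early.
* A perfect (noiseless) fit's RSS is floored at $10^{-12}$, so nested
  perfect fits show zero deviance gain and parsimony selects the
  smallest adequate model; this also keeps the fit exactly invariant to
  rescaling the MMR series by a positive constant.

The procedure is deterministic, runs in ~30 ms per series, and on 200
generator-default series (noise sd 0.005 on the log scale, segments of
at least 6 years, adjacent-segment APC gaps of at least 2 points)
recovers breakpoint years exactly with segment APCs within 0.2
percentage points in 98–100% of series depending on seed, with no
systematic over- or under-selection.

**Trend classification.** Whether a country's decline has stalled is
judged against a fixed 2015 pivot: single segments are refit to the
2015–2020 and 2000–2015 windows regardless of where the selected
joinpoints fall, so the pivot is honored even when no breakpoint lands
on 2015. The trend is *increasing* if the post-2015 APC is positive,
*stalled* if it is non-positive but strictly less negative than the
pre-2015 average decline, and *declining* otherwise.

## Uncertainty intervals

The 2020 MMR's 80% UI is a normal approximation,
$\mathrm{MMR} \pm z_{0.9}\,\mathrm{se}$ with $z_{0.9} \approx 1.2816$
(10th/90th percentiles), floored at a small positive value. Projected
UIs scale both bounds by the ratio of estimated to baseline MMR — the
simplest propagation consistent with deriving 2030 intervals from the
2020 interval. It preserves the interval's relative width; a Monte-Carlo
check confirms the nominal 80% coverage of `ui_from_se()` within ±3
points over 1,000 draws.

## The synthetic panel generator

`generate_panel()` emulates the *structure* of the inputs the analysis
consumes, without imitating any real country:

* **Composition.** 126 countries allocated over 6 WHO regions × 3 World
  Bank income groups with counts resembling the LMIC composition
  (AFR 46, AMR 17, SEAR 10, EUR 17, EMR 16, WPR 20).
* **MMR levels.** 2020 values uniform within income-group bands (low:
  300–700; lower-middle: 70–400; upper-middle: 10–170 per 100,000),
  magnitudes consistent with reported regional strata.
* **Trends.** Piecewise log-linear 2000–2020 with 0–2 breakpoints
  (probabilities 0.35/0.40/0.25), segment APCs uniform in [−8%, +3%],
  segments at least 6 years, and adjacent-segment APC gaps of at least
  2 points so that breakpoints are statistically identifiable — a
  recovery benchmark with unidentifiable kinks would measure nothing.
* **Noise.** Log-normal observation noise (sd 0.01 on the natural-log
  scale by default), conjugate to the log-linear fitted model.
* **Cause shares.** A Dirichlet draw over six aggregate causes
  (concentration 3.7, 3.0, 1.8, 1.6, 4.4, 5.5 for hemorrhage,
  hypertensive disorders, sepsis, abortion, other direct, indirect),
  with hemorrhage then decomposed by the fixed 24/3/73 split. Mean
  shares resemble the reported pattern in which hypertensive disorders
  and postpartum hemorrhage lead among specific causes.
* **The rest.** Coverage uniform in [0.2, 0.9] per intervention; live
  births log-uniform between 20 thousand and 5 million; the 2020 MMR's
  relative standard error 0.08.

Each country draws from its own substream whose seed is a deterministic
function of (seed, index), so records are bit-identical regardless of
generation order — the panel is a multiset invariant under permutation,
which the tests check directly.

What passing tests on this panel do **not** show: real MMR series have
non-normal, serially correlated estimation error, country-specific
revision histories and shocks (conflict, COVID-19); real cause profiles
and coverage are correlated with income and with each other; and real
intervention effectiveness values differ from the placeholders. The
synthetic results validate the *arithmetic and its invariants*, not any
substantive claim about actual countries.

## Numerical choices and degenerate inputs

* Cause shares must sum to 1 within $10^{-9}$; the hemorrhage split
  reconstitutes its aggregate to $10^{-12}$.
* `fit_segment()` needs ≥ 2 observations, `fit_joinpoint()` ≥ 7; a
  series too short for any admissible breakpoint returns the
  0-breakpoint fit with a warning flag rather than an error.
* Ties in model selection resolve toward fewer breakpoints.
* A zero-width baseline UI propagates to a zero-width projected UI;
  `ui_from_se(mmr, 0)` is the degenerate interval at the point estimate.
* Scenario trajectories clamp to $[0,1]$ and are floored at baseline.

## Problem sizes

The shipped test-suite and acceptance runs use the full 126-country
panel for projection invariants, 200 series for joinpoint recovery, 20
series for brute-force oracle agreement, 1,000 draws for the
Monte-Carlo UI coverage check and 1,000 random inputs for the formula
identity — sizes at which every property is sharp while the whole suite
completes in well under a minute on a single CPU.

## Known limitations

* The multi-intervention combination rule and the proportional
  attribution are modelling conventions; other defensible rules
  (e.g. sequential attribution) give different per-intervention splits,
  though identical totals.
* Percent reduction is defined against scenario 0 explicitly; published
  scenario tables sometimes use other comparators, so cross-study
  comparisons of "reduction (%)" columns need care.
* Live births are held constant over the projection window; no
  demographic projection is attempted.
* The joinpoint selection controls spurious-joinpoint probability at
  $\alpha = 0.05$ per series under Gaussian log-scale noise; heavier
  tailed noise would inflate it.
* The placeholder effectiveness values make absolute projected MMRs
  illustrative only; relative scenario orderings and every conservation
  property hold for any valid registry.
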