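# mmrimpact

Scenario projections of the maternal mortality ratio (MMR) under
intervention coverage scale-up in low- and middle-income countries
(LMICs), for epidemiologists and health planners who want the Lives
Saved Tool (LiST) style maternal-mortality arithmetic as a tested,
scriptable R package rather than a GUI workflow.

Many LMICs have stalled on MMR reduction since 2015 and are off track
for SDG Target 3.1 (MMR below 70 per 100,000 live births by 2030). The
package answers two questions about a country panel:

1. **What happened?** Joinpoint regression on log-MMR 2000–2020 with
   annual percent changes (APC), average APC (AAPC), and a
   stalled/increasing/declining classification against a fixed 2015
   pivot.
2. **What would scaling up services buy?** A cause-and-intervention
   impact model over eight causes of maternal death and fourteen
   maternal health interventions, projected to 2030 under four coverage
   scenarios, with 80% uncertainty intervals and births-weighted
   regional aggregation.

## The model

For one intervention acting on one cause of death:

    estimated MMR = MMR × (1 − cause share × coverage change
                               × efficacy × affected fraction)
    lives saved   = live births × MMR/100,000 × cause share
                               × coverage change × efficacy × affected fraction

Multiple interventions acting on a cause combine multiplicatively on
residual deaths, `D_c × Π_i (1 − e_ic)`, and each cause's deaths averted
are attributed to interventions in proportion to their independent
savings. Coverage trajectories come from four scenarios: no scale-up,
+2 percentage points/year (capped at 100%), +5 pp/year (capped), and a
linear ramp to 95% coverage by 2030. Joinpoints are placed by exhaustive
search over observed years and their number chosen by Bonferroni-corrected
likelihood-ratio tests; the trend of a segment with log-scale slope `b`
is reported as `APC = (exp(b) − 1) × 100`.

The bundled per-intervention efficacy/affected-fraction values are
**placeholders** (see `inst/extdata/interventions_placeholder.json`);
supply real effectiveness values via `read_interventions()` for
substantive work. A seeded synthetic panel generator
(`generate_panel()`) emulates the structure of the WHO/GBD/LiST inputs
for testing and examples.

## Worked example

```r
library(mmrimpact)

panel <- generate_panel(panel_config(n_countries = 4, seed = 7))
rec <- panel$records[["XAB"]]
rec
#> Country XAB (AFR, low income): MMR 2020 = 461.6 (80% UI 414.3-508.9), 973,957 live births

summary(fit_joinpoint(rec$series))
#> Joinpoint fit: 21 observations 2000-2020, 1 breakpoint(s) at 2012
#> Segments (APC in %):
#>   start  end  slope    apc
#> 1  2000 2012 -0.047 -4.632
#> 2  2012 2020 -0.008 -0.770
#> AAPC 2000-2020: -3.11%
#> Breakpoint-count selection (sequential LR tests):
#>   breakpoints   rss placements deviance_gain threshold selected
#> 1           0 0.070          1        97.730    30.161        0
#> 2           1 0.002         17        17.489    25.685        1
#> 3           2 0.001        120            NA        NA        0
#> 4           3 0.001        455            NA        NA        0
#> Trend since 2015: stalled (APC post -1.04%, pre -4.16%)
```

This synthetic country fell at 4.6%/year until 2012 and at only
0.8%/year since — its post-2015 decline is slower than its pre-2015
decline, so it is classified as *stalled*. Projecting the substantial
scale-up scenario (+5 pp coverage/year):

```r
project(rec, builtin_scenarios()$s2, default_intervention_registry())
#> XAB, scenario 2, 2030: MMR 276.50 (80% UI 248.15-304.85), 1802.9 lives saved/yr, -40.10% vs no scale-up
```

Scaling every intervention's coverage up by 5 points per year would cut
this country's MMR from 461.6 to 276.5 by 2030 (a 40% reduction,
uncertainty interval scaled from the 2020 interval) and avert about
1,800 deaths in 2030 — though with the placeholder effectiveness values
these magnitudes are illustrative, not estimates. The whole pipeline is
also available as shell stages (`run_simulate()`, `run_fit_trends()`,
`run_project()`, `run_report()`, or `inst/cli/mmrimpact.R`).

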