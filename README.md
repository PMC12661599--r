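# fpecon

Health-economic modelling of facial palsy care and of telerehabilitation
added to the facial neuromuscular retraining (fNMR) pathway.

Facial palsy is the most common single-nerve disorder; roughly 30% of
patients recover incompletely and live with long-term reductions in
quality of life. `fpecon` packages the building blocks of a UK economic
evaluation of this condition for health economists and HTA analysts:

- **Budget impact** — line-item cost ledgers (activity, volume, unit
  cost, slash-path category), NHS-style inflation re-indexing, category
  subtotals, grand totals and percentage shares.
- **Morbidity burden** — time in recovery state, QALY losses
  `cases × years × utility decrement`, monetisation with the NICE
  willingness-to-pay band (£20,000–£30,000 per QALY) as low/high money
  intervals, and flat per-case societal cost add-ons.
- **Cost-effectiveness** — a decision-analytic tree engine: validation,
  joint-probability path enumeration, rollback of expected costs and
  House-Brackmann (HB) grade effects, dominance classification
  (`dominant` / `dominated` / `tradeoff_icer` / `equivalent`), ICER
  ΔC/ΔE and net monetary benefit `WTP·ΔE − ΔC`, break-even device
  pricing, and cohort scaling.
- **Delphi consensus** — modal-agreement scoring of expert rating
  panels, ex-ante consensus thresholding (inclusive at the boundary),
  multi-round carry-forward, response rates.
- **Synthetic data + study fixtures** — seeded generators for ledgers,
  two-arm trees and rating panels, plus the published UK study tables as
  typed objects (`study_fixtures()`).

Everything is tidyverse-native: functions take data frames first and
return tibbles, results have `tidy()` / `glance()` / `autoplot()`
methods.

## The model in brief

A strategy is a tree of chance nodes ending in terminal payoffs
`(cost, effect)`. For terminal node *j* reached with joint probability
`p_j` (the product of branch probabilities along its pathway), the
strategy's expectations are

```
E[C] = upfront_cost + Σ_j p_j · cost_j        E[B] = Σ_j p_j · effect_j
```

Comparing intervention *a* with comparator *b*: ΔC = E[Cₐ] − E[C_b],
ΔE = E[Bₐ] − E[B_b]. ΔC < 0 with ΔE > 0 is *dominant* (no ICER
reported); otherwise the ICER is ΔC/ΔE. Because E[C] is affine in the
device price with slope equal to the probability of incurring the
device, the break-even price is `price − ΔC / device_probability`.

## Worked example

```r
library(fpecon)

fx <- study_fixtures()

gbp_millions(grand_total(fx$treatment_ledger))
#> [1] 86.98   # annual UK treatment cost, GBP millions

cea <- compare_strategies(fx$cea$with_frame, fx$cea$without_frame)
cea
#> Cost-effectiveness comparison (with Frame vs without Frame)
#> # A tibble: 2 × 3
#>   label         expected_cost expected_effect
#>   <chr>                 <dbl>           <dbl>
#> 1 with Frame            1095.            1.26
#> 2 without Frame         1563.            1.12
#> incremental cost -467.69 GBP, incremental effect +0.136
#> dominance class: dominant
#> NMB at WTP 20000: 3187.69 GBP

round_half_up(break_even_price(fx$cea$device_price, cea$delta_cost))
#> [1] 964    # device price at which the saving vanishes, GBP
```

The telerehabilitation arm costs £467.69 less per patient and gains
0.136 HB grades, so it is dominant; the smart-glasses price could rise
from £495.83 to £964 before the pathways break even on cost.

The whole published analysis — budget totals and shares, QALY losses,
burden intervals, incrementals, break-even, cohort savings, Delphi
summary — is re-run and checked line by line against the printed
figures with:

```r
glance(reproduce_analysis())
#> # A tibble: 1 × 5
#>   n_checks n_matched n_flagged dominance ok
#>      <int>     <int>     <int> <chr>     <lgl>
#> 1       33        26         7 dominant  TRUE
```

The 7 flagged lines are figures that are internally inconsistent in the
source tables (independently rounded cells); `tidy(reproduce_analysis())`
shows each with its explanation. `render_report()` writes the same
content as CSV, JSON and plain text.

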