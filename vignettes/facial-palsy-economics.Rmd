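---
title: "Methods: economic modelling of facial palsy telerehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: economic modelling of facial palsy telerehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpecon)
```

`fpecon` implements the three layers of a national economic evaluation of
facial palsy: a budget-impact analysis of the annual treatment cohort, a
long-term morbidity-burden model for unresolved cases, and a
decision-analytic comparison of the face-to-face fNMR (facial
neuromuscular retraining) pathway with a telerehabilitation pathway in
which smart glasses support home exercises. A Delphi modal-consensus
scorer supplies the monetary valuation of clinical recovery, since trials
in this field report House-Brackmann (HB) grades rather than utilities.
This vignette records the models, their assumptions, the parameters that
matter, and the design decisions taken where the design was genuinely
open.

## Budget impact

A cost ledger is a tibble of line items: annual `volume` × `unit_cost`
(GBP, at a stated financial price-year), with a slash-delimited
`category` path such as `medical/primary-care`. Aggregation is by
category *prefix*: `subtotal(ledger, "medical")` sums everything under
`medical/`, which is the simplest scheme that reproduces two-level table
subtotals. All arithmetic is carried at full double precision; rounding
is applied only at presentation, with `round_half_up()`. This matters
because published table cells are independently rounded: summing rounded
cells reproduces some printed totals but not others, so the package
computes exact sums and *flags* cells that cannot be reconciled (see
"Reproduction checks" below).

Price re-indexing between financial years uses a user-supplied index
series (`inflate_cost()`), multiplying by the ratio of index values. The
NHS Cost Inflation Index is the intended series, but no index values are
baked in: the index is data, not a constant of the package.

Degenerate inputs are handled explicitly: an empty category match
subtotals to 0; a share with a non-positive denominator is an error
rather than an `NaN`.

## Morbidity burden

Unresolved cases are split into recovery states with an annual cohort
count and a time-in-state:

- full recovery: HRQoL affected for 0.5 years (the "about six months"
  convention for transient cases);
- partial recovery and permanent deficit: the remaining lifetime,
  `life_expectancy − median_age_dx` = 81.6 − 37.5 = 44.1 years, with no
  age/sex stratification or life-table integration.

QALY losses are `cases × years × decrement`, where the utility decrement
(unit: QALYs per person-year, in [0, 1]) is a single scalar applied to
all states. The published tables do not print the decrement; the package
recovers it by algebraic inversion (`calibrate_decrement()`), and the
value implied by the partial-recovery row (0.04 to 4 s.f.) reproduces
every per-state row. Per-state losses are rounded half-up to whole QALYs
*before* summing, because the published total (11,912) is the sum of
independently rounded rows — the unrounded sum is 11,911.2.

No discounting is applied anywhere by default: treatment costs fall
within 12 months, and the source analysis applied none to lifetime QALYs
either. `qaly_loss()` exposes a `discount_rate` hook (continuous-time
annuity factor) defaulting to 0 for analysts who want a discounted
variant; it is not used in any reproduction.

Monetisation multiplies QALYs by the NICE willingness-to-pay band,
£20,000–£30,000 per QALY, kept as a low/high `money_interval` end to
end; societal costs use a flat £5,000–£10,000 per case over five years
(cumulative benefit payments for comparable disablement). Intervals are
never collapsed to midpoints, and interval operations preserve
`low ≤ high` by construction.

One inconsistency in the source cohort surfaced during implementation:
the per-state case counts (16,086 + 2,945 + 3,625) sum to 22,656, one
below the printed all-cases figure of 22,657. The societal-cost
calculation uses the printed 22,657, which is what reproduces the
printed societal band; the fixtures carry both numbers.

## Decision-analytic cost-effectiveness

Each strategy is a finite acyclic tree: chance nodes with branch
probabilities summing to 1 (tolerance 1e-9), terminal nodes with
non-negative `(cost, effect)` payoffs, and an `upfront_cost` applied to
every entrant. Effects are HB-grade improvements, not QALYs: the ICER
unit is GBP per HB grade, and conversion of health gains to money goes
through the Delphi valuation, not a utility mapping.

`rollback()` computes bottom-up expectations; `enumerate_paths()`
computes joint pathway probabilities by the product rule. The two are
algebraically identical and the test suite verifies their agreement at
1e-12 on 100+ random trees, against a brute-force oracle written
independently of either routine.

`compare_strategies()` classifies the incrementals with a tie tolerance
of 1e-9 on both axes: `equivalent` within tolerance, `dominant` when
ΔC < 0 and ΔE > 0, `dominated` when the signs reverse, and otherwise
`tradeoff_icer` with ICER = ΔC/ΔE — reported as undefined (`NA`) when
ΔE = 0 but ΔC ≠ 0, rather than an infinite ratio. Net monetary benefit
`WTP·ΔE − ΔC` is always reported; the default WTP of £20,000 is the
lower NICE bound and only affects the NMB line.

The device is costed as an upfront per-entrant cost with probability 1
(single-use assumption). Because the expected cost is affine in the
device price with slope equal to the probability of incurring it,
`break_even_price()` solves ΔC = 0 in closed form:
`price − ΔC / device_probability`. The `device_probability` argument is
exposed for reuse scenarios (a device shared across patients); at
`device_probability = 0` no break-even exists and the function signals
an error rather than returning an infinity. Tests verify the closed form
by re-rolling back actual trees at the returned price and asserting
|ΔC| < 1e-6.

The published branch probabilities of the two-arm model are not printed,
so the two arms' probability-weighted expected values (1095.38/1.261 and
1563.07/1.125) enter the package as fixture constants rather than
computed quantities; the engine that would compute them is verified
structurally by the oracle properties above, and `gen_tree()` ships the
model's *shape* (two strategies × recovery/no-recovery × three severity
strata) with free probability parameters.

Pathway cost schedules (`pathway_cost()`) treat a stated `line_total` as
authoritative for its line when present — published subtotals
occasionally disagree with `unit_cost × units` at the penny level — and
flag any line whose stated and computed values differ by more than
1e-6 GBP.

## Delphi consensus

Agreement for an item is the share of non-missing ratings on the modal
category. Three denominators were possible; the package uses responders
to that item in that round (not the invited panel, not the round-1
returners), which is how a shrinking panel's later rounds are reported.
Multimodal ties yield *no consensus* rather than an arbitrary tie-break:
the modal-consensus approach presumes a unique mode. The ex-ante
threshold (default 66%) is inclusive at the boundary. Monetary rating
bands (e.g. "≥£19,400") are ordinal categories; no interpolation is
attempted within bands. `run_rounds()` extracts an item at its earliest
consensus round and does not re-score it afterwards, so revisions in
later rounds cannot undo an extraction.

## Synthetic data

The generators exist so that every engine is testable on inputs with
known structure:

- `gen_ledger()` draws lognormal unit costs (meanlog log(100), sdlog 1 —
  a heavy right tail like reference-cost schedules) and uniform integer
  volumes over a two-level category hierarchy.
- `gen_tree()` emulates the model shape with a configurable recovery
  uplift and device cost; identical arms with no uplift and no device
  must classify `equivalent`.
- `gen_panel()` rates with probability `modal_concentration` on a
  designated modal category and uniformly otherwise, with independent
  missingness; at n = 500 panelists, observed agreement recovers the
  concentration within ±5 points in the seeded tests.

Each generator derives a private substream from `(seed, generator name)`
and restores the caller's random state, so identical seeds give
bit-identical output and adding a generator never perturbs another.
What the generators do *not* emulate: real NHS reference-cost
distributions, correlated ratings across panelists or items, structured
missingness, or patient-level heterogeneity in pathway probabilities.
Passing tests on synthetic data therefore demonstrate the algebra and
the invariants, not calibration to real-world cost data.

## Reproduction checks

`reproduce_analysis()` recomputes every headline figure from the
packaged inputs and compares each with its printed value at the
precision it was printed (half-up). Test problem sizes are kept small —
100-tree oracle sweeps, 500-panelist agreement checks, 20-30 random
configurations per property — which the seeded substreams make exactly
reproducible. Printed figures that are internally inconsistent with
their own printed inputs are *flagged*, not matched:

- the primary-care subtotal "3.7653 million" (sum of rounded cells;
  exact volume × unit-cost arithmetic gives 3.7652 million);
- the morbidity high bound 357.31 and its cells 9.60 and 191.86 (vs
  322 × 30,000 = 9.66m and 6,395 × 30,000 = 191.85m);
- the total-burden low bound "£351 million" (computed 351.5m);
- the fNMR course total 3126.10 (its own printed lines sum to 3126.15);
- the national saving "£3.08 million" (467.69 × 6,570 = 3.07m,
  presumably computed upstream from unrounded per-patient savings).

`reproduce_analysis()$ok` is `TRUE` only when every *unflagged* check
matches, so a regression in any computation is caught even though the
known source-table artifacts remain documented rather than papered over.

## Limitations

The package deliberately mirrors the scope of the analysis it
implements: a 12-month treatment horizon with no Markov/state-transition
modelling, no probabilistic sensitivity analysis, no half-cycle
corrections, no productivity-loss modelling beyond the flat per-case
societal interval, and GBP only (the £1.36 = US $1 conversion is a
report footnote, not a computation path). A lifetime-horizon model with
patient heterogeneity would need different machinery.
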