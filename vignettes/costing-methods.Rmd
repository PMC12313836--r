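---
title: "Activity-based costing of thyroid-nodule treatments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based costing of thyroid-nodule treatments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrocost)
```

## The model

`thyrocost` implements an activity-based costing (ABC) model for comparing
treatments of benign symptomatic thyroid nodules: total thyroidectomy,
hemithyroidectomy with isthmectomy, and ultrasound-guided thermal ablation
(laser or radiofrequency, in a day-hospital setting). ABC assigns the full
per-patient cost of a treatment by enumerating the resources ("cost
drivers") each phase of care consumes and valuing each driver at its unit
cost.

The per-patient grand total of an intervention is

$$
T \;=\; (1+r)\Big(\underbrace{\textstyle\sum_i q_i c_i}_{\text{pre-hosp.}}
 + D + M + P + \text{OR} + \text{Stay}\Big)
 \;+\; \underbrace{\textstyle\sum_k f_k C_k}_{\text{follow-up}}
 \;+\; (1+r)\,L,
$$

with:

* $q_i$, $c_i$ — mean quantity per patient and per-patient cost of driver
  $i$ (a consultation, a lab test, a disposable);
* $D$ — pharmaceutical cost, summed over drug macro-categories
  (anesthetics, opioids, antibiotics, corticosteroids, other); within a
  category, *alternative* agents average and *co-administered* agents sum,
  and a category may instead carry a printed weighted cost where the
  source table's weighting is not recoverable;
* $P$ — personnel cost (engagement-time-weighted cost per professional,
  summed over roles);
* OR, Stay — operating-room and hospital-stay costs, each a printed cost
  or duration × rate (EUR/minute, EUR/bed-day);
* $f_k$, $C_k$ — frequency and annual cost of post-operative course $k$
  (standard / acute complications / chronic complications); frequencies sum
  to at most 1, the residual fraction incurring no follow-up cost;
* $L$ — productivity loss by the human-capital approach:
  $L = d\,h\,w\,(1 + s)$, where $d$ is hospitalization plus convalescence
  days, $h$ hours of work lost per day (default 5), $w$ the weighted hourly
  wage (default EUR 14.05), and $s$ the fraction of patients assisted by a
  caregiver (who is assumed to lose the same amount);
* $r$ — the retreatment rate: the fraction of patients who undergo the
  procedure again (0.15 for thermal ablation, 0 for surgery). Folding
  repeat procedures into the per-patient average multiplies the affected
  components by $(1+r)$. Follow-up is not uplifted: retreated patients
  re-enter the same annual follow-up schedule, not a second one.

Three accounting **perspectives** select which components enter $T$:
`nhs_direct` (payer-borne direct costs only), `societal` (adds $L$), and
`opportunity_cost_societal` (societal minus $P$, treating staff time as an
opportunity cost the payer incurs regardless of service delivery). By
construction the engine computes the opportunity-cost total as the societal
total minus the included personnel component, so the identity
`societal − personnel = opportunity` holds to the last cent on any dataset.

## Fidelity mode and raw mode

Published cost tables round every aggregate to cents, so recomputing a
published grand total from raw rows accumulates rounding drift. The engine
therefore has two modes:

* **fidelity** (default): first-level printed aggregates carried by a
  dataset — phase totals, course annual totals, productivity patient and
  caregiver terms, and the printed procedure subtotal — are authoritative,
  and every derived component (weighted follow-up terms, uplifted
  components, the grand total) is rounded half-up to cents at its boundary.
  On the bundled fixtures this reproduces the published headline totals
  (EUR 5,185.36 / 4,211.92 / 1,560.06) to the cent.
* **raw**: everything is recomputed from quantities and unit costs, with no
  intermediate rounding; only display rounds. On the bundled fixtures raw
  totals differ from fidelity by at most ~0.02%. Property-based tests and
  all sensitivity analyses run in raw mode, so a perturbed quantity or
  price actually propagates instead of being shadowed by a printed value.

Rounding is **half-up at cents** (`round_cents()`), the commercial rule the
source tables use, not R's round-half-even. Money is held as numeric euros
rather than integer cents: one fixture value (the ablation materials base,
661.98/1.15) is not cent-exact, and storing it exactly is what lets the
multiplicative uplift land on the printed 661.98.

## The bundled fixtures and their errata

`bundled_datasets()` transcribes the published tables for the three
interventions, keeping printed aggregates as reconciliation metadata.
`reconcile_dataset()` recomputes every such aggregate and reports
discrepancies; within EUR 0.02 per aggregation step is treated as printed
rounding drift. Four discrepancies in the source are genuine errata that the
validator must flag, and their magnitudes are pinned in tests:

| where | printed | recomputed | gap |
|---|---:|---:|---:|
| total-thyroidectomy materials table, total row | 3,489.42 | 3,502.42 | 13.00 |
| ablation materials table, total row | 755.15 | 1,219.15 | 464.00 |
| hemithyroidectomy follow-up subtotal | 49.79 | 122.38 | 72.59 |
| ablation follow-up subtotal | 108.70 | 91.11 | −17.59 |

Design choices where the source is silent or inconsistent:

* **Uplift scope.** The source never states which aggregates receive the
  ablation ×1.15 factor. Applying it to pre-hospitalization, drugs,
  materials, personnel, hospital stay and productivity — and not to
  follow-up — is exactly the combination that reproduces every printed
  comparative-summary value (369.25, 1.94, 40.64, 193.78, 183.77) and the
  grand total 1,560.06.
* **Ablation materials.** The device rows (laser fibers, RF electrode)
  cannot be combined into the printed aggregate without an unstated
  modality-share weighting; the phase therefore carries a flat override
  (661.98/1.15) while the table rows remain as documentation.
* **Ablation follow-up.** The printed subtotal 108.70 exceeds the weighted
  standard course (0.93 × 97.97 = 91.11) by an unexplained 17.59, modeled
  as a flat residual and flagged by reconciliation.
* **Hemithyroidectomy personnel.** The staff table totals 184.75 while the
  comparative summary prints 184.65 in that cell; 184.75 is used because it
  alone reconciles both the procedure subtotal 3,051.77 and the
  opportunity-cost figure 4,027.17.
* **Follow-up mixture rounding.** The engine computes the mixture itself
  (half-up per weighted term: 105.33 + 7.98 + 9.07 = 122.38 for
  hemithyroidectomy) rather than honoring the summary table's own weighted
  rows (which give 122.39); the computed value is the one consistent with
  the printed grand total 4,211.92.
* **Drug category totals.** The anesthetics category costs printed for the
  surgical interventions (1.54, 1.56) match neither the sum nor the mean of
  their lines; they are carried as `printed_override` policies. The phase
  totals 11.49/12.08/1.69 are likewise pinned as printed values in fidelity
  mode; raw mode recomputes 11.50/12.07/1.77.
* **Follow-up horizon.** Follow-up is a single-year cost: no discounting,
  no multi-year horizon, and the same horizon for all three interventions
  (a limitation inherited from the source, which likely understates
  long-term ablation surveillance and long-term surgical replacement
  therapy).

## Sensitivity analysis

The source quantifies no uncertainty; the sensitivity module is an
extension anchored to the two quantities its discussion flags: material
price fluctuation, and an ablation recurrence risk of roughly 5–25%
(against the 15% base case). Parameters are addressed by dotted paths
(`retreatment_rate`, `facility.stay_days`,
`material_items[Gauze].unit_cost`, ...). `one_way_sweep()` and `tornado()`
evaluate the engine at range endpoints; `monte_carlo()` propagates
independent draws (uniform, triangular, or normal truncated at zero —
distribution choices are user inputs, not source claims; where no range is
known, uniform ±20% is the suggested default).

Randomness contract: a single master seed governs a run; each parameter
draws from its own substream derived from the master seed and its position
in the spec list, so appending a parameter leaves existing draws unchanged.
Because every price and the uplift rate enter the total linearly, the Monte
Carlo mean must converge to the total evaluated at the parameter means;
this is tested at n = 10,000 against a 3-standard-error band.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the real tables — 3 to 14
items per phase with a mix of quantity×price, flat, and pre-weighted rows;
drug lines across the five categories under random policies; staff lines;
stay (and sometimes OR) given as duration × rate; 1–3 follow-up courses
whose Gamma-drawn frequencies are renormalized only when they would exceed
1; retreatment rate in [0, 0.3); caregiver share in [0, 0.2] — with all
money drawn from a common price range. Each bundle carries ground-truth
grand totals for all three perspectives computed by a straight-line
closed-form walk inside the generator, written independently of the engine,
making it a true oracle: the suite checks engine = truth to the cent over
100 seeded bundles. `generate_paperlike()` fixes the study's exact shape
(14 pre-hospitalization items, 5 staff roles, follow-up at
0.93/0.035/0.035, retreatment 0.15) with randomized values.

What the generator does **not** emulate: patient-level heterogeneity,
correlated prices, survival or multi-year horizons — the model is a
deterministic per-patient average, as in the source. Passing the oracle
sweep therefore certifies the accounting arithmetic, not the realism of any
particular cost estimate.

## Numerical choices and problem sizes

* Reconciliation tolerance EUR 0.02 per aggregation step; oracle and
  additivity assertions at half a cent or tighter.
* Validation raises a single error listing every violation; reconciliation
  is never fatal.
* Degenerate inputs: empty phases cost 0; a zero-priced dataset totals 0
  under every perspective; `r = 0` is the exact identity; a single course
  at frequency 1 is the degenerate mixture.
* Tornado ties break lexicographically by parameter path.
* Suite sizes: the oracle sweep uses 100 seeds, the Monte Carlo convergence
  check 10,000 draws, sweeps about 20 steps — the whole model is desk-scale
  and the full test suite runs in well under a minute.

## Limitations

The engine reproduces a single-country, single-year, average-patient
costing exercise. It does not model cost-utility (no QALYs), discounting,
currency conversion, budget impact, or operator learning curves, and the
fixture values inherit every limitation of the underlying survey-based
estimates, including the four documented errata above.
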