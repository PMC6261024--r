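---
title: "Predicting serum sodium by mass balance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting serum sodium by mass balance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natremia)
library(dplyr)
```

## The prediction problem

Critically ill patients receive many sodium-bearing fluids per shift —
resuscitation fluids, drug diluents, enteral and parenteral nutrition —
while losing water and sodium in urine. The clinical question this package
addresses is short-horizon and chart-based: given what is on the fluid chart
for the next 8 hours, what will the serum sodium be at the end of the
interval, and how much of a chosen solution must be infused to land on a
target value?

The core predictor treats the patient as a single well-mixed sodium
compartment of size TBW (total body water) and conserves mass over the
epoch:

$$
[\mathrm{Na}]_{8h} \;=\;
\frac{[\mathrm{Na}]_0 \cdot TBW \;+\; \sum_i [\mathrm{Na}]_i V_i
      \;-\; [\mathrm{Na}]_u V_u}
     {TBW + \Delta V},
\qquad \Delta V = \sum_i V_i - V_u .
$$

The denominator is the end-of-epoch body water: TBW plus the signed net
fluid balance ("equilibrium"). Both sides of the balance use concentration
× volume products; sodium amounts are never stored independently of their
defining streams.

Assumptions worth keeping in view:

* **Single compartment, instant mixing.** No osmotically inactive sodium
  stores, no glucose/osmole corrections, no SIADH-specific handling.
* **Insensible losses ignored.** Skin and GI losses are not on the chart
  and are not modeled; in febrile or diarrheal patients this biases the
  prediction upward.
* **Potassium excluded from the mass balance.** The comparator formulae
  accept potassium (and it is included by default when charted,
  `include_potassium = TRUE`), but the mass-balance numerator is
  sodium-only by construction.
* **Urine flow treated as representative.** One aggregate urine stream per
  epoch; whether its volume is the epoch's own or the preceding 8-hour
  window's (a common charting convention, acceptable when flow is steady)
  is left to the data preparer and matters in acute kidney injury.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `tbw_fraction` | 0.5 | — | bedside TBW rule (weight × 50%), same for both sexes and all ages; deliberately crude, hence configurable |
| `include_potassium` | `TRUE` | — | comparators were derived with (Na+K); the mass balance never uses K |
| `na_target` | — | mmol/L | dosing target, restricted to the plausible range [100, 200] |
| `infusate_na` | — | mmol/L | e.g. 0 (free water), 77 (0.45% saline), 154 (0.9%), 513 (3%) |

The 1.96 multiplier (95% limits of agreement) and the sample (n−1) SD are
fixed choices of the agreement module, as is the difference direction
predicted − measured (negative bias = under-prediction). The Percentage
Similarity uses the mean of each pair referenced to the measured value,
`100 · ((p+m)/2)/m`, which makes the mean percentage difference identically
`mean similarity − 100` — an identity the tests assert on every emitted
report.

## The dosing inverse

Solving the balance equation for the infusion volume is linear because the
unknown volume appears once in the numerator (as infused sodium mass) and
once in the denominator (as added water):

$$
V \,( c - [\mathrm{Na}]_{target} ) \;=\;
[\mathrm{Na}]_{target}(TBW + \Delta V_{other}) -
\big([\mathrm{Na}]_0 TBW + Na_{in,other} - Na_{out}\big)
$$

with `c` the infusate sodium. Including `V` inside the net-balance term is
the self-consistent choice: it is exactly how the forward predictor would
see the infusion, and the package's round-trip property — forward
prediction after the solved infusion hits the target to 1 part in 10⁹ —
holds only under this convention. Design decisions:

* **Negative volumes are infeasible, not "remove fluid".** The solver
  answers an infusion-dosing question; a hypotonic solution cannot raise
  sodium and the plan says so (`feasible = FALSE` with a reason) rather
  than suggesting ultrafiltration.
* **Tonicity equal to target** with a nonzero sodium gap has no solution
  and raises a classed error; if the epoch is already at target the volume
  is 0.

## Numerical choices

* Denominators at or below 10⁻⁹ L raise a classed degenerate-balance error
  instead of returning an unbounded concentration; inside `predict_all()`
  the failing predictor is tagged per epoch and the others still evaluate.
* Chart CSVs are written with 17 significant digits and re-parsed through
  base `strtod`, so `read_chart(write_chart(x))` is bit-for-bit identical
  and the shipped fixture regenerates byte-identically from its seed.
* Boundary sodium values 135 and 145 mmol/L classify as normonatremic:
  both clinical definitions are strict inequalities.
* Sodium chart entries outside [100, 200] mmol/L are rejected as
  implausible rather than silently propagated; validation reports all
  offending rows at once.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` exists because desk-scale testing needs data with a
*known* ground truth. Its defaults sketch a mixed ICU population:

* baseline sodium ~ truncated normal, mean 143.5, SD 6 mmol/L on
  [125, 165], drawn stratified to an enrollment dysnatremia mix of 10%
  hyponatremic / 53% normonatremic / 37% hypernatremic;
* urine sodium ~ truncated normal, mean 99.2, SD 50 mmol/L on [10, 215];
  urine volume uniform 0.5–2.5 L per 8 h;
* input streams present with probabilities 0.90 (infused), 0.50 (drug),
  0.758 (enteral), 0.607 (parenteral), with uniform volume and
  concentration ranges typical of each stream;
* weight ~ truncated normal, mean 75, SD 15 kg on [40, 130];
* two consecutive epochs per patient, the second starting from the first
  epoch's latent (noise-free) final sodium.

The latent true final sodium **is** the mass-balance value, and the
measured final sodium adds Gaussian noise (SD 2 mmol/L by default, the
scale of point-of-care blood-gas sodium measurement; baseline sodium is
treated as known). This is a deliberate epistemic choice: the generator
answers "is the formula implemented and evaluated correctly?", not "is the
formula physiologically true?". Consequently:

* the mass-balance predictor must recover zero bias and an SD of
  differences equal to the injected noise SD — a parameter-recovery check
  the acceptance suite runs at 500 patients (1000 epochs);
* the comparator formulae show structured, nonzero biases on the same
  cohort (they model the epoch differently), which exercises the
  method-comparison machinery exactly as a real formula shoot-out would;
* passing tests say nothing about unmodeled physiology: insensible losses,
  within-epoch dynamics, renal replacement therapy, osmotic shifts, or
  correlated charting errors. Real-data performance is a separate,
  clinical question.

Problem sizes used by the test-suite and acceptance script — grids of
1000–5000 flux-free epochs, 500-case equivalence and dosing sweeps, and a
500-patient evaluated cohort — were chosen as the smallest sizes at which
the stochastic checks are statistically decisive (e.g. the bias bound of
0.3 mmol/L sits more than 4 standard errors from zero at n = 1000).

## Known limitations

* TBW as a fixed fraction of weight ignores sex, age and body composition;
  the fraction is configurable but the default is the bedside rule.
* The comparator formulae are applied to whole-epoch totals; their original
  derivations were per liter of infusate. With volumes well under body
  water the two readings differ only in the second order, and applying
  totals keeps all five predictors on the same footing.
* Epoch labels are taken from the chart as-is; the package never infers
  epoch order or adjudicates inconsistent labeling.
* The agreement module treats the two epochs of one patient as independent
  pairs; no repeated-measures correction is applied.
* No correction-rate safety ceilings (mmol/L per hour) are enforced on
  dosing plans — the solver answers the arithmetic question only, and its
  output is not clinical advice.

## A compact session

```{r example, eval = FALSE}
chart <- generate_cohort(n_patients = 50, seed = 7)
ev <- evaluate_cohort(chart)
tidy(ev)                       # Bland-Altman + similarity, per subgroup
glance(ev)                     # one-row overview
autoplot(ev)                   # Bland-Altman panels
autoplot(ev, type = "similarity")
solve_infusion_volume(chart, na_target = 142, infusate_na = 154)
```
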