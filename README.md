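# natremia

Serum sodium disturbances (dysnatremias) develop in the majority of ICU
patients, often iatrogenically, and empirical correction attempts are a
leading cause of dangerous sodium swings. `natremia` is an R toolkit for
clinicians and biostatisticians that forecasts a patient's serum sodium over
an 8-hour epoch directly from the fluid chart, doses the infusion needed to
reach a target sodium, and evaluates any prediction formula against measured
sodium with method-comparison statistics.

## The model

The core predictor is a mass-conservation balance over the epoch. With total
body water `TBW = 0.5 × weight (kg)` and the *equilibrium*
`ΔV = Σ V_in − V_urine` (net fluid balance, liters):

```
              [Na]₀·TBW + Σᵢ [Na]ᵢ·Vᵢ − [Na]ᵤ·Vᵤ
  [Na]₈ₕ  =  ─────────────────────────────────────
                          TBW + ΔV
```

where the inputs `i` run over infused fluids, drug diluents, enteral and
parenteral nutrition, and the single output is urine. Four classical bedside
formulae are implemented as comparators over the same epoch totals:

| predictor | idea |
|---|---|
| `adrogue_madias` | closed system: `( [Na]₀·TBW + V·[Na+K]_inf ) / (TBW + V)` |
| `barsoum_levine` | adds renal losses: `( [Na]₀·TBW + (Na+K)_in − (Na+K)_out ) / (TBW + ΔV)` |
| `kurtz_nguyen` | plasma-water scale: `( ([Na]₀+23.8)·TBW + 1.03·Δ(Na+K) ) / (TBW + ΔV) − 23.8` |
| `efwc` | renal free water only: `[Na]₀·TBW / (TBW − EFWC)`, `EFWC = Vᵤ·(1 − (Naᵤ+Kᵤ)/[Na]₀)` |

Agreement with measured sodium is summarized by Bland–Altman bias with 95%
limits of agreement (bias ± 1.96 SD of predicted − measured) and by the
Percentage Similarity (per pair, `100 × mean(pred, meas) / meas`) with its
coefficient of variation, overall and by natremia subgroup (hyponatremic
< 135, hypernatremic > 145 mmol/L, strict inequalities).

The dosing solver inverts the balance equation for the infusion volume `V` of
a solution with sodium `c`: `V·(c − target) = target·(TBW + ΔV_other) −
([Na]₀·TBW + Na_in − Na_out)`, returning an infeasible plan (never a negative
volume) when the tonicity is on the wrong side of the target.

## Worked example

Charts are long-format CSVs — one row per fluid stream, with the epoch header
(weight, baseline and measured final sodium) repeated. A 10-patient synthetic
fixture ships with the package:

```r
library(natremia)

chart <- read_chart(system.file("extdata", "synthetic_cohort_n10.csv",
                                package = "natremia"))
ev <- evaluate_cohort(chart)
ev
#> <na_evaluation> 20 agreement report(s) over 20 epoch(s)
#>   mass_balance    n= 20  bias +0.124  SD 2.619  LoA [-5.009, +5.257]  similarity 100.06% (CV 0.93%)
#>   adrogue_madias  n= 20  bias -1.149  SD 3.756  LoA [-8.510, +6.212]  similarity  99.62% (CV 1.31%)
#>   barsoum_levine  n= 20  bias -0.539  SD 2.696  LoA [-5.823, +4.744]  similarity  99.83% (CV 0.95%)
#>   kurtz_nguyen    n= 20  bias -0.929  SD 2.841  LoA [-6.497, +4.638]  similarity  99.69% (CV 1.00%)
#>   efwc            n= 20  bias +3.129  SD 3.090  LoA [-2.928, +9.186]  similarity 101.12% (CV 1.10%)
```

Each line is one predictor evaluated over the 20 epochs: `bias` is the mean
of predicted − measured sodium (mmol/L; negative = under-prediction), `LoA`
the interval expected to hold ~95% of differences, and `similarity` the mean
Percentage Similarity (100% = perfect agreement). In this cohort the
generator's ground truth follows the mass balance, so that predictor shows
the smallest bias (+0.12 mmol/L, consistent with the simulated 2 mmol/L
measurement noise) while the comparators show structured offsets (e.g. EFWC
ignores all infused sodium and over-predicts by +3.1 mmol/L here).

Dosing — how much 3% saline (513 mmol/L) raises patient P0001's first-epoch
sodium to 140 mmol/L given everything else on the chart:

```r
chart |>
  dplyr::filter(patient_id == "P0001", epoch == "epoch1") |>
  solve_infusion_volume(na_target = 140, infusate_na = 513)
#>   patient_id  epoch na_target infusate_na volume_required na_projected feasible
#> 1      P0001 epoch1       140         513        1.486846          140     TRUE
```

`tidy(ev)` returns the full report table (per predictor and subgroup),
`glance(ev)` a one-row overview, `autoplot(ev)` Bland–Altman panels, and
`agreement_plots(ev, dir)` writes per-predictor figures. A thin CLI with
`simulate`, `predict`, `evaluate` and `dose` subcommands is installed at
`system.file("cli", "natremia", package = "natremia")`.

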