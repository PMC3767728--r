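---
title: "A patient-level simulation model of perioperative blood management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A patient-level simulation model of perioperative blood management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodsim)
```

## The model

`bloodsim` simulates individual elective hip- and knee-arthroplasty patients
and runs each of them, as identical clones, through three perioperative
blood-management strategies:

* **ABT** — no blood conservation; allogeneic transfusion only.
* **PAD** — preoperative autologous donation: two red-cell units are banked
  before surgery (if baseline Hb is at least 11 g/dl) and reinfused first
  when transfusion is needed; donation lowers the hemoglobin available at
  surgery.
* **EPO** — preoperative epoetin alfa: 40,000 IU injections are given while
  the running Hb is below a termination level, raising the hemoglobin
  available at surgery.

A patient is a draw from a population table (procedure stratum × age band ×
sex), followed by draws of age, body weight, estimated blood volume
(weight × 65 ml/kg), a sex-specific Weibull baseline hemoglobin, comorbidity
flags (ASA ≥ III, rheumatoid arthritis, cardiac history, revision surgery)
and a surgical blood loss expressed directly in g/dl Hb. The episode then
follows the arithmetic of hemoglobin mass balance:

1. the arm adjusts the preoperative Hb (PAD subtracts a normally distributed
   decrement; EPO adds per-injection increments; ABT does nothing);
2. post-surgery Hb = adjusted Hb − blood loss (floored at 0);
3. if post-surgery Hb is below the effective trigger (8.5 g/dl base case,
   +1 g/dl for cardiac history), `ceiling((trigger − Hb)/hb_per_unit)` units
   are transfused — autologous stock first, allogeneic for the remainder;
4. infection and pneumonia events are Bernoulli draws whose probabilities
   are elevated for transfused patients;
5. length of stay is the DRG base stay × 1.2 (transfusion), × 1.6
   (infection) or × 1.9 (both);
6. costs accrue per EPO dose (€200), per allogeneic unit (€320), per
   donation (€500 flat, reinfused or not), per hospital day (€300) and per
   pneumonia episode (€5,000).

Outputs are stratified by baseline-Hb bands of 0.5 g/dl from 10 to 13 g/dl —
the range in which epoetin is a relevant option — and reported as
(mean, SE, SD) triplets with paired incremental total costs ABT−EPO and
PAD−EPO. Bands are half-open `[lo, hi)`, so a patient at exactly 11.0 g/dl
belongs to `[11.0, 11.5)`; donation columns are suppressed below 11 g/dl,
where PAD is not indicated.

## Random-number architecture

Every run is keyed to one master seed. Patient characteristics are drawn
from a sub-stream derived from `(seed, patient_id)`, and each arm's
preoperative and episode draws from `(seed, patient_id, arm)`. Two
consequences matter for inference:

* **Common random numbers.** Clones share characteristics exactly, so
  incremental costs are paired differences (SE = SD(differences)/√n), and
  scenarios run at the same seed share their patient population, so scenario
  deltas are not dominated by re-sampling noise.
* **Stable identities.** Patient `i` is the same person regardless of cohort
  size or execution order; reports are byte-identical across reruns of the
  same configuration.

## Parameters that matter

All parameters live in one configuration object (`default_config()`,
serializable to YAML/JSON). The clinically load-bearing ones:

| parameter | default | note |
|---|---|---|
| `transfusion_trigger` | 8.5 g/dl | scenarios at 8.0 / 9.0 |
| `cardiac_trigger_shift` | +1 g/dl | applied regardless of trigger |
| `hb_per_unit` | 1.0 g/dl | Hb gained per unit; the standard clinical rule of thumb, exposed because published sources rarely state it |
| `blood_loss_mean_hip` / `knee` | 3.3 / 3.5 g/dl | normal, SD 1.0, truncated at 0 |
| ASA / old-age / revision loss factors | ×1.05 / ×1.05 / ×1.25 | compose multiplicatively |
| `pad_hb_decrement_mean` (SD) | 1.2 (0.83) g/dl | one draw per donation pair |
| EPO regimen | stop ≥ 13.3 g/dl, max 3 doses | increments N(1.0, 0.6) truncated at 0 |
| `ra_epo_attenuation` | 0.8 | rheumatoid patients respond less |
| LOS factors | 1.2 / 1.6 / 1.9 | transfusion / infection / both |
| pneumonia risk | 0.8% → 1.6% | doubled by transfusion |

Choices that were genuinely open, and how they were settled:

* **Age within band** is integer-uniform: the least-informative choice given
  only band membership; configurable via the population table granularity.
* **Blood-loss modifiers compose multiplicatively.** Each factor is quoted
  as an independent percentage increase; multiplicative composition is
  symmetric in the factors and lets the zero-correlation scenario switch
  each off independently (set all three factors to 1).
* **Equality at the trigger** transfuses nothing: a patient exactly at the
  trigger already "meets" it and zero units restore it. Published wording is
  ambiguous at exact equality, so `transfuse_at_equality` exposes the other
  convention (then forcing a minimum of one unit).
* **The PAD decrement is an untruncated normal.** Truncating or folding
  N(1.2, 0.83) at zero would inflate the realized mean decrement to ≈1.23 to
  1.25 g/dl, visibly above the intended 1.2; the rare negative draw is read
  as measurement-inclusive variation around donation.
* **The day-of-surgery epoetin dose** (liberal 15 g/dl protocol) is modeled
  by running the usual check-then-dose loop and then withdrawing the last
  administered dose's increment: that dose is given and paid for, but cannot
  act on the hemoglobin available at surgery.
* **Incremental SEs are paired.** The arms are clones, so the paired
  formulation is the correct one; an unpaired SE would overstate uncertainty
  without changing the mean.
* **"All costs ±25%"** scales the five unit costs jointly, as a scenario
  distinct from the per-cost ±25% scenarios. With event draws fixed it is a
  pure rescaling of every money output.

## The synthetic population and its calibration

The package ships no registry data. `generate_fixture_population()` builds a
synthetic table with the *structure* of the German arthroplasty case mix:
57.5% hip, 65% female, four age bands peaking at 65–74 (mean age ≈ 70),
revision risk 10.4%, ASA ≥ III risk 40%, base stays of 13 (hip) and 12
(knee) days. Baseline hemoglobin uses Weibull(9, 14.5) for women and
Weibull(10, 15.3) for men, calibrated once, in closed form
(`pweibull`), so that ≈ 23–24% of a mixed cohort falls in the 10–13 g/dl
reporting range with band occupancy increasing toward 13 — the anemic-cohort
structure this class of model targets. Because women's distribution sits
lower, the 10–13 band is ≈ 76% female, an emergent property of the Hb
distributions rather than of the table.

What the fixture does **not** emulate: real DRG codes and their
procedure-specific stay/risk differences, within-stratum correlation between
comorbidities, age–Hb dependence, and seasonal or site effects. Tests that
pass on this fixture therefore validate the model *mechanics* (triggers,
unit arithmetic, stream discipline, cost accounting) and qualitative
orderings, not site-specific magnitudes; for those, load a local population
CSV (`read_population()`) and refit the Weibull parameters.

## Numerical and degenerate-input conventions

* Lengths of stay are kept fractional internally so costs are exact
  (€300 × days); rounding happens only in printed reports.
* Baseline Hb draws are clamped to the physiological 6–18 g/dl; weight is
  clamped below at 35 kg; post-surgery Hb is floored at 0.
* Zero-SD distributions are legal everywhere and make episodes exactly
  hand-computable; the test suite leans on this.
* Empty Hb bands are reported as missing cells, never zeros.
* Sub-stream seeds are derived with modular mixing below 2^31, so any small
  integer master seed is safe on 32-bit R integers.

## Problem sizes

Headline runs use 50,000 patients (≈ 30 s on one core). The bundled
system-level checks run 10,000-patient cohorts, large enough that cohort
shares carry binomial errors below one percentage point. One caveat at that
scale: adjacent high-Hb bands differ in EPO-arm transfusion rates by only
1–2 points, which is within binomial noise of a 10,000-patient cohort, so
*strict* per-band monotonicity of the EPO arm is only reliably observable in
larger cohorts (it holds cleanly at 50,000).

## Known limitations

* Epoetin adverse events, iron therapy, cell salvage and fluid management
  are outside the model, as is any post-discharge resource use: the
  perspective is a single hospital admission.
* No QALYs or discounting; the outputs are event rates, stays and euros.
* The per-injection epoetin increment and the donation decrement are normal
  approximations of distributions whose published forms are not available;
  their parameters are configuration fields, not constants.
* The age adjustment of length of stay defaults to a no-op multiplier
  because no published magnitude is available; set `los_age_factor` to
  activate it.
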