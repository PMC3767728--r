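# bloodsim

Individual-patient Monte-Carlo simulation of perioperative blood management
in elective hip and knee arthroplasty, from a hospital cost perspective.

Allogeneic transfusion after arthroplasty remains common, and preoperative
anemia is its strongest predictor. `bloodsim` is for health economists and
transfusion-medicine researchers who want a transparent, configurable model
of the question a hospital actually faces: for an anemic patient
(baseline Hb 10–13 g/dl), is it cheaper to do nothing (**ABT**, allogeneic
transfusion only), to bank two autologous units (**PAD**), or to give
preoperative epoetin alfa (**EPO**)?

## The model

Each simulated patient *i* is a draw of procedure stratum, age, sex, weight,
comorbidity flags and a baseline hemoglobin Hb⁰ᵢ from a sex-specific Weibull
distribution, plus a surgical blood loss Lᵢ (in g/dl Hb, normal, inflated
×1.05 for ASA ≥ III, ×1.05 for age ≥ 75, ×1.25 for revision). The patient is
cloned across the three arms with common random characteristics; arm *a*
adjusts the preoperative hemoglobin to Hbᵃᵢ (PAD: −N(1.2, 0.83) with two
units banked if Hb⁰ᵢ ≥ 11; EPO: +N(1.0, 0.6)-increments per 40,000 IU dose
until the running Hb reaches 13.3 g/dl or 3 doses). Then

* post-surgery Hb: Hbᵖᵒˢᵗ = max(0, Hbᵃᵢ − Lᵢ)
* units transfused: uᵢ = ⌈(T − Hbᵖᵒˢᵗ)/δ⌉ if Hbᵖᵒˢᵗ < T else 0, with
  trigger T = 8.5 (+1 for cardiac history) and δ = 1 g/dl per unit;
  autologous stock is used first
* infection and pneumonia are Bernoulli events with transfusion-elevated
  risks (pneumonia 0.8% → 1.6%)
* length of stay: base × {1, 1.2, 1.6, 1.9} for {neither, transfusion,
  infection, both}
* cost: €200 × doses + €320 × allogeneic units + €500 × [donation] +
  €300 × days + €5,000 × [pneumonia]

Results are stratified by baseline-Hb bands of 0.5 g/dl from 10 to 13, each
cell a (mean, SE, SD) triplet, with paired incremental total costs ABT−EPO
and PAD−EPO per band. A scenario grid varies triggers, blood loss, the
donation effect, the liberal epoetin protocol (15 g/dl, 4 doses), LOS
inflation and every cost ±25%. See the vignette
(`vignettes/blood-management-model.Rmd`) for the full parameter table and
design rationale.

## Worked example

```r
library(bloodsim)
cfg <- default_config(n_patients = 2000, seed = 7)
run <- run_simulation(cfg)
print(run)
#> <bloodsim_run> 'base': 2000 patients x 3 arms (seed 7)
#>   ABT: transfused  18.6%, mean LOS 13.22 d, mean total EUR  4111.15
#>   PAD: transfused  37.8%, mean LOS 13.78 d, mean total EUR  4733.88
#>   EPO: transfused   6.2%, mean LOS 12.90 d, mean total EUR  4059.89

summary(run)
#> <bloodsim_summary> scenario 'base' (2000 patients)
#> stat / Hb band               10.0-10.5 10.5-11.0 11.0-11.5 11.5-12.0 12.0-12.5 12.5-13.0
#> n                                   20        51        62        83       116       155
#> ABT transfused_pct               100.0      96.1      79.0      65.1      49.1      27.7
#> ABT mean_los                      16.5      15.0      14.6      14.5      14.3      13.5
#> ABT total_cost                  5769.0    5174.5    4994.8    4720.7    4553.5    4189.1
#> PAD transfused_pct                  NA        NA      93.5      91.6      83.6      67.1
#> PAD mean_los                        NA        NA      15.0      15.3      15.0      14.7
#> PAD total_cost                      NA        NA    5299.8    5341.7    5189.7    5039.6
#> EPO transfused_pct                35.0      17.6      17.7      10.8       6.9       5.8
#> EPO mean_los                      13.6      13.4      13.1      12.9      13.0      12.9
#> EPO total_cost                  5289.0    4840.8    4585.5    4431.6    4324.7    4184.5
#> ABT_minus_EPO_total              480.0     333.7     409.4     289.2     228.9       4.6
#> PAD_minus_EPO_total                 NA        NA     714.4     910.1     865.1     855.1
```

Reading the output: transfusion risk falls steeply with baseline Hb in every
arm; epoetin cuts it most (e.g. 79.0% → 17.7% at Hb 11.0–11.5) and shortens
stays, so the EPO arm is cheapest in every band — by €480 down to €5 per
patient against no conservation (ABT−EPO row, shrinking as anemia
disappears), and by €714–910 against autologous donation (PAD−EPO row),
which adds its flat €500 collection charge on top of a donation-lowered
hemoglobin. Donation columns are `NA` below 11 g/dl, where PAD is not
indicated. `write_report()` saves these tables as per-scenario CSV plus
JSON; `run_scenario_grid()` produces them for the whole sensitivity grid;
`plot(summary(run))` draws the per-band transfusion rates.

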