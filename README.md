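# carbsafe

Personalized safe limits for carbohydrate-counting errors in type 1
diabetes, validated in silico.

## The problem

People with type 1 diabetes dose mealtime insulin from an estimate of the
carbohydrates they are about to eat, using the standard bolus calculator

```
B = CHO / ICR + (G - G_T) / ISF - IOB
```

where `ICR` (g/U) is the insulin-to-carbohydrate ratio, `ISF` (mg/dL/U) the
insulin sensitivity factor, `G` the preprandial glucose, `G_T` the target and
`IOB` the insulin still active on board.  Counting mistakes translate
directly into dosing errors, but "keep errors under 10 g" advice ignores
that tolerance to mis-counting is patient-specific.  The personal limit is

```
dCHO_max = (ICR / ISF) * min(G_H - G_T, G_T - G_L)
```

the largest absolute counting error whose bolus error still keeps
post-prandial glucose inside the `[G_L, G_H] = [70, 180]` mg/dL range
(target 100).  A patient with `ICR = 15.9` and `ISF = 42.2` can absorb
errors up to ~11.3 g; one with a tight ratio may tolerate barely 5 g.

carbsafe computes these limits and stress-tests them in a simulated
90-day basal–bolus trial: a 33-subject virtual cohort (11 adults,
11 adolescents, 11 children), five meals a day, and ten error-injection
scenarios `E0` (error-free control) through `E9`, each defined by a 95%
normal error interval in multiples of `dCHO_max` — symmetric (`E1`),
within-limit under-/overestimation (`E2`–`E5`), on the limit (`E6`/`E7`)
and beyond it (`E8`/`E9`).  Glucose is generated by a minimal
glucose–insulin ODE model calibrated per subject so that its measured ISF
and meal response match the assigned therapy parameters; outcomes are the
CGM consensus metrics (TIR/TAR/TBR, %<50, %>300) and every scenario is
compared with the control by paired percentile bootstrap.

It is aimed at researchers in diabetes technology and simulation-based
trial design who want an open, reproducible test bed for counting-error
tolerance, without a proprietary metabolic simulator.

## Worked example

```r
library(carbsafe)

th <- therapy_params(icr = 15.9, isf = 42.2)   # adult population means
compute_delta_cho_max(th)
#> [1] 11.30332

build_error_spec("E8", 13.11)                  # beyond-limit underestimation
#> CC error spec E8: 95% interval [1, 1.5] x 13.11 g -> mu 16.387 g, sigma 1.672 g

fit <- run_trial(trial_config(master_seed = 1))  # ~20 s: 33 x 10 x 90 days
fit
#> In-silico CC-error trial: 33 patients x 10 experiments x 90 days
#> Excluded (control TIR < 90%): none
#> Strata: TIR == 100%: n = 33; TIR >= 90%: n = 33
#> Mean TIR (%) by experiment:
#>     E0     E1     E2     E3     E4     E5     E6     E7     E8     E9
#> 100.00  98.27  99.89  99.30  99.80  99.65  99.67  97.77  99.37  86.69
```

Reading: with exact counting (`E0`) every calibrated subject stays fully in
range.  Errors kept inside the personal limit (`E1`–`E5`) cost at most a
couple of TIR percentage points, while the beyond-limit scenarios degrade
sharply — most visibly `E9`, where 97.5% of meals are overestimated by more
than `dCHO_max` and mean TIR drops to 86.7%.  The bootstrap comparisons show
the mechanism:

```r
summary(fit)   # excerpt, stratum TIR >= 90%
#>   E6:  TIR -0.33 [-0.92, +0.00]  TAR +0.33 [+0.00, +0.92]  TBR +0.00 [+0.00, +0.00]
#>   E7:  TIR -2.23 [-2.86, -1.62]  TAR +0.00 [+0.00, +0.00]  TBR +2.23 [+1.61, +2.88]
#>   E8:  TIR -0.63 [-1.42, -0.06]  TAR +0.63 [+0.06, +1.46]  TBR +0.00 [+0.00, +0.00]
#>   E9:  TIR -13.31 [-13.85, -12.82]  TAR +0.00 [+0.00, +0.00]  TBR +13.31 [+12.82, +13.85]
```

Underestimation (`E6`, `E8`: too little insulin) shows up as time above
range, overestimation (`E7`, `E9`: too much insulin) as time below range —
the asymmetry that makes beyond-limit overestimation the clinically
dominant hazard here, since hypoglycemia targets (<4% TBR) are much
stricter than hyperglycemia targets (<25% TAR).
`plot(fit, metric = "tir", stratum = "tir90")` draws the difference bars
with their bootstrap whiskers.

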