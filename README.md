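# memdisc

Delay discounting, episodic memory, and gender in older adults: a tested,
reusable pipeline from raw binary intertemporal choices to discounting
parameters, memory scores, and moderated regression — with a
synthetic-cohort generator whose known ground truth makes every stage
verifiable by parameter recovery.

## Who this is for

Researchers analyzing (or simulating) titration-style intertemporal choice
tasks in which a smaller-sooner amount varies against a fixed larger-later
reward, and who want to relate individual discounting to cognitive
covariates — here, associative memory (face–name paired associates) and
autobiographical memory (events and personal semantics) — while testing
whether those relationships differ by gender.

## What it computes

Per participant, from six 18-trial blocks (later option fixed at 20 €,
sooner amount 0–20 € in 2.50 € steps; 108 trials, 24 of them dominated
catch trials used for attention QC):

1. **Indifference points** per block by logistic regression of choice on
   the sooner amount, `IP = -a/b`, with a midpoint fallback under perfect
   separation; converted to proportions of the 20 € reward.
2. **Discount models** fitted by bounded least squares to the four
   tomorrow-anchored IPs at *T* = 3, 6, 9, 12 months and compared by AIC:
   - hyperbolic: `SV(T) = 1 / (1 + kT)`
   - quasi-hyperbolic (β–δ): `SV(0) = 1`, `SV(T>0) = β·δ^T`, where β
     indexes present-bias and δ long-run patience (discount rate
     `log(1/δ)`);
   plus the model-free impulsivity count `NImp` (sooner choices on
   non-catch trials).
3. **Memory scores** on proportion scales: FNPA-PF = hits/20 − FA/20 in
   [−1, 1]; IGD-C1 and IGD-C2 in [0, 2] combining a recall-quantity and a
   quality/confidence proportion.
4. **Inference**: EM imputation of missing income under a joint normal
   model; three nested OLS models per outcome (memory scores → + gender,
   age, income, IQ → + gender × centered-memory interactions) with
   standardized betas and ΔR² F-tests; Shapiro-gated t / Mann–Whitney
   gender comparisons; Holm-corrected memory–covariate correlations; and
   median-split summaries.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted hierarchies support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(memdisc)

res <- run_pipeline(config = cohort_config(), seed = 1)
res
#> Intertemporal-choice pipeline (seed 1):
#>   58 participants, 0 excluded by catch-trial QC
#>   outcomes: ln_k, beta, delta, n_imp

dplyr::select(res$fits, participant_id, k, ln_k, beta, delta, preferred_model, n_imp)
#> # A tibble: 58 × 7
#>   participant_id      k  ln_k  beta delta preferred_model  n_imp
#>   <chr>           <dbl> <dbl> <dbl> <dbl> <chr>            <int>
#> 1 p001           0.117  -2.15 0.993 0.922 hyperbolic          31
#> 2 p002           0.0447 -3.11 0.885 0.978 quasi-hyperbolic    14
#> 3 p003           0.132  -2.03 0.944 0.921 hyperbolic          33
#> 4 p004           0.115  -2.16 0.993 0.923 quasi-hyperbolic    29
#> # ℹ 54 more rows
```

Each row is one simulated participant run through the full estimation
chain: `k` is the hyperbolic rate per month (`ln_k` its floored log), β
near 1 means little present-bias, δ near 1 means patience over months,
`preferred_model` is the lower-AIC model for that participant, and
`n_imp` of 84 non-catch trials counts impulsive choices.

```r
glance(res$hierarchies$ln_k)[, c("model", "statistic", "r.squared",
                                 "p.value", "delta_r2_f", "delta_r2_p")]
#>   model statistic r.squared p.value delta_r2_f delta_r2_p
#> 1     1     0.607    0.0326   0.613         NA         NA
#> 2     2     0.380    0.0505   0.910      0.236      0.917
#> 3     3     0.565    0.1074   0.833      0.998      0.402
```

With the default null configuration (no injected gender × memory effect)
none of the three models explains ln(k) — exactly what a calibrated
pipeline should report. Injecting an interaction
(`cohort_config(effect_gender_memory_on_lnk = 3)`) makes the model-3
increment significant and flips the high/low median-split ordering
between genders:

```r
plot_discount_curve(res$ips)                       # mean IPs + both model fits
median_split_summary(res$analysis, "igd_c2", "ln_k") |>
  plot_median_split("ln(k)")
```

Parameter-recovery and calibration experiments are one call each:

```r
recovery_experiment(n = 200, temperature = 5, seed = 1)   # beta/delta errors
interaction_power(effect = 0, reps = 1000, seed = 1)      # null calibration
```

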