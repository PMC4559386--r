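---
title: "Models and methods: from binary intertemporal choices to gender-by-memory interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdisc)
library(dplyr)
```

`memdisc` implements a complete analysis chain for a class of aging studies
that relate episodic memory to intertemporal choice: binary choices between
a smaller-sooner and a larger-later monetary reward are reduced to
indifference points, discount-model parameters, and hierarchical regressions
probing whether the memory–discounting relationship differs by gender.
Because raw participant data of this kind are rarely deposited, the package
ships a synthetic-cohort generator with known ground truth, making every
stage of the chain testable by parameter recovery.

## The choice task

The task has six blocks of 18 trials. The later option is always 20 € at
delay 3, 6, 9 or 12 months (blocks 1–4, sooner option available
"tomorrow") or at 9 or 12 months against a sooner option itself delayed by
6 months (blocks 5–6). The sooner amount runs over 0, 2.50, …, 20 €, each
offered twice per block. "Tomorrow" is encoded as delay 0 months: in the
quasi-hyperbolic model below, the extended present covers tomorrow, so the
present-bias parameter acts on everything strictly later. The one extra
day on the nominal delays (3 months *and one day*, etc.) is ignored as
negligible relative to monthly discount steps.

Trials offering 0 € or 20 € now are catch trials: one option dominates
(0-now vs 20-later should elicit *later*; 20-now vs 20-later should elicit
*sooner*, the earlier receipt of the same amount), so errors index
inattention rather than preference. Each block contains four of them, 24
in total. A participant answering more than half of their catch trials
(13+ of 24) against the dominant option is excluded. Both catch types are
counted.

Block order, trial order and the screen side of the sooner option are
randomized per participant under a seed; whether the original task
randomized block order per participant or once is not specified anywhere,
and per-participant randomization is the safer assumption for a simulator
(it averages out order effects by design).

## Indifference points

Within a block, the probability of taking the sooner option rises with its
amount. We fit the psychometric curve

$$P(\text{sooner}) = \operatorname{logit}^{-1}(a + b \cdot \text{amount})$$

by maximum likelihood and define the indifference point (IP) as the amount
at which both options are equally attractive, $-a/b$, clipped to $[0, 20]$
and expressed as a proportion of the 20 € delayed reward (10 € ↦ 0.5).
Catch trials enter the regression: the dominated offers anchor the tails
of the curve and cost nothing when the participant treats them logically.

With 18 binary trials, deterministic responders are the rule rather than
the exception, and then the likelihood has no finite maximum (perfect
separation). The package detects separation directly (a threshold splits
later- from sooner-choices) and falls back to a model-free estimate, the
area under the empirical choice curve over the nine amounts,

$$\widehat{IP} = 2.5 \sum_a \hat p_{\text{later}}(a) - 1.25,$$

which for a monotone deterministic responder is exactly the midpoint
between the largest always-later amount and the smallest always-sooner
amount (e.g. a threshold at 12.50 € gives (10 + 12.5)/2 = 11.25 €), and
degrades gracefully for non-monotone patterns. All-later responders get
IP = 20, all-sooner responders IP = 0 after clipping. The same fallback
guards non-converged or non-positive-slope fits (slope magnitude above 10
per euro is treated as quasi-separation). The `separated` flag in the
output records which route produced each IP.

## Discount models

Two models are fitted to the four tomorrow-anchored IP proportions at
$T = 3, 6, 9, 12$ months (blocks 5–6 inform QC and the model-free count
only). The hyperbolic model

$$SV(T) = \frac{1}{1 + kT}$$

summarizes discounting steepness in a single rate $k$ (1/months). The
quasi-hyperbolic (β–δ) model

$$SV(0) = 1,\qquad SV(T>0) = \beta\,\delta^T$$

separates present-bias $\beta \in [0,1]$ (a smaller β is a larger premium
on immediacy) from long-run patience $\delta \in [0,1]$, whose per-month
discount rate is $\log(1/\delta)$.

Both fits minimize the sum of squared IP errors: $k$ over $[0, 10]$ by a
log-spaced multi-start grid refined with bounded one-dimensional search
($k = 10$/month already collapses value to under 0.04 at three months, so
the bound is not a practical restriction), and $(\beta, \delta)$ over the
unit square by a coarse grid (0.05 × 0.02) refined with L-BFG-B from the
five best starts. Tests verify both fitters against dense-grid oracles;
the fitted SSE never exceeds the best grid value. β and δ are constrained
to $[0,1]$ because values outside the unit interval have no meaning in the
model, whatever an unconstrained optimizer might prefer.

Model comparison uses the least-squares AIC,
$n \log(SSE/n) + 2p$ with $n = 4$ points and $p$ = 1 or 2 parameters, the
SSE floored at $10^{-10}$ so exact fits remain comparable. On β–δ-generated
cohorts the quasi-hyperbolic model wins this comparison for the cohort
mean fit — the qualitative pattern the pipeline is designed to reproduce.
Because $\hat k = 0$ occurs at the patient boundary, regressions use
$\ln k$ with a floor of $10^{-4}$ before the log.

The model-free impulsivity count `n_imp` is the number of sooner choices
on the 84 non-catch trials; it runs through the same downstream
regressions as the fitted parameters.

## Memory scores

Three scores summarize the two memory instruments, all on proportion
scales:

* **FNPA-PF** (face–name paired associates): hits/20 − false alarms/20,
  in $[-1, 1]$. The raw hits-minus-false-alarms difference is divided by
  the 20 pairs of each type because only the proportion scale is
  consistent with published score magnitudes of roughly 0.3–0.6.
* **IGD-C1** (autobiographical events): events recalled (max 5 per
  life episode, 20 total) as a proportion of 20, plus the
  vividness/specificity/emotionality ratings as a proportion of their
  maximum 36; range $[0, 2]$. The 4-point rating scales are scored 0–3,
  because 4 episodes × 3 dimensions × 3 = 36 matches the printed maximum
  while 1–4 scoring would give 48.
* **IGD-C2** (personal semantics — facts and dates): the proportion of
  answered items endorsed "yes" plus the confidence awarded on the
  yes-items as a proportion of its maximum (0–3 each); range $[0, 2]$.
  The inventory's manual is not public; the normalization over yes-items
  (rather than all answered items) is the reading consistent with a
  half-confidence responder scoring 0.5 on the confidence component.

## The synthetic cohort

`cohort_config()` defaults describe a cohort of 58 healthy older adults
(30 women, 60–89 years, mean age 72.6): women outscore men on all three
memory scores (male means 0.33/1.62/1.66, female–male gaps
0.24/0.12/0.11, within-gender SDs ≈ 0.2, derived from published group
means and standard errors at these group sizes), incomes are log-normal
and lower for women (means 15.8k vs 29.4k €/year), and each income is
missing completely at random with probability 6/58. Scores are clamped to
their legal ranges; at these means and SDs the clamping shifts group
means by well under 0.01.

Discounting truth is generated on the log scale:

$$\ln k = \mu_k + \gamma \cdot \text{gender}_c \cdot \text{IGD-C2}_c + \varepsilon,$$

with centered gender and memory, so a positive interaction slope γ makes
discounting rise with memory in women and fall in men while leaving the
marginal gender difference at zero — the qualitative pattern the
regression stage is meant to detect. Defaults are $\mu_k = -2$ (median
$k \approx 0.14$/month) and $\varepsilon \sim N(0, 1)$; no published
distributional information exists beyond group means, so these are
documented configuration values, not claims about any real population.

Choices are simulated from the β–δ model with both options discounted
(necessary in blocks 5–6, where the sooner option sits at 6 months):
$P(\text{later}) = \operatorname{logit}^{-1}(\tau \,[SV_L - SV_S])$ with
subjective values in euros and temperature τ in 1/€ (default 2; ∞ gives
deterministic choice with fair-coin ties). Logistic choice noise is
chosen for conjugacy with the logistic IP regression; any smooth
symmetric noise would serve. Per-participant β and δ are derived from the
generated $k$ by matching the hyperbolic curve at 3 and 12 months
($\delta = (SV_{12}/SV_3)^{1/9}$, $\beta = SV_3/\delta^3$), so each
participant carries one internally consistent level of impatience and the
injected interaction on $\ln k$ propagates to the simulated choices. A
consequence worth knowing: default cohorts have δ around 0.94–0.96,
slightly more impatient in the long run than typical published means
(≈ 0.98); configure `lnk_mean` lower if that matters for an application.

What the generator does *not* emulate: response times, learning or
fatigue across blocks, session effects, non-logistic lapses, and any
dependence of missingness on income itself (missingness is MCAR). Passing
recovery tests therefore demonstrate that the estimation chain is
consistent for this generative family — not that real older adults behave
like it.

All randomness descends from one root seed through per-participant
substreams drawn row-wise, so enlarging a cohort leaves earlier
participants' data byte-identical.

## Missing data and inference

Missing incomes are filled by expectation-maximization under a joint
normal model over age, IQ, income and the three memory scores: E-step
conditional means given each row's observed entries, M-step mean/covariance
updates including the conditional covariance of the imputed entries,
iterated to a $10^{-6}$ change in imputed values (cap 200 iterations).
With missingness confined to one column this converges to regression
imputation from the complete cases, which is what the tests check against.
Observed values are never altered.

The regression stage fits three nested OLS models per outcome
($\ln k$, β, δ, `n_imp`): memory scores only; plus gender, age, income,
IQ; plus the three gender × memory interactions. Interaction regressors
multiply *mean-centered* memory scores with the gender indicator
(female = 1, male = 0), limiting the collinearity with the memory main
effects that uncentered products would produce — though with a binary
moderator substantial correlation remains, so memory main effects in
model 3 should not be interpreted. All variables, products included, are
z-scored before fitting; coefficients are standardized betas. Since no
convention fixes the gender coding, only the opposite-slopes pattern —
not coefficient signs — is a meaningful output. The increment from model
to model is tested with

$$F = \frac{(R^2_{\text{full}} - R^2_{\text{red}})/q}{(1 - R^2_{\text{full}})/(n - p_{\text{full}} - 1)},$$

which at $n = 58$ and 10 full-model predictors gives the (3, 47) degrees
of freedom characteristic of this design. Monte Carlo tests confirm the
model-3 interaction test holds its nominal 5% size under the null
(rejection rate within [0.03, 0.07] over 1000 cohorts) and recovers the
sign of an injected interaction essentially always at high signal.

Group descriptives use Shapiro–Wilk (α = 0.05) within each gender to
choose between a pooled-variance t-test and a Mann–Whitney U test;
memory–covariate correlations use Pearson or Spearman by the same gate
and are Holm–Bonferroni corrected within each covariate's family of three
tests (so a family's smallest p is compared to α/3 ≈ 0.017). Median
splits at the sample median (ties to the low group) provide the
descriptive high/low × gender cell means that accompany the interaction
regressions.

## Numerical choices, sizes, and limitations

* IP grid resolution bounds recovery: one amount step is 2.50 € = 0.125
  in proportion units, which is the honest error floor for β; δ, acting
  across four delays, is recoverable to ~0.01. The shipped recovery
  experiment (200 participants, temperature 5/€) achieves median absolute
  errors of about 0.03 (β) and 0.005 (δ).
* The hyperbolic $k$ recovered from β–δ-generated choices carries a small
  model-mismatch bias (~0.03 at low noise); error medians decrease with
  temperature down to that floor, not to zero.
* Default experiment sizes (200 recovery participants, 1000 null
  cohorts, 40 full-pipeline replicates, 50 oracle vectors) keep the whole
  verification suite in the minutes range on a single core while leaving
  Monte Carlo error well inside the asserted margins.
* Ties in the logistic choice rule (equal subjective values, e.g. the
  20-vs-20 catch trial under no discounting) resolve as a fair coin;
  degenerate IP blocks resolve to the clipped boundaries.
* The pipeline is frequentist and per-participant: no hierarchical
  pooling of IPs or discount parameters across participants, no
  reaction-time modelling, no exponential-model fit, and no attempt to
  reproduce any particular study's coefficient values — with synthetic
  data, only design arithmetic, worked examples, calibration and
  recovery are meaningful verification surfaces.

## A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(config = cohort_config(), seed = 1)
res$qc                      # catch-trial report, exclusions flagged
res$fits                    # k, ln k, beta, delta, AICs, NImp per participant
glance(res$hierarchies$ln_k)  # three models with increment F-tests
plot_discount_curve(res$ips)
plot_median_split(
  median_split_summary(res$analysis, "igd_c2", "ln_k"), "ln(k)"
)
```
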