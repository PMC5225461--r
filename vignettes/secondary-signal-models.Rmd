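---
title: "Secondary-signal models of training and performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary-signal models of training and performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trainsignal)
```

## The model family

The package models the dose-response relationship between daily training
load and physical performance through an indirect (secondary-signal)
mechanism, in the spirit of pharmacodynamic turnover models. Training on
day $i$ is an impulse dose $W_i$ (in training units, tu). It produces a
latent signal that accumulates and dissipates first-order; the signal — not
the training itself — drives the production of performance, which is
simultaneously removed first-order. Performance (watts, the mean power a
subject can sustain over a 5-min maximal trial) is measured sparsely, 2–3
times a week.

With day-0 state $Signal_0 = Inhib_0 = Fatigue_0 = 0$, $Perf_0$ fixed at
the first measured performance and $W_0 = 0$, the daily recursion is, for
$i \ge 1$:

$$
\begin{aligned}
Signal_i &= Signal_{i-1}\,e^{-k_{s1}} + W_i\\
Inhib_i  &= k_i W_i \\
Prod_i   &= k_{off}Perf_0 + k_{s2}\,(1 - Inhib_i)\,Signal_i\\
Perf_i   &= Perf_{i-1} + Prod_{i-1} - k_{off}\,Perf_{i-1}\\
Fatigue_i &= Fatigue_{i-1}\,e^{-k_{f2}} + k_{f1} W_i
\end{aligned}
$$

Four nested variants switch the inhibition and fatigue terms on and off:

| Model | free parameters | inhibition | fatigue | observable |
|-------|-----------------|------------|---------|------------|
| T     | 3 ($k_{off}, k_{s1}, k_{s2}$) | no | no | $Perf$ |
| TI    | 4 (+ $k_i$)     | yes | no | $Perf$ |
| TF    | 5 (+ $k_{f1}, k_{f2}$) | no | yes | $Perf - Fatigue$ |
| TIF   | 6 (all)         | yes | yes | $Perf - Fatigue$ |

The baseline production rate is not a free parameter: stationarity at zero
training ties it to the removal rate ($k_{0} = k_{off} Perf_0$), so
performance is *exactly* constant in the absence of training — a property
the test suite asserts for every variant.

Inhibition is memoryless and same-day: a large session reduces the
transformation of the *whole accumulated signal* into performance on that
day. The term $(1 - k_i W_i)$ is deliberately not clamped at zero; doses
above $1/k_i$ genuinely drive marginal production negative, which is what
creates the inverted-U steady-state dose-response. Fatigue, in contrast,
is a classic antagonistic first-order store subtracted from the
observable; its gain $k_{f1}$ is left unconstrained in sign because fits
to real data are known to turn it negative for most subjects.

## Discretisation choices

Two conventions are fixed and documented rather than hidden:

* **Decay-then-add within a day.** The signal (and fatigue) first decays
  from its previous-day level by the exact one-day factor $e^{-k}$, then
  receives the whole day's dose as an impulse. This keeps the constant-dose
  steady state clean: $S^\ast = w/(1 - e^{-k_{s1}})$.
* **Hybrid performance update.** Performance uses the Euler one-day
  removal factor $(1 - k_{off})$ — day $i$'s performance is day $i-1$'s
  plus the balance of production and removal on day $i-1$ — while the
  signal and fatigue stores use the exact exponential factor. A
  `perf_decay = "exp"` switch selects $e^{-k_{off}}$ instead; at the
  fitted scale ($k_{off} \approx 0.03$/day) the two differ by
  $O(k_{off}^2) \approx 0.05\%$ per day. Under either switch the baseline
  production is tied to the *same* one-day factor, so zero-training
  stationarity is exact in both.

A consequence worth knowing: production on day $i$ uses the same-day
signal, but performance on day $i$ uses production from day $i-1$. A
measurement on day $i$ is therefore unaffected by that day's load — the
trial's own 100 tu influence later days only.

## Fitting

Residuals are taken on measurement days between measured performance and
the model observable. Assuming i.i.d. Gaussian errors with the variance
profiled out at $\hat\sigma^2 = RSS/n$, the negative log-likelihood is
$\tfrac{n}{2}[\ln(2\pi RSS/n) + 1]$ — a monotone transform of RSS at fixed
$n$. The optimiser therefore minimises the RSS itself (identical argmin,
but quadratic and well-conditioned near an exact fit, where the profiled
likelihood diverges), with `stats::nlm()` on a transformed scale: log for
every positivity-constrained rate, natural scale for $k_{f1}$.

Because single-start nonlinear fits of this model family are known to be
start-sensitive, `fit_model()` launches 20 Latin-hypercube starts (package
`lhs`) inside boxes that bracket published estimates with at least a
three-fold margin: $k_{off} \in [0.001, 0.2]$, $k_{s1} \in [0.01, 2]$,
$k_{s2} \in [10^{-5}, 0.1]$, $k_i \in [10^{-5}, 0.01]$,
$k_{f1} \in [-1, 1]$, $k_{f2} \in [0.01, 2]$. `compare_models()`
additionally seeds each richer model with the optimum of its nested
reduction ($k_{f1} = 0$ exactly, $k_i = 10^{-8}$ since the log scale
cannot represent 0), which enforces the nesting inequality
$RSS_{full} \le RSS_{reduced}$ at the returned optima. All starts are
drawn under the caller's seed; fits are bitwise reproducible.

Two numerical guards:

* The back-transform clamps $e^\theta$ to $[10^{-300}, 10^{300}]$ so that
  a flat direction (e.g. $k_{f2}$ when $k_{f1} \to 0$) cannot underflow a
  rate to an invalid zero.
* The *reported* log-likelihood floors $\hat\sigma$ at
  `sigma_floor = 0.01` W. Residual standard deviations far below any
  plausible power-measurement resolution carry no evidence, and without
  the floor AICc diverges to $-\infty$ for every variant on noise-free
  data, leaving model choice to optimiser stall points. With it, exact
  fits tie on likelihood and the parsimony penalty decides — on noise-free
  Model T data the battery selects Model T deterministically. The floor
  is three orders of magnitude below realistic residual scales
  ($\hat\sigma \approx 3$ W) and never binds on noisy data; the reported
  RSS is never floored.

Convergence uses `gradtol = 1e-8` / `steptol = 1e-12` on the transformed
scale; `nlm` codes 1–3 are accepted (code 3 marks an approximate local
minimum at this very tight step tolerance).

## Model selection

`compare_models()` assembles the standard battery per variant: $R^2$
against TSS about the measurement mean, adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$, the mean square error
$SE = RSS/(n-p)$, the overall ANOVA F on $(p, n-p-1)$ degrees of freedom,
$AICc = -2\ln L + 2p + 2p(p+1)/(n-p-1)$ with $p$ the 3/4/5/6 parameter
count (the profiled $\sigma$ is not counted), Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$, and the nested F-ratio
tests T→TI, T→TF, TI→TIF, TF→TIF with
$F = [(RSS_r - RSS_f)/(p_f - p_r)]/[RSS_f/(n - p_f)]$ (a negative
numerator clamps $F$ to 0, $p$ to 1). P-values are kept at machine
precision; conventional thresholds appear only in rendered reports.

## Steady state, optimal dose, session interaction

Under a constant daily dose $w$ the signal converges to
$S^\ast = w/(1 - e^{-k_{s1}})$ and performance (sampled daily, after the
day's update) to

$$Perf^\ast = baseline + \frac{k_{s2}\,(1 - k_i w)\,S^\ast}{k_{off}},$$

with the denominator replaced by $1 - e^{-k_{off}}$ under the exponential
performance switch, and the fatigue steady state
$k_{f1} w/(1 - e^{-k_{f2}})$ subtracted for TF/TIF. The steady-state gain
is proportional to $w(1 - k_i w)$: an inverted U with interior maximum at
exactly $1/(2 k_i)$. `optimal_dose()` returns the golden-section maximiser
by default and the analytic value on request; the tests require agreement
within 0.5 tu and agreement of the closed form with long-horizon iteration
of the recursion to $10^{-6}$ W across a 20-point random parameter sweep.

```{r dose-response}
p <- model_params("TI", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
                  k_i = 0.0021)
steady_state_performance("TI", p, dose = 250, baseline = 250)
optimal_dose(p)
```

`session_interaction()` reproduces the single / next-day / two-days-later
session experiments from rest: all scenarios start with no training
history, and the per-session gain is the peak gain over baseline divided
by the number of sessions. Under Model T responses superpose exactly
(asserted to $10^{-10}$); under TI the second session inhibits the
transformation of the first session's residual signal, so the combined
peak is strictly sub-additive.

## The synthetic protocol generator

`build_protocol()` emulates a 15-week, six-subject cycling study plus a
baseline week: week 0 trials only; weeks 1–8 three combined
trial + 4-repetition-session days per week (Mon/Wed/Fri); week 9 rest with
trials only; weeks 10–13 five consecutive training days with trials on
days 1/3/5 and 5-repetition sessions on days 2/4; weeks 14–15 rest with
trials only. Trials are worth 100 tu; a session's dose follows
$W = 100 \cdot rep \cdot (P_{mean}/P_{lim5'})$ with intensity prescribed
at $P_{mean} = 0.85\,P_{lim5'}$ of the last measured performance, so the
per-session dose reduces exactly to $100 \cdot rep \cdot 0.85$ (340 tu for
4 repetitions, 425 for 5; 440 tu on combined trial days). The code
computes the reduced form directly — the prescription and the
normalisation share the same denominator — which also keeps the load
schedule exactly identical across noise seeds.

Weekday placement within weeks is a convention (the model is day-indexed);
week 0 carries three trials and rest weeks two, giving 45 trials, inside
the study's reported 40–46. The day-0 trial yields a measurement but its
load is recorded as 0, matching the recursion's $W_0 = 0$ initialisation.

`generate_subject()` walks the recursion day by day and adds i.i.d.
Gaussian noise (default `noise_sd = 3` W, which at these effect sizes
produces adjusted $R^2$ in the 0.93–0.99 range typical of such studies) to
the model observable on trial days. What the generator does *not* emulate:
day-to-day biological variability in responsiveness, missed sessions,
drift in trial execution, or serially correlated measurement error.
Passing recovery tests therefore demonstrates estimator correctness under
the model's own assumptions, not robustness to real-data misspecification.

One misspecification is, however, inherited from the study design and
shows up even in synthetic data: $Perf_0$ is anchored to the *noisy* first
measurement, not a free parameter. The anchor error propagates as a
quasi-constant offset in every prediction, and a slow negative fatigue
term can partially compensate it — so on single noisy subjects generated
from Model T, richer variants win the AICc comparison in a substantial
minority of noise draws. This is a property of the model family and
protocol, not of the optimiser.

## Problem sizes and runtime choices

The test suite fits at most ten starts per model in the six-subject
battery (24 fits) and uses 100 replicates at 10 starts for the noisy
parameter-recovery study and 10 replicates for the noise-free one; a
single 112-day fit with 10 starts takes well under a second. Steady-state
iteration checks run 30 000 days, enough to bring the slowest admissible
performance mode ($k_{off} = 0.001$/day) within $10^{-6}$ W of its fixed
point.

## Known limitations

* Sub-daily structure (session timing, within-day ordering of trial and
  session) is aggregated into one daily impulse.
* The inhibition term is memoryless; multi-day carry-over of
  maladaptation is representable only through the signal store.
* Parameter uncertainty is not quantified (no bootstrap or Bayesian
  machinery); the multi-start optimiser reports only the best local
  minimum and per-start objective values.
* With $k_{s2}$ small and $k_{s1}$ small (one published subject), the
  training effect is weak relative to 3 W noise and $k_{s1}$, $k_{s2}$
  are poorly identified; recovery assertions therefore target the
  removal and inhibition constants, which remain well identified.
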