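---
title: "Methods: simulating and analyzing the sequential patch depletion task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing the sequential patch depletion task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchdep)
```

## The task and its model

In the sequential patch depletion procedure a water-restricted rat chooses
between two "patches" (snout-poke receptacles). Entering a patch delivers an
initial reward of 150 uL; each further "stay" reward is reduced by 20%
(multiplicative retention 0.8), one reward every 4 s, so the schedule runs
150, 120, 96, 76.8, ... uL. Choosing to "leave" imposes a changeover delay
(COD) — the operational travel cost — during which no reward is available
anywhere, after which the alternative patch is entered at the full 150 uL
and the abandoned patch replenishes. Sessions end after 10 min or a
cumulative 5 mL, whichever comes first. The COD varies across sessions in
the cycle 0, 0, 6, 12, 18, 24 s, repeated four times; analysis uses the
last two cycles with the first (repeated 0-s) session of each cycle
excluded, so each COD contributes two analyzed sessions per subject.

`simulate_session()` runs this environment as an event loop for an
arbitrary stay/leave policy. Two modeling reductions are deliberate. First,
the live task allows two response topographies for staying (re-poking after
the 4-s interval, or holding the snout in the receptacle); both produce the
same reward timing, so the simulator has a single decision point per
reward. Second, response latencies default to zero, which makes sessions of
deterministic policies exactly periodic and the worked examples exact; an
exponential per-response latency (mean `latency_mean`, quantized to the
task's 1-ms clock) can be enabled so that time-based measures are not
degenerate — with zero latency and a 0-s COD, a leave-after-one-reward
agent accrues its whole session at time zero and its reinforcement rate is
infinite. Reward delivery itself is instantaneous (pump time is not
modeled). The volume cap is enforced by truncating the final reward so the
cumulative total equals the cap exactly; that reward lives in the final
patch, which the dependent measures exclude anyway. Patch identity always
starts at A. A leave is honored at any decision point, including during a
reward's 4-s unavailability window. Volumes are continuous uL throughout —
the canonical 150/120/96 sequence is exact under pure geometric decay, so
rounding would only obscure it.

## Optimality benchmarks

For a patch visit collecting $n$ rewards at changeover delay $c$, the
cumulative rate of return counts the COD as travel time:

$$R(c, n) = \frac{\sum_{k=1}^{n} 150 \cdot 0.8^{\,k-1}}
                 {c + 4\,(n-1)} \quad \text{(uL/s)}.$$

At $c = 6$ s this gives 25, 27 and 26.14 uL/s for $n = 1, 2, 3$: the rate
peaks at two rewards, so the optimal (Marginal Value Theorem) policy leaves
after the second reward and the optimal rejection volume — the scheduled
volume at the leaving position — is 120 uL. `optimal_n()` maximizes
$R(c, \cdot)$ by enumeration (ties toward fewer rewards; the rate must
already be declining at the search bound `n_max = 200`, which geometric
depletion guarantees and an assertion enforces for unusual configurations).
At $c = 0$ the first reward arrives at zero elapsed time; we adopt the
limiting convention $R(0, 1) = +\infty$, so the optimum is one reward and
the optimal time in patch is 0 s. Optimal time in patch is in-patch time
only, $4\,(n^\ast - 1)$, excluding the COD, paralleling the observed
time-in-patch definition.

```{r benchmarks}
benchmark_table(c(0, 6, 12, 18, 24))
```

### Two rejection-volume conventions

The *observed* rejection volume of a visit is defined one position beyond
the last collected reward: it is the next scheduled volume the subject
forgoes by leaving (a visit ending after 150 + 120 uL rejects 96 uL). The
classical *optimal* rejection volume, by contrast, is the scheduled volume
*at* the optimal leaving position (120 uL at a 6-s COD). These two
conventions differ by exactly one depletion step, and comparing them
directly would brand the optimal policy itself a 20% overharvester. The
benchmark therefore carries both: `optimal_rejection_volume` (classical)
and `optimal_next_volume` (`scheduled_volume(n_star + 1)`, the optimal
policy's forgone volume under the observed convention). All deviation
measures compare observed against `optimal_next_volume`, so an optimal
agent scores exactly zero; the classical figure is reported unchanged. We
surface rather than harmonize the discrepancy — users comparing against the
classical convention should expect the one-step offset.

One consequence worth noting: at a 0-s COD the optimal next volume is
120 uL, which is also the *ceiling* of what patch-leaving can express (a
subject always takes the entry reward, so it can never reject more than the
second scheduled volume). Noiseless threshold agents with bias $b \le 0.8$
therefore classify as exactly optimal at 0 s, and the decline of the
overharvesting fraction with delay is meaningful over positive CODs.

A related finite-horizon effect: ranking fixed-$n$ policies by their
*realized* session-long intake rate under the default caps does not quite
reproduce the steady-state optimum at every COD, because the 5-mL
truncation and the COD-free first patch favor marginally shorter visits
(at a 12-s COD the realized rates of $n = 3$ and $n = 4$ nearly tie). The
simulation-based cross-check of `optimal_n()` therefore lifts the volume
cap and lengthens the horizon so the long-run rate dominates.

## Dependent measures

Per session, the first and final patches (and their patch changes) are
excluded; a session with two or fewer visits yields missing measures rather
than zeros, since the exclusion rule leaves nothing to average. Over the
included visits:

* **Water rate** (uL/min): summed volume divided by the span from the first
  included entry to the last included exit. The span includes the interior
  CODs by default (`rate_includes_cod = TRUE`) — the time cost of travel is
  exactly what the MVT trades against — but the in-patch-only denominator
  is available as a documented toggle.
* **Patch changes**: the number of included visits, each terminated by a
  leave.
* **Time in patch** (s): mean visit duration.
* **Rejection volume** (uL): mean forgone next scheduled volume — the
  indifference point.
* **Percent volume deviation**: $(\text{optimal} - \text{observed}) /
  \text{optimal} \times 100$ against `optimal_next_volume`; positive =
  overharvesting. **Percent time deviation** uses the same form with the
  sign convention that staying longer than optimal is negative. At a 0-s
  COD the optimal time is zero and the time deviation is undefined; it is
  reported missing, not imputed.
* **Harvest class**: over / optimal / under by the sign of the volume
  deviation (exact zeros are "optimal").

Subject-level measures average the analyzed sessions (two per COD under the
default schedule); missing session measures propagate.

## The synthetic cohort

No raw animal data accompany the study design this package implements, so
the cohort generator is a first-class module rather than a test fixture.
Each subject is a *myopic indifference-threshold agent*: it values the
replenished alternative (amount $A = 150$ uL at delay $c$) at the
hyperbolic discount

$$v^\ast = \frac{b\,A}{1 + k\,c},$$

and leaves when the next scheduled volume has depleted to $v^\ast$ or below
(the "or below" tie-break makes a $b = 0.8$, $k = 0$ agent leave
immediately after every entry reward, where the threshold equals the second
scheduled volume exactly). With choice noise the leave probability is
logistic in the value gap, $P(\text{leave}) = \text{logit}^{-1}((v^\ast -
v_{\text{next}}) / \tau)$, with temperature $\tau$ in uL; $\tau = 0$ is the
deterministic rule. We chose this generative family, rather than a
rate-maximizing agent, because the hyperbolic fit is then the matched
estimator and parameter recovery is well-posed; the MVT agent is provided
separately as the optimal reference. The logistic noise structure is our
modeling choice — the task description specifies none.

Population defaults: $k$ lognormal per sex (median 0.1 s$^{-1}$, geometric
SD 2.5 — positive and right-skewed, as discount rates typically are), bias
$b$ truncated-normal (mean 0.8, SD 0.05, clipped to $(0, 1]$; 0.8 is the
observable ceiling noted above), noise temperature 5 uL, mean latency
0.5 s. The default `n_per_sex = 100` keeps test-suite cohorts fast; the
study scale (896 males, 898 females) is one argument away. Each subject
draws from a private substream derived from the master seed and its index,
so cohorts are reproducible independently of iteration order.

What the generator does *not* emulate: estrous cycles, body-weight and
water-restriction physiology, batch/site effects, within-session learning,
or any serial dependence in choices beyond the threshold rule. Passing
tests therefore certify the pipeline's arithmetic and the internal
consistency of the analysis on data that *obey* the hyperbolic threshold
model — they cannot certify that real rats obey it.

## Discounting fits

`fit_k()` fixes the bias from the 0-s indifference point ($b = v_0 / A$, as
in the fixed-bias hyperbolic parameterization) and least-squares fits $k$
on the positive delays, searching $[0, 100]$ s$^{-1}$: a log-spaced grid of
~80 candidates brackets the optimum, `stats::optimize()` (tolerance
$10^{-10}$) refines it, and both boundaries stay in the candidate set so a
flat profile returns exactly $k = 0$. Noiseless hyperbolic profiles are
recovered to $10^{-6}$.

Because patch leaving can only express indifference points on the geometric
volume grid (120, 96, 76.8, ... uL), even noiseless threshold agents yield
quantized points, and $\hat k$ inherits a quantization error. The test
suite bounds it with an explicit oracle — snap the exact hyperbolic profile
to the grid, refit, and require the pipeline's $\hat k$ to match that
refit — rather than hiding it; rank recovery across a two-decade $k$ range
remains near-perfect (Spearman $\rho > 0.99$ for 200 agents).

Normalized AUC is the trapezoidal area of the indifference-point curve with
delays scaled by the maximum delay and volumes by $A$ (comparable across
subjects); normalizing by the subject's own 0-s point is available via
`auc_normalize_by = "v0"`. The delays used are the schedule actually run,
$\{0, 6, 12, 18, 24\}$ s.

## Composite scores and correlation comparisons

Composites sum each delay-varying measure across the five CODs (time
deviation across the four positive CODs, where it is defined) and carry $k$
and AUC through; subjects with any missing piece are listwise-dropped with
a message. Pearson matrices over the seven variables (k, AUC, VD, TD, TIP,
PC, WR) are computed per sex with t-distribution p values.

To compare the strength of two correlations sharing a common variable on
the same subjects, `meng_z_test()` implements the
Meng–Rosenthal–Rubin procedure: with $\bar r^2 = (r_{y1}^2 + r_{y2}^2)/2$,
$f = \min\!\big(1, (1 - r_{12}) / (2(1 - \bar r^2))\big)$ (the cap follows
the original recommendation) and $h = (1 - f \bar r^2)/(1 - \bar r^2)$,

$$z = \big(z_{r_{y1}} - z_{r_{y2}}\big)
      \sqrt{\frac{N - 3}{2\,(1 - r_{12})\,h}},$$

two-tailed normal $p$. The suite verifies the algebraic fixed points
($z = 0$ at equality, antisymmetry under swapping), calibration (type-I
error $0.05 \pm 0.01$ under a simulated trivariate-normal null, $N = 200$,
$10^4$ replicates) and agreement of the rejection decision with a
Monte-Carlo oracle for the sampling distribution of the Fisher-z
difference. `comparison_table()` arranges the 4 comparisons
(k/AUC vs. VD/TD) by 3 common variables (TIP, PC, WR) per sex — twelve
cells per sex, the classical layout. No multiplicity correction is applied
to the correlation matrix, matching the two-tailed 0.05/0.01 reporting
convention it accompanies.

## Numerical and I/O choices

* All event times live on the task clock's 1-ms grid (the apparatus
  resolution), which is also the 3-decimal text grid of the event-log CSV;
  volumes are written with 17 significant digits and re-parsed with a
  correctly rounded converter, so write-then-read is *bit-identical* on
  every field and re-analyzing a written log reproduces the measures
  byte for byte.
* The event-log dialect has no termination column; the reader re-derives
  the termination reason from the totals against the caps, which is exact
  under the truncate-to-cap rule.
* Same-seed replays of the simulator, the cohort generator, and the whole
  pipeline are byte-identical; the pipeline manifest records the seed and a
  configuration hash.
* Problem sizes used by the test suite — e.g. 50 optimal-policy subjects
  for the end-to-end null, 200 noiseless agents for recovery, $10^4$
  replicates for z-test calibration, 40 subjects per sex for the
  qualitative sex-contrast cohort — were chosen as the smallest scales at
  which the corresponding claims are stable, and are stated in the tests
  themselves.

## Known limitations

* The threshold agent is myopic: it never integrates over future patch
  cycles, so its behavior encodes the hyperbolic model by construction.
  Real subjects may mix rate maximization, perseveration and side biases
  the generator does not produce.
* Quantization to the volume grid bounds how finely $k$ can be resolved
  from noiseless patch-leaving; the bound is explicit in the recovery
  oracle.
* With zero latency, time-based measures at a 0-s COD are degenerate
  (infinite rate); enable latencies when those measures matter.
* The deviation measures use the matched (next-volume) convention
  throughout; analyses tied to the classical optimal-rejection-volume
  convention should read it from the benchmark table instead.
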