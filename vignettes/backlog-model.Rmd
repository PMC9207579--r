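---
title: "A waiting-list backlog model for severe aortic stenosis treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A waiting-list backlog model for severe aortic stenosis treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asbacklog)
```

## The model

Severe symptomatic aortic stenosis is lethal untreated — on the order of
half of patients die within two years of symptom onset — and the only
effective treatment is valve replacement, surgical (SAVR) or
transcatheter (TAVI). The pandemic left an *excess* backlog $W_0$ of
untreated patients on top of a system whose routine capacity only covers
the normal inflow of new cases. We model the excess list as a single
national compartment that shrinks through exactly two flows: death while
waiting, at a constant per-person hazard $\mu$, and treatment through
*surplus* capacity $T_e$ (procedures per year above the prepandemic
baseline):

$$\frac{dW}{dt} = -\mu W - T_e, \qquad W(0) = W_0 .$$

Solving gives $W(t) = (W_0 + T_e/\mu)e^{-\mu t} - T_e/\mu$, the
clearance time (first zero of $W$)

$$t_c = \frac{\ln\!\left(1 + W_0\mu/T_e\right)}{\mu},$$

and, since treatment removes exactly $T_e t_c$ patients by then, the
waiting-list mortality

$$m(t_c) = W_0 - T_e t_c .$$

The three compartments conserve patients at every time:
$W(t) + \text{treated}(t) + \text{deaths}(t) = W_0$ up to clearance
(`waitlist_trajectory()` returns all three).

Key assumptions, all deliberate simplifications:

* **Steady state before the shock.** The prepandemic system absorbed its
  inflow, so inflow cancels out of the excess-list balance and the
  steady-state list can be set to zero without loss of generality.
* **One national list.** Population and capacity are treated as evenly
  distributed; centre-level heterogeneity would lengthen real clearance.
* **$\mu$ is an instantaneous exponential hazard**, used directly at its
  annual value (0.36/year), not converted from a one-year risk via
  $-\ln(1-0.36)$. The two conventions differ materially; the direct
  convention is the one under which the closed forms, the daily-step
  simulation oracle and the published scenario outcomes all agree, which
  is how we fixed it before building the rest of the package.
* **Constant surplus capacity** for the whole recovery period; no
  ramp-up, no inflow shocks, no re-entry of survivors.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| $W_0$ | excess backlog | 4989 (95% CI 4020–5959) | persons |
| $\mu$ | mortality hazard untreated | 0.36 (95% CI 0.12–0.60) | 1/year |
| $r_{S0}$ | baseline SAVR throughput | 7830 | procedures/year |
| $r_{T0}$ | baseline TAVI throughput | 5197 | procedures/year |
| year | day-count convention | 365 | days |

Defaults are the published NHS England estimates and are baked into
`population_params()` and the scenario-file loader, so an empty scenario
file is the national baseline.

## Strategies and surplus capacity

Two levers create surplus. A *general* increase by fraction $c$ adds
$c(r_{S0}+r_{T0})$ procedures/year; at $c = 0.05$ this is 1.785 extra
procedures per day nationally. *Conversion* of a fraction $p$ of SAVR
cases to the faster TAVI procedure frees operating time: at
time-equivalence ratio $a\!:\!b$ ($b$ TAVI fit in the time of $a$ SAVR;
default 2:3, sensitivity ratios 3:4, 2:4, 3:5), each converted case
frees $b/a - 1$ slots, so the surplus is $p\,r_{S0}(b/a-1)$. Slot counts
are stored as integers and the factor $b/a-1$ is formed only at
evaluation, so ratios stay exact.

When both levers combine, the general increase is applied to the
**post-conversion throughput**:
$T_e = \text{conv} + c\,(r_{S0}+r_{T0}+\text{conv})$. This was a
genuinely open design point (the alternative applies $c$ to the
prepandemic mix); we adopted the post-conversion convention because extra
lists added after converting cases run at the converted case mix, and
because only this convention reproduces the published combined-strategy
outcomes — the prepandemic-mix alternative predicts clearance roughly 20
days slower for the 40% + 20% strategy.

Short-term clinical constraints cap both $p$ and $c$ at 50%; the caps are
*soft* (a warning, suppressible with `allow_above_cap = TRUE`) because
the doubling scenario legitimately uses $c = 1$.

## Monte-Carlo uncertainty propagation

`draw_parameters()` is the package's synthetic-data generator: it draws
$(W_0, \mu)$ pairs independently from normal distributions whose means
are the point estimates and whose standard deviations are recovered from
the 95% CIs as half-width divided by `qnorm(0.975)` (1.959964…, not the
rounded 1.96 — cosmetic, but stated so ranges are bit-reproducible).
Draws are truncated below — $W_0$ at 0, $\mu$ at $10^{-4}$/year — by
rejection resampling: about 0.16% of untruncated $\mu$ draws would be
negative, where the system never clears and the closed form leaves its
domain; resampling preserves unimodality and moves the means by far less
than the reporting precision. A floor above mean $+ 5\sigma$ is rejected
at configuration time because rejection would stall.

`mc_summary()` pushes each draw through the closed forms and reports the
mean and the empirical 2.5/97.5 percentiles (the 95% *reference range*,
a distribution interval, not a CI of the mean). Percentiles use linear
interpolation between order statistics (`quantile()` type 7). The
default draw count is 10 000 and the default seed 20220616 (an arbitrary
fixed integer; every function accepts any seed). Because $t_c$ is convex
in both parameters, the Monte-Carlo mean exceeds the point estimate — a
Jensen gap of a few days at +20% capacity — so the two modes are kept
distinct throughout and never interchanged.

What the generator emulates is *parameter* uncertainty only. It does not
emulate correlated uncertainty between $W_0$ and $\mu$, uncertainty in
the baseline throughputs or the conversion ratio, non-normal tails,
centre-level heterogeneity, or stochastic inflow. Tests passing under
this generator therefore validate the propagation machinery and the
closed forms, not the realism of the input distributions.

## Planner: grids, isoclines, inversion

`compute_grid()` evaluates both outcomes over a
(conversion, capacity) lattice, in point-estimate mode or as Monte-Carlo
means. MC-mean surfaces reuse **one fixed draw set across all cells**
(common random numbers), which makes each objective a smooth, strictly
monotone function of $c$; `find_capacity_for_deaths()` /
`find_capacity_for_time()` then invert it with Brent root finding
(`uniroot`, tolerance $10^{-8}$ on $c$, comfortably below the 0.5-person
/ 0.1-day objective tolerances used in the tests). Isoclines are
extracted by per-column inversion rather than marching squares: each
contour point is individually testable against the forward model, and
the contour inherits monotonicity (required capacity falls as conversion
rises) from the surplus arithmetic.

The zero-surplus cell $(p,c) = (0,0)$ never clears; grids store a
sentinel there — infinite clearance time, with the one-year zero-surplus
death count $W_0(1-e^{-\mu})$ as the mortality marker — rather than
failing, so heatmaps render the full domain. Note the marker is a
one-year figure, not a clearance total, so it is deliberately excluded
from monotonicity comparisons with clearing cells.

Whether published planning contours were drawn on MC means or point
estimates was not stated; both modes are provided and `mc-mean` is the
default because the benchmark planning statements (deaths held to 1000
by +25% capacity at no conversion, or +8.7% at 50% conversion) are
reproduced in that mode.

## Numerical choices

* $t_c$ is evaluated as `log1p(W0*mu/Te)/mu`; for $|\mu| < 10^{-8}$ the
  series limit $W_0/T_e$ is returned. At the branch point the two forms
  agree to ~$10^{-10}$ relative, so the function is continuous in $\mu$.
* $m(t_c)$ is clipped into $[0, W_0]$ only within $10^{-9}$ relative
  tolerance; a larger violation means `tc` did not come from the same
  parameters and is an error, not a clamp.
* The trajectory is truncated at zero for $t \ge t_c$; the model is
  defined only up to clearance.
* Non-clearing regimes ($T_e \le 0$, or $1 + W_0\mu/T_e \le 0$ under
  negative hazards) are errors in the closed forms and sentinels in
  grids.
* Day values are kept in floating point throughout; rounding to whole
  days happens only in `print()` methods.

## Simulation oracles

Two independent brute-force implementations guard the closed forms.
`simulate_deterministic()` integrates the same flow balance with explicit
Euler steps (deaths accumulated as $\mu/365 \cdot W \cdot h$ per step,
crossing located by linear interpolation); it is first-order convergent
and agrees with the closed forms to better than $10^{-3}$ relative at a
$10^{-3}$-day step — the test suite asserts this over a 5×5
$(W_0, T_e)$ grid. `simulate_stochastic()` is a patient-level queue with
integer patients: each day every waiting patient dies with probability
$1-e^{-\mu/365}$ (deaths applied *first* — the ordering changes tallies
at $O(h)$ and must be fixed for reproducibility), then accumulated
fractional treatment slots are spent on whole patients with the unspent
fraction carried over, so annualised capacity is never lost to rounding.
Replicate means converge to the deterministic tallies (within 3% at 200
replicates in the tests) and each replicate conserves
treated + died + waiting $= W_0$ exactly.

## Problem sizes in the test suite

The suite runs Monte-Carlo summaries at the full $n = 10\,000$ (they are
vectorised and cheap), the Jensen-gap check at $n = 10^5$, the stochastic
queue at 200 replicates, and the Euler grid at a $10^{-3}$-day step over
25 cells whose clearance times stay under two years. These sizes were
chosen as the smallest at which the assertions are comfortably inside
their tolerances.

## Known limitations

Everything the model omits is a direction in which reality is worse or
simply different: centre-level heterogeneity, waiting-time-dependent or
prioritisation-dependent mortality, TAVI demand growth, post-procedural
resource constraints (ICU, length of stay), clinical eligibility limits
on conversion, and pandemic deaths already removed from the backlog
estimate. The package quantifies a deliberately spare national-level
balance; treat its outputs as planning magnitudes, not forecasts.
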