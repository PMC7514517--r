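---
title: "Maximum-entropy modelling of territorial population distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy modelling of territorial population distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxentpop)
library(dplyr)
```

## The model

A country is divided into `N` territorial units (TUs). In year `t` the
unit populations `b_i` define shares `p_i = b_i / B` on the simplex.
The modelling premise is that a population distribution is shaped by
the flows of information, energy and matter that sustain it, and that
— absent further knowledge — the least-committed estimate of `p`
compatible with what *is* known is the one maximizing Shannon entropy

$$H(p) = -\sum_{i=1}^N p_i \ln p_i$$

subject to $\sum_i p_i = 1$, $p_i \ge 0$, and linear restrictions
$\sum_i p_i\, g_r(i) = C_r$. The restrictions come in two families.

**Flow restrictions.** For each flow variable — higher-education
students (an information flow), electricity consumption in kWh
(energy), water demand in m³ (matter) — write `u_i` for the unit total
and `alpha_i = u_i / b_i` for its per-capita rate. Weighting each unit
by its share of the national total `q_i = u_i / U` gives the
self-weighted departmental mean `u_bar = sum_i q_i u_i = sum_i u_i^2 / U`,
and algebra on `u_i = alpha_i b_i` yields the restriction

$$\sum_i p_i\, u_i\, \alpha_i \;=\; \bar{u}\, A, \qquad A = U/B,$$

with exact analogues for electricity and water. Two properties matter
here. First, the self-weighted mean (not the simple mean `U/N`) is the
only choice for which the observed shares satisfy the restriction
*identically* on self-consistent data — both sides reduce to
`sum_i u_i^2 / B`; by Cauchy–Schwarz it always dominates the simple
mean. Second, because rates are always derived as `u_i / b_i` from the
stored totals, every panel this package reads or generates is
self-consistent by construction, so the three flow rows are jointly
feasible with the true distribution inside the feasible set.

**Index-moment restrictions.** Flow restrictions alone reproduce the
broad shape of the distribution but fail badly on thinly populated
units, where access to services and education does not govern where
people live. Social inertia — attachment to place, family, tradition —
is encoded by constraining the raw moments of the *unit index* under a
reference distribution: after assigning each unit an index `1..N`,

$$\sum_i i^m\, p_i = C_m, \qquad C_m = \sum_i i^m\, p^{\mathrm{ref}}_i,
\quad m = 1, \dots, m_{\max},$$

with `p_ref` by default the previous year's observed shares
(`moment_ref = "previous"`), optionally the current year's
(`moment_ref = "current"`). Because the restriction acts on positions,
the permutation assigning units to indices is part of the model:

* `descending` — largest unit at index 1, ties broken by unit code;
* `bell` — largest unit at the central index `floor(N/2) + 1`,
  subsequent ranks placed center-outward alternating right then left
  (the right side first), so populations fall toward both ends;
* `original` — official code order.

The bell construction is one of several possible center-outward
placements; the alternation rule above was fixed once and is the
package's convention. The permutation is frozen at the first
calibration year and reused for every subsequent year. Recomputing it
annually would make the moment series `C_m(t)` incomparable across
years — a unit hopping between indices changes `C_m` discontinuously —
and the forecast stage depends on those series being smooth.

## The solver

The maximizer of `H` under linear restrictions is the exponential
family member
$p_i = \exp(-\lambda_0 - \sum_r \lambda_r g_r(i))$,
found by minimizing the convex dual
$\ln Z(\lambda) + \sum_r \lambda_r C_r$. The implementation is a
damped Newton iteration:

* **Initialization** at `lambda = 0`, the uniform distribution; the
  solve is fully deterministic.
* **Conditioning.** Raw moment rows reach `33^10 ≈ 1.5e15`, which
  would destroy the dual Hessian. Each row is first rescaled to unit
  maximum absolute value (recorded in the constraint set's `scale`
  field; by scale invariance this does not move the solution), then
  the row space is centered and orthonormalized by QR internally.
  Centering only shifts `lambda_0`; orthonormalization is an
  invertible recombination of rows, undone when the multipliers are
  reported on the original scale. In the working basis the Hessian at
  the uniform start is essentially the identity, and ten-moment
  problems on 33 units converge in under ten iterations.
* **Line search.** Backtracking halving with an Armijo condition on
  the dual; when the predicted decrease falls below floating noise the
  full Newton step is taken, which avoids stalling at the numerical
  floor.
* **Convergence** when `max_r |residual_r| / max(1, |C_r|) <= tol`
  (default `1e-10`), residuals taken on the unit-rescaled rows. Since
  any feasible target satisfies `|C_r| <=` the row maximum, the
  rescaled criterion is effectively an absolute one.
* **Degenerate inputs.** Targets are range-checked per row before
  iterating (a target outside the open attainable range is refused as
  infeasible; a constant row must equal its constant); rank-deficient
  row sets — duplicated or collinear rows — are refused as a
  conditioning error; more than `N - 1` rows are refused because
  normalization consumes the last degree of freedom.

Verification is double-routed: a 1-D bisection oracle on the geometric
family for single-restriction problems, a simplex-grid brute force for
`N = 3`, and an augmented-Lagrangian softmax optimizer for general
small instances — all independent of the dual Newton path.

## Calibration, trends, forecast

`calibrate()` assembles, per year, the configured flow rows from that
year's macro-state plus moment rows from the reference shares, solves,
and scores against the observed shares with two metrics: RMSE on the
shares, `sqrt(mean((p_est - p_true)^2))`, and the mean relative error
`100 * mean(|p_est - p_true| / p_true)` in percent. The relative-error
definition weights every unit equally, which is deliberate: it exposes
the small-unit failure mode that a population-weighted metric would
hide. An infeasible or non-convergent year is recorded with its
message and skipped rather than aborting the window.

`fit_moment_regressions()` fits `C_m = slope * year + intercept` by
ordinary least squares per moment order, with the Pearson correlation
as a trend diagnostic (a constant series is flagged degenerate with
correlation reported as 0). `forecast()` then rebuilds each
out-of-window year from *predicted* inputs only: per-unit flow totals
extrapolated by per-unit OLS lines over the calibration years
(non-positive extrapolations clamped to the last observed value, with
a warning record), per-capita rates frozen at their last calibration
values, moment targets from the fitted trend lines, and the national
macro-state recomputed from the extrapolated totals. Predicted moment
targets are range-checked like any others; a year whose predicted
targets leave the attainable range is reported infeasible and skipped.

## What the synthetic generator does and does not emulate

`generate_panel()` draws first-year shares from a normalized power law
over ranks; the default exponent 0.744 puts 0.16 on the top unit of
33 — the observed concentration in the setting this package targets,
with the smallest unit near 0.012. National population defaults to
4e7. Per-unit populations follow exactly linear trends (growth rates
drawn once per unit, mean 1.2%/year, sd 0.8%), rates are drawn once
per unit from ranges a demographer would accept (students 1–6% of
population; 300–3000 kWh per head; 20–120 m³ per head), and totals are
`rate × population`, students rounded to whole persons. Optional noise
is multiplicative log-normal on every total, with shares renormalized
— positivity and the simplex are preserved by construction.

The generator reproduces the *statistical* structure the method needs
(heavy tail, smooth trends, self-consistent flows). It does not
attempt spatial correlation, migration shocks, census revisions, or
reporting error that correlates across variables — so green tests here
demonstrate correctness of the machinery, not forecasting skill on any
real country.

`generate_planted_panel()` additionally makes the truth *exactly*
recoverable: yearly targets for `m_max` moment rows interpolate
linearly between the moment vectors of two rank-law distributions
(a convex path, hence always feasible), the true shares are defined as
the maximum-entropy solution of those rows, and the panel is rebuilt
from the shares. Two facts make this a sharp end-to-end test. The flow
rows are satisfied by the truth identically (previous section), and
adding restrictions that the current solution already satisfies cannot
change a maximum-entropy solution; so calibrating with
`moment_ref = "current"` and the emitted (descending) ordering must
return the planted truth to solver precision. With
`moment_ref = "previous"` recovery is only approximate — the targets
drift between years by design — which is why the recovery tests pin
the `current` mode. The same Pythagorean property of entropy
projections (restrictions satisfied by the truth can only shrink
`KL(truth || estimate)`) underlies the tested invariant that adding
flow rows to a truth-feasible moments model does not worsen the fit.

## Problem sizes and numerical choices in the tests

The test-suite experiments use the full 33-unit country with 7–17 year
panels; solver cross-checks run on 3–8 units where brute-force and
penalty oracles are sharp. These sizes were chosen because every
qualitative phenomenon of interest — the error decay in the moment
count, the descending-versus-bell gap, the small-unit error
concentration — is already stable at them; nothing in the machinery is
specific to 33 units. Key tolerances: solver residuals `1e-10`
(default), exact-recovery assertions `1e-8` on shares, flow identities
`1e-12` relative, oracle agreement `1e-6`.

## Known limitations

* Moment restrictions make the model self-referential: most predictive
  power comes from the previous distribution, and the flow variables
  refine rather than drive the estimate. This mirrors the method being
  packaged; the moments-only comparison in the acceptance script
  quantifies it.
* Relative errors on the smallest units remain large (tens of percent
  on noisy panels, hundreds on flow-only models) — the well-documented
  weak spot of this model family.
* Forecast uncertainty is not quantified; the RMSE-based band one can
  back-compute for a single unit is descriptive, not inferential.
* Continuous-support maximum entropy and migration dynamics are out of
  scope; only the discrete TU case is implemented.
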