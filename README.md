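# maxentpop

Maximum-entropy modelling of how a national population distributes
itself across territorial units (departments or provinces), driven by
socio-ecological flow variables and by the statistical memory of the
previous distribution.

## The problem

A country of `N` territorial units (TUs) has yearly population shares
`p_i = b_i / B`, where `b_i` is the population of unit `i` and `B` the
national total. At the national scale only aggregate quantities are
easy to observe — total higher-education enrolment, total electricity
consumption, total water demand. The question this package addresses:
given those macro-state aggregates, what is the most unbiased estimate
of the regional distribution `p`?

Following the maximum-entropy principle, the answer is the distribution
that maximizes Shannon entropy

    H(p) = - sum_i p_i ln p_i

subject to the normalization `sum_i p_i = 1` and to linear restrictions
`sum_i p_i g_r(i) = C_r` encoding what is known. Two families of
restrictions are built:

* **Flow restrictions.** Each flow variable — students `u_i`
  (information), electricity `ce_i` in kWh (energy), water `cw_i` in
  m³ (matter) — with per-capita rate `alpha_i = u_i / b_i`, contributes

      sum_i p_i u_i alpha_i = u_bar * A,

  where `u_bar = sum_i u_i^2 / U` is the self-weighted mean of the
  variable across units and `A = U / B` its national per-capita rate
  (analogously for electricity and water). On self-consistent data the
  observed shares satisfy these identically.

* **Index-moment restrictions.** After reordering units by population
  (descending, or bell-shaped with the largest unit central), the raw
  moments of the unit index under a reference distribution — by
  default the previous year's shares — are imposed:
  `sum_i i^m p_i = C_m`, `m = 1 ... m_max`. These encode the
  population's tendency to stay where it is.

The unique maximizer has exponential form
`p_i = exp(-lambda_0 - sum_r lambda_r g_r(i))`; the package finds the
multipliers by Newton's method on the convex Lagrangian dual, with
internal row rescaling and orthonormalization so that even ten
high-order moment rows on 33 units stay numerically tame.

A calibration/forecast pipeline wraps the solver: per-year calibration
against observed shares; linear-trend regressions of the moment targets
and per-unit least-squares extrapolation of the flow totals (with
per-capita rates held constant) for out-of-window verification. Since
the national datasets behind such studies are rarely deposited, a
seeded synthetic generator emulates the setting — 33 units, a
heavy-tailed share distribution with the capital around 16%, linear
yearly trends — and a *planted-truth* mode produces panels whose true
shares are exactly the maximum-entropy solution of a known restriction
set, enabling exact end-to-end recovery tests.

## Worked example

```r
library(maxentpop)

panel <- generate_panel(generator_config(seed = 1))   # 33 TUs, 2000-2015
cal   <- calibrate(panel, 2001:2010)                  # 3 flows + 10 moments, descending
cal
#> <maxent_calibration: 10 year(s) 2001-2010, flows = {students, electricity, water}, m_max = 10, descending ordering>
#>   mean relative error 2.508%, mean RMSE 0.000877 over 10 converged year(s)

fc <- forecast(panel, cal, 2011:2015)
glance(fc)
#> # A tibble: 1 × 5
#>   n_years n_converged n_scored mean_rmse mean_rel_err_pct
#>     <int>       <int>    <int>     <dbl>            <dbl>
#> 1       5           5        5   0.00180             5.39

head(fit_moment_regressions(cal), 3)
#> # A tibble: 3 × 5
#>       m   slope intercept correlation degenerate
#>   <int>   <dbl>     <dbl>       <dbl> <lgl>
#> 1     1 0.00661     -2.80       1.000 FALSE
#> 2     2 0.0971       1.22       1.000 FALSE
#> 3     3 1.83       881.         1.000 FALSE

error_report(cal, fc)
#> <maxent_error_report>
#> Window averages:
#> # A tibble: 2 × 5
#>   phase       n_years mean_rmse mean_rel_err_pct max_rel_err_pct
#>   <chr>         <int>     <dbl>            <dbl>           <dbl>
#> 1 calibration      10  0.000877             2.51            4.31
#> 2 forecast          5  0.00180              5.39            6.10
#> Worst units by mean relative error: TU14 (24.0%), TU24 (20.0%), TU06 (14.4%)
```

Reading the numbers: within the calibration window the integrated
model (three flows plus ten moments of the previous year's shares)
reproduces the yearly distribution with a mean relative error of about
2.5% across units and an RMSE on the shares below 0.001; extrapolating
the restrictions five years ahead roughly doubles the error, and the
per-unit profile shows the error concentrating in the small units at
the tail of the ordering — the characteristic behaviour of this model
family. `autoplot(cal)`, `plot_shares(fc)` and `plot_error_profile(cal)`
draw the corresponding figures, and `tidy()`/`glance()` return the
tables above for further wrangling.

A thin command-line interface over the same functions lives at
`inst/cli/maxentpop.R` (subcommands `simulate`, `solve`, `calibrate`,
`forecast`, `report`, driven by a YAML config); see `?run_cli`.

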