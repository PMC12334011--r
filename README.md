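# crimedyn

A dynamical-systems toolkit for studying criminal involvement, arrest,
desistance and rehabilitation from longitudinal panel data.

Criminal careers are shaped by interacting transitions — onset, first
arrest, recidivism, desistance, rehabilitation — whose long-run
consequences cannot be read off any single rate in isolation. `crimedyn`
is for quantitative criminologists, epidemiologists of delinquency, and
policy analysts who want to move from wave-to-wave panel observations
(binary *offended* / *arrested* flags) to system-level statements: what is
the long-run ("equilibrium") share of the population outside crime, which
transition rates is it most sensitive to, and which rate gaps between
demographic groups generate the gap in long-run outcomes.

## The model

Five mutually exclusive states, assigned per person-year:

| state | meaning |
|-------|---------|
| X  | inactive, no recent arrest history (incl. rehabilitated: 3+ inactive years after arrest) |
| C1 | offending, never arrested |
| A  | arrested within the last year |
| R  | inactive, but active/arrested within the last 3 years |
| C2 | offending, previously arrested |

Eleven free per-year probabilities (αx1: X→C1, αxa: X→A, β1x: C1→X,
γ1a: C1→A, ζa2: A→C2, βar: A→R, γ2a: C2→A, β2r: C2→R, αr2: R→C2,
αra: R→A, εrx: R→X) plus derived stay probabilities form a row-stochastic
matrix **M**; population fractions evolve as x(t+1) = x(t) M. The
equilibrium share in X has the closed form

    X* = εrx (β1x + γ1a) (γ2a βar + β2r (βar + ζa2)) / D

(`equilibrium_closed_form()`), verified against an independent
stationary-distribution solve (`equilibrium_solve()`). On top of this sit
partial derivatives and elasticities of X* in every rate
(`sensitivity_report()`, `sweep_x_star()`), and a two-group disparity
decomposition by one-at-a-time counterfactual substitution
(`disparity_report()`). Transition rates are estimated from panels either
by direct counts (`empirical_matrix()`) or by per-arrow random-intercept
logistic regression with adaptive Gauss–Hermite quadrature (`ri_logit()`,
`fit_transition_logit()`), and a seeded synthetic panel generator
(`generate_panel()`) makes the whole pipeline testable end to end with no
external data.

## Worked example

Packaged fixtures carry the printed transition rates for two groups of
men and their initial state distributions:

```r
library(crimedyn)
bm <- load_params(crimedyn_fixture("table5_black_men.json"))
init <- load_state(crimedyn_fixture("table4_initial_black_men.json"))

equilibrium_closed_form(bm)
#> long-run equilibrium (closed-form)
#> state distribution (t = 0): X=0.6415 C1=0.0599 A=0.0953 R=0.1524 C2=0.0509
#> X* = 0.6415   crime rate 1 - X* = 0.3585
```

So at these rates, 64.15% of the group ends up criminally inactive in the
long run; iterating the system reproduces the approach to that value
(64.2% is reached within ~50 annual steps from the 79.4% initial share).

Which rates matter? Equalizing each Black–White rate difference one at a
time and recomputing both equilibria:

```r
wm <- load_params(crimedyn_fixture("table5_white_men.json"))
dr <- disparity_report(bm, wm)
head(as.data.frame(dr)[order(-dr$pct_reduction_equalize),
                       c("arrow", "abs_diff", "pct_reduction_equalize")], 3)
#>    arrow abs_diff pct_reduction_equalize
#> 2   X->A    0.020              77.655316
#> 11  R->X   -0.025              14.590730
#> 1  X->C1    0.005               5.886983
```

Closing the early-arrest gap X→A (2 percentage points) removes ~78% of the
9.4-point equilibrium gap — dwarfing every other substitution, including
the *largest* rate gap (C2→A, 7.5 points), which removes essentially
nothing. Sensitivities tell the same story locally:

```r
r <- sensitivity_report(bm)
r[r$arrow %in% c("X->A", "C1->A", "C2->A", "R->X"),
  c("arrow", "partial", "elasticity", "sign_prediction")]
#>    arrow     partial  elasticity                         sign_prediction
#> 2   X->A -3.26518105 -0.23864432                                negative
#> 4  C1->A -0.20274222 -0.03942243                             conditional
#> 7  C2->A  0.00611147  0.00262119 conditional (sign of beta_ar - beta_2r)
#> 11  R->X  0.58918039  0.22510442                                positive
```

First arrests of the never-arrested *increase* long-run crime
(∂X\*/∂γ1a < 0) while re-arrests of recidivists are negligible — the
system-level asymmetry the model exists to expose.

A command-line veneer covers the same pipeline
(`assign`, `estimate`, `simulate`, `equilibrium`, `sensitivity`,
`disparity`, `synth`, `run`), e.g.:

```sh
Rscript -e 'crimedyn::crimedyn_cli()' equilibrium \
  --params inst/extdata/table5_black_men.json --out eq.csv
```

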