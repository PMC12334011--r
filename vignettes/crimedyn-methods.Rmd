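---
title: "Methods: a five-state dynamical system of criminal involvement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-state dynamical system of criminal involvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crimedyn)
```

## The model

`crimedyn` implements a linear, discrete-time compartmental model of
criminal involvement over five mutually exclusive states, defined from two
annually observed binary flags — *offended in the last year* and *arrested
in the last year* — plus their history:

* **X** — criminally inactive with no recent arrest history: either never
  arrested and not offending this year, or previously arrested but inactive
  for three consecutive years ("rehabilitated");
* **C1** — offending, never arrested;
* **A** — arrested within the last year (regardless of offending);
* **R** — previously arrested, active within the last three years, but
  neither offending nor arrested this year;
* **C2** — offending, with an arrest history but no arrest this year.

Eleven free per-year transition probabilities connect these states (onset
`alpha_x1`, `alpha_xa`; desistance `beta_1x`, `beta_ar`, `beta_2r`; arrest
`gamma_1a`, `gamma_2a`; post-arrest continuation `zeta_a2`; recidivism
`alpha_r2`, `alpha_ra`; rehabilitation `epsilon_rx`). Each source state's
*stay* probability is the complement of its outflows — stays are derived,
never free, so the 5×5 matrix built by `make_matrix()` is row-stochastic by
construction, with structural zeros where a move is impossible by
definition (e.g. X cannot reach C2 in one step, because C2 requires a prior
arrest).

Population fractions evolve by left-multiplication with this matrix
(`step_state()`, `simulate_chain()`). Because rows sum to one, total mass
is conserved exactly; for interior parameters the chain is irreducible and
aperiodic, so it converges to a unique stationary distribution from any
starting point.

### Equilibrium, two routes

`equilibrium_closed_form()` evaluates the analytic expression

$$X^* = \frac{\epsilon_{rx}(\beta_{1x}+\gamma_{1a})
  \left(\gamma_{2a}\beta_{ar}+\beta_{2r}(\beta_{ar}+\zeta_{a2})\right)}{D},$$

with $D$ a sum of degree-4 parameter products, and recovers the remaining
components from the per-state balance relations. `equilibrium_solve()` is
the independent route: the left null space of $M^\top - I$ with a
sum-to-one constraint. The two agree to machine precision over thousands of
random interior draws (the test suite asserts $10^{-10}$ over 1,000), which
is what justifies two editorial reconstructions we had to make in the
printed formulas:

1. two symbols in the printed $D$ (`alpha_x2`, `beta_2x`) are undefined in
   the model and are read as `alpha_r2` and `beta_2r`;
2. the displayed pre-simplification system omits the `gamma_2a`·C2 inflow
   into A and the C2 line entirely; both are restored from the flow diagram.

Degenerate parameterizations (no effective flow out of the crime states,
$D = 0$) raise an explicit error; reducible chains from boundary parameters
are flagged as non-unique and the limit from a strictly positive start is
returned.

### Sensitivity and elasticity

All perturbation analyses use one convention: a change to one free rate is
absorbed entirely by the same source state's stay probability; the other
ten rates are untouched. `partial_x_star()` differentiates $X^*$ by central
differences (step $10^{-6}$) on the closed form; for the two arrest rates,
whose sign is the theoretically interesting case, the exact quotient-rule
expressions are also implemented (`method = "analytic"`) and agree with the
numeric route to $10^{-6}$ relative. The sign structure is a property of
the algebra, tested on hundreds of random draws: entry/re-entry rates
(`alpha`s) lower $X^*$; desistance and rehabilitation rates raise it;
re-arrest `gamma_2a` helps exactly when post-arrest desistance exceeds
pre-arrest-state desistance (`beta_ar > beta_2r`); first-arrest `gamma_1a`
is harmful at both printed parameter sets. First and second derivatives are
opposite in sign wherever the first is non-negligible (diminishing
returns).

Elasticity (`elasticity_x_star()`) is deliberately the *forward 1%
multiplicative perturbation*, not the infinitesimal limit — percent change
in $X^*$ per one percent relative change in the rate — and the
percentage-point analog (`point_change_x_star()`) uses +0.01 additively.
Large-change sweeps (`sweep_x_star()`) cover $[0, \text{upper}]$ where
upper is the largest value keeping the source stay probability nonnegative.

### Disparity decomposition

`gap_table()`, `equalize_one()` and `gap_reduction_elasticity()` quantify
how per-parameter differences between two groups translate into the gap in
equilibrium $X^*$, by one-at-a-time counterfactual substitution (set group
A's rate to group B's value, or move it a fraction of the way) and
recomputation of both equilibria. Percent reductions are defined on the
absolute $X^*$ gap; the complementary crime-rate gap is identical in
magnitude. Relative differences default to (A − B)/B with the reversed
quotient available — the source material states both conventions in
different places, and printed relative values are reproducible only from
unrounded inputs, so neither is asserted numerically.

On the packaged printed inputs the decomposition's qualitative findings are
reproduced by the tests: equalizing the early-arrest rate X→A removes
roughly three quarters of the equilibrium gap (far ahead of rehabilitation
R→X, the runner-up at ~15%), and the re-arrest rate C2→A — despite having
the largest absolute gap — contributes essentially nothing. One
quantitative claim in the source prose (a 1% reduction of the X→A gap
reducing the equilibrium gap "by 2%") is not reproducible from the rounded
printed inputs: this procedure gives ~0.70%, and reading it as a 1%
reduction of the parameter itself gives ~1.6%. The tests assert only the
ranking. Similarly, the prose's "equilibrium at 55%" for Black men
conflicts with the printed 0.642 equilibrium table; the table is what the
package reproduces.

## State assignment and estimation

`assign_states()` turns a person-wave panel of the two flags into states by
a fixed precedence: arrest this year → A; never arrested: offending → C1
else X; ever arrested: offending → C2, otherwise R until the third
consecutive inactive year, then X. Where a full 3-year window does not yet
exist (early waves), available history is used — the only policy requiring
no imputation; person-waves with missing flags are dropped and counted,
never imputed. The rare inconsistency of self-reported offending after 3+
inactive post-arrest years re-enters C2 and is tallied in the diagnostics.

`build_transitions()` pairs consecutive waves (gaps skipped listwise) and
rejects, with a count, observed pairs off the admissible 16-arrow set —
possible for real data (and for the generator's rehabilitated re-offenders,
see below). `empirical_matrix()` estimates rates by direct counts, refusing
equilibrium computation when an origin row is empty.

`ri_logit()` fits the per-arrow transition regression: a logit on quadratic
age (centered at 16), woman/Black/Hispanic dummies and sex-by-race
interactions (White men the reference), with a person-level
Normal(0, σ_u²) random intercept capturing time-invariant heterogeneity in
offending propensity, so the transition estimates are "net of" population
heterogeneity. The marginal likelihood is maximized with *adaptive*
Gauss–Hermite quadrature (21 nodes by default; 21 vs 41 nodes agree in
log-likelihood to $10^{-6}$ in the tests), with analytic scores via the
Fisher identity and standard errors from the numerically differentiated
score. We wrote this fitter directly rather than calling a mixed-model
package because the acceptance-scale recovery study (50 replicate fits at
5,000 persons × 6 pairs) needs ~8 s per fit; `lme4::glmer` at the same
quadrature order takes ~145 s per fit. lme4 remains in the test suite as
the independent oracle on a smaller fixture — coefficients, σ_u, standard
errors and log-likelihood all agree well below one standard error. With
σ_u constrained to zero (or unidentifiable, e.g. one observation per
person) the fit reduces exactly to ordinary logistic regression, with a
warning in the unidentified case.

Subgroup summaries (`subgroup_table()`) average predicted probabilities
over each sex-by-race cell's observed age distribution. Whether the
original analysis marginalized over the random intercept or set u = 0 is
not stated; both are exposed, and the *population-averaged* (integrated)
version is the default, since the quantities feed a population-level
compartmental model. Intervals come from a parametric bootstrap of the
coefficient sampling distribution (1,000 draws by default; delta method as
the fast option). Stay probabilities are derived by complement, so each
origin's destination probabilities sum to one exactly.

## The synthetic panel generator

`generate_panel()` emulates the panel structure the analysis assumes —
about 6,459 persons, 7 annual waves, 51% men, 26/51.9/21.2% Black/White/
Hispanic, baseline ages uniform on 12–17 (the observed cohort mean is
14.9; the uniform integer approximation has mean 14.5), initial state
distribution from the packaged round-1 table — under two modes, because no
single generator can both treat the rehabilitation rate `epsilon_rx` as a
free parameter and keep state assignment exactly invertible:

* **markov** — the latent process is exactly the parameterized five-state
  chain. This tests the model half: empirical rates converge to the
  generating matrix (asserted at n = 50,000 within 3 binomial SEs per
  arrow). An optional person-level random intercept tilts the logits of
  the crime-ward destinations (C1, A, C2) with a shared loading before
  renormalization, mirroring a fixed propensity to offend.
* **history** — the R→X move is *not* drawn: rehabilitation happens
  deterministically when the inactive streak reaches three years, so
  `epsilon_rx` becomes emergent, and onset from rehabilitated X re-enters
  C2 (prior arrest) rather than C1. With this bookkeeping,
  `assign_states()` applied to the observables reproduces the latent
  sequence for 100% of person-waves — the round-trip acceptance criterion.
  Initial states are restricted to X, C1, A (renormalized), since R or C2
  at wave 1 would presuppose history the assignment cannot see. A
  consequence faithful to the source data's "<0.5%" inconsistency: a
  rehabilitated person who re-offends produces an X→C2 pair off the
  admissible arrow set, which `build_transitions()` rejects and counts.

The emergent per-entrant rehabilitation probability has the closed form
$(1-\alpha_{r2}-\alpha_{ra})^2$ — surviving the two further annual draws
needed to complete the three-year window — and is checked against the
simulated completion frequency of the R-entrant cohort.

Observables are `arrested = (state == A)` and `offended = 1` for C1/C2,
Bernoulli(0.7) for A (arrestees do not always self-report offending), 0
for X/R. Identical seeds give bit-identical panels; the caller's RNG state
is restored.

What a green test does **not** establish: the generator has no attrition,
no survey weights, no time-varying rates, no contagion between persons,
and its age effects default to zero — so recovery tests validate the
estimators under the model's own assumptions, not robustness to the ways
real panel data violate them.

## Numerical choices

* Iterative equilibrium: L1 per-step change < $10^{-12}$ or 300 steps,
  whichever first (the printed convergence protocol).
* Finite differences: $10^{-6}$ central for first derivatives, $10^{-4}$
  for second differences (order-1 quantities; balances truncation and
  round-off).
* Optimizer: L-BFGS-B on (β, σ_u) with σ_u ∈ [10⁻⁴, 25]; a boundary σ_u
  estimate is reported as ~0.
* State vectors renormalize on construction (printed initial columns sum
  to 1.001); published full matrices renormalize rows with a warning only
  when the raw sum deviates from 1 by more than 0.02.
* Ties/degeneracies: zero reference values give `NA` relative differences
  (never infinities); boundary parameters refuse derivatives rather than
  silently one-siding.

## Known limitations

Printed regression coefficient tables and subgroup prediction curves from
the original survey data are not reproducible without the microdata; they
are covered by property-based recovery tests on synthetic panels instead.
The closed-form equilibrium is specific to this 16-arrow topology; changing
the state graph requires re-deriving it (the stationary solve generalizes).
The CLI is a thin veneer over the R API and does not render figures — sweep
and sensitivity outputs are CSVs intended for external plotting.
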