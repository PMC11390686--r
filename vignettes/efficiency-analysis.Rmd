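---
title: "Two-stage efficiency analysis of DMU panels: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage efficiency analysis of DMU panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deapanel)
```

# The problem

Health-system panels — hospital groups, districts, community health
centers (CHCs) — are small: ten to twenty units, a handful of years,
two to five input and output quantities each. The questions asked of
them are standard: which units convert staff, beds, floor area and
equipment into visits and services efficiently; whether productivity is
rising; and which environmental factors explain the differences. This
vignette documents how `deapanel` answers each, which conventions it
fixes where the applied literature is silent, and what its validation
does and does not establish.

# Stage one: cross-sectional efficiency

## Radial models

`radial_efficiency()` solves the envelopment-form CCR (constant returns
to scale) and BCC (variable returns) programs. Input orientation
minimises the contraction $\theta$ subject to
$X\lambda \le \theta x_k$, $Y\lambda \ge y_k$; output orientation
maximises the expansion $\varphi$ and reports $1/\varphi$, so all
scores share the $(0, 1]$ scale. BCC adds $\sum_j \lambda_j = 1$. A
second-phase solve maximises the slack sum at the fixed radial factor
so reported slacks are max-slack projections; slacks are normalised by
the evaluated unit's own levels in that objective, which keeps the
phase-2 solution invariant to measurement units (a raw slack sum would
depend on whether beds are counted in beds or bed-days). Ties among
alternate phase-2 optima are not resolved further.

`multiplier_oracle()` solves the dual (multiplier) program
independently. It exists for verification: by LP duality its optimum
must match the envelopment score, and the test suite holds the gap
below $10^{-6}$ across random instances.

## SBM and super-efficiency

The non-oriented slack-based measure is the fractional program

$$\min\ \rho = \frac{1 - \tfrac1m \sum_i s^-_i / x_{ik}}
                    {1 + \tfrac1q \sum_r s^+_r / y_{rk}}
\quad \text{s.t.}\quad x_k = X\lambda + s^-,\ y_k = Y\lambda - s^+ .$$

It is linearised exactly by the Charnes–Cooper transformation: a scale
variable $t$ with $t \cdot (\text{denominator}) = 1$, all $\lambda$ and
slacks multiplied by $t$, and a back-transform before reporting. The
same device linearises the super-efficiency program, which excludes the
evaluated unit from the reference set and minimises the ratio of the
(input-inflated, output-deflated) reference bundle to the unit's own
bundle; its optimum is $\ge 1$.

Two conventions follow the common practice of applied efficiency
studies:

* **SE-SBM on inefficient units.** If a unit's SBM score is below
  $1 - \tau$, `super_sbm_efficiency()` returns the SBM result
  unchanged, so a scored cross-section mixes super-efficiency values
  above 1 with ordinary SBM values below 1 — the layout of published
  score tables.
* **Default configuration: non-oriented, CRS.** Neither choice is
  forced by the mathematics; non-oriented SBM is the form in which the
  model family is usually quoted, and CRS keeps the stage-one scores on
  the same returns-to-scale assumption as the Malmquist core. Both are
  `dea_config()` flags.

The efficiency threshold is $\tau = 10^{-6}$: a unit is *efficient*
when its score is at least $1 - \tau$. Report tables round to 3
decimals — the print convention of the field — while internal objects
keep full precision.

## The LP engine

All programs are solved by the package's dense two-phase primal
simplex (`solve_lp()`). These LPs are small (tens of variables and
constraints) and are solved thousands of times per study, so a dense
tableau with Dantzig pricing, switching to Bland's rule under prolonged
degeneracy, is both fast (milliseconds per solve) and deterministic.
Phase one uses a full artificial basis and declares infeasibility when
the residual infeasibility exceeds $10^{-7}$ relative to the data
scale; redundant rows are dropped when artificials cannot be pivoted
out. The engine was validated during development against an
independent interior-point/simplex implementation on randomly generated
programs spanning optimal, infeasible and unbounded cases, and is
continuously cross-checked in the test suite through LP duality, the
analytic worked examples, and a brute-force grid oracle.

Infeasibility is *surfaced, never patched*: a VRS super-efficiency
program with no convex reference excluding the unit returns
`status = "infeasible"` with an `NA` score rather than a large
placeholder value. A single-unit cross-section scores 1 with a warning.

# Stage one, over time: the Malmquist index

`malmquist_pair()` builds the index between adjacent periods $t$ and
$t+1$ from six Farrell distances (four CRS, two within-period VRS):

$$\text{EFFCH} = \frac{D^{t+1}(t+1)}{D^{t}(t)}, \qquad
\text{TECHCH} = \sqrt{\frac{D^{t}(t+1)}{D^{t+1}(t+1)} \cdot
                      \frac{D^{t}(t)}{D^{t+1}(t)}},$$

with $\text{TFPCH} = \text{EFFCH} \times \text{TECHCH}$,
$\text{PECH} = D^{t+1}_{vrs}(t+1) / D^{t}_{vrs}(t)$ and
$\text{SECH} = \text{EFFCH} / \text{PECH}$. The identities are computed,
not fitted, and hold to $10^{-9}$ relative error by construction; the
test suite asserts them anyway as a guard against regression.

Fixed conventions, each a deliberate choice where practice varies:

* **Distances are radial, output-oriented, CRS** — the convention of
  the DEAP-style software family that dominates the applied
  literature. The evaluated unit *is* included in its own reference
  technology (super-efficiency exclusion applies only to SE-SBM).
* **PECH from within-period VRS distances only**, with SECH derived as
  a ratio. Cross-period VRS distances — the ones that can genuinely be
  infeasible — are never required.
* **Adjacent pairs only**, no chaining across non-adjacent periods.
* **Arithmetic aggregation by default.** Published per-unit tables in
  this field are arithmetic means over period pairs — visible because
  printed row products (EFFCH × TECHCH) do not reproduce printed TFPCH
  on some rows, which only arithmetic averaging explains. The
  geometric mean (under which the index-reversal property holds
  exactly) is available via `method = "geometric"` and is what the
  property tests use.

`index_summary()` reproduces the printed-table layout: a trailing
row-mean column and a final column-mean row. Applied to the bundled
published tables (`luohu_chc_mpi()`, `shenzhen_region_mpi()`) it
recovers the published means exactly at print precision, which pins
down the aggregation convention.

# Stage two: the Tobit determinants regression

`fit_tobit()` maximises the two-limit censored-normal log-likelihood
over $(\beta, \log\sigma)$ — the log parameterisation keeps
$\sigma > 0$ without constraints — by BFGS from the least-squares
start, followed by Newton polishing with the observed information
until the gradient norm falls below $10^{-8}$ (relative to the
log-likelihood scale). Standard errors come from the inverse observed
information, with the $\sigma$ row delta-transformed from the log
scale; p-values are asymptotic-normal z tests, matching the stars in
standard software output.

Default bounds are $L = 0$, $U = +\infty$. Efficiency scores are
bounded below, and super-efficiency scores exceed 1, so censoring at 1
would discard genuine variation in exactly the units the second stage
is most interested in. Both bounds are arguments. Estimation is pooled
over (dmu, period) rows — small panels give no purchase on random
effects — with an optional cluster-robust (on DMU) sandwich
correction. The dependent variable is each unit's *yearly* score
joined to that year's covariates; a study preferring period means can
aggregate before calling.

The likelihood code is cross-checked in the tests against
`survival::survreg`'s censored-gaussian fit (coefficients, scale,
log-likelihood and standard errors agree to at least five decimals),
and its inference is calibrated by simulation: the z-test's type-I
error over 500 null replicates at $n = 100$ stays within [0.03, 0.07].

# Synthetic data: what it emulates and what it does not

Real microdata behind published district studies are rarely released;
the generators make the pipeline testable anyway, in two complementary
ways.

**Frontier panels with known truth** (`generate_frontier_panel()`).
Inputs are log-normal; the frontier output level is Cobb–Douglas,
$A_0 (1+g)^{t-1} \prod_i x_i^{\alpha_i}$ with $\sum \alpha_i = 1$ (CRS)
by default; total output is split across the $q$ outputs by per-unit
share vectors that sum to one (a Dirichlet draw around a common mean);
and realised outputs are scaled by $e^{-u}$ with half-normal
$u \sim |N(0, \sigma_u)|$, drawn once per unit (persistent) or per
period. Because shares sum to one, every zero-inefficiency unit is
radially CCR-efficient — convex combinations of on-frontier peers
cannot dominate an on-frontier point under a concave CRS technology —
which gives the solvers a sharp truth to hit. Known $g$ gives the
Malmquist stage its truth: with persistent inefficiency the
geometric-mean TECHCH recovers $1 + g$ up to sampling noise (the tests
plant $g = 0.05$ at $n = 50$ and require [1.03, 1.07]).

**Calibrated fixtures** (`generate_luohu_fixture()`). The CHC fixture
is a 20-unit × 7-year panel (4 inputs, 5 outputs) whose *every* column
total equals the corresponding published yearly aggregate exactly.
Totals are apportioned by stable random shares — a per-unit size
weight drawn once, times a small per-cell Gamma jitter — and integer
cells are reconciled by largest-remainder rounding, preserving totals
exactly while keeping every cell at least 1. The regional fixture
(10 units × 7 years, 2 inputs, 2 outputs) uses 8× the published
group-level totals, because district-level totals are not published:
it is shape-compatible, not value-calibrated, and is documented as
such. The default seed is a fixed documented constant so fixtures are
byte-stable. One quirk is reproduced deliberately: the published 2021
health-education total is an order of magnitude above every earlier
year (a suspected unit change in the source); the fixture calibrates
to it as printed and flags it in the calibration notes, and it is why
fixture TECHCH jumps in the final pair.

What passing tests on these fixtures shows: the solvers, index
decomposition, aggregation and regression behave correctly on data
with exactly the study's shape and aggregate scale. What it does not
show: per-unit published scores are reproduced — those depend on
microdata that are not public, and any within-column allocation
consistent with the totals would give different per-unit scores.

# Numerical choices and degenerate inputs

* LP tolerances: pivot tolerance $10^{-9}$, feasibility $10^{-7}$
  (relative); efficiency threshold $\tau = 10^{-6}$.
* Zero cells: DEA requires strictly positive data, so
  `validate_panel()` errors by default; with
  `epsilon_substitute = TRUE` zeros become $10^{-6} \times$ the
  column maximum, each substitution listed in the validation report.
  Silent fixes hide data errors; the default is deliberate.
* The $n > 2(m+q)$ discrimination rule of thumb is reported as a
  warning, never an error.
* Periods sort lexicographically unless an explicit order is given;
  year labels make lexical and chronological order coincide.
* Thousands separators are tolerated on CSV load because published
  tables print them.

# Problem sizes used in validation

The bundled suite runs at deliberately modest scale — random
cross-sections up to $n = 15$, $m, q \le 3$; Malmquist panels up to 50
units × 7 periods; Tobit recovery at $n = 5000$ and 500 null
replicates at $n = 100$ — chosen so the full suite completes in well
under a minute while still exercising every code path at the shape of
real studies. The acceptance script re-runs the same computations from
scratch in a few seconds.

# Known limitations

* No inference on DEA scores (no Simar–Wilson bootstrap); score
  differences near the frontier should not be over-interpreted.
* Alternate-optima slack profiles are only pinned down up to the
  max-slack phase; reference weights $\lambda$ are not unique.
* No panel-structure Tobit (random effects); clustering is the only
  concession to dependence.
* Malmquist variants beyond the adjacent-period CRS core (global,
  biennial, Hicks–Moorsteen, SBM-based) are out of scope.
* The calibrated fixtures match published aggregates, not published
  per-unit scores; they validate machinery, not history.
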