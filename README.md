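# deapanel

Two-stage efficiency analysis for balanced panels of decision-making
units (DMUs), in the style used throughout health-services research:
hospital groups, administrative regions, or community health centers
(CHCs) observed yearly with a handful of input and output quantities.

The package answers three questions about such a panel:

1. **How efficient is each unit each year?** Cross-sectional data
   envelopment analysis (DEA): radial CCR/BCC scores, the slack-based
   measure (SBM), and the super-efficiency SBM (SE-SBM), which ranks
   efficient units by letting their scores exceed 1.
2. **How is productivity changing over time?** The adjacent-period
   Malmquist index, fully decomposed as
   `TFPCH = EFFCH × TECHCH = PECH × SECH × TECHCH`.
3. **What explains the differences?** A second-stage censored-normal
   (Tobit) maximum-likelihood regression of the scores on environmental
   covariates.

All DEA models are solved as linear programs by a built-in two-phase
simplex; fractional programs (SBM, SE-SBM) are linearised exactly with
the Charnes–Cooper transformation.

## The models

For DMU *k* with inputs `x_k` (length *m*) and outputs `y_k` (length
*q*) evaluated against peers `(X, Y)`, the non-oriented SBM score is

```
min ρ = [1 − (1/m) Σᵢ s⁻ᵢ/x_ik] / [1 + (1/q) Σᵣ s⁺ᵣ/y_rk]
s.t.   x_k = Xλ + s⁻,   y_k = Yλ − s⁺,   λ, s⁻, s⁺ ≥ 0
```

with ρ ∈ (0, 1] and ρ = 1 exactly when all slacks vanish. For
SBM-efficient units the super-efficiency program removes unit *k* from
the reference set and minimises

```
ρ = [(1/m) Σᵢ x̄ᵢ/x_ik] / [(1/q) Σᵣ ȳᵣ/y_rk]
s.t. x̄ ≥ Σ_{j≠k} λⱼ xⱼ,  ȳ ≤ Σ_{j≠k} λⱼ yⱼ,  x̄ ≥ x_k,  0 < ȳ ≤ y_k
```

whose optimum is ≥ 1. The Malmquist index between adjacent periods is
built from output-oriented CRS Farrell distances, with the VRS
within-period distances supplying the PECH/SECH split.

Because the per-unit microdata behind published district studies are
typically not released, the package ships **calibrated synthetic
fixtures**: panels whose yearly column totals exactly match published
aggregates for the Luohu Hospital Group case (20 CHCs × 7 years,
4 inputs, 5 outputs; and a 10-region × 7-year shape), plus Cobb–Douglas
frontier generators with known inefficiency draws so every solver can
be checked against ground truth.

## Worked example

```r
library(deapanel)

panel <- generate_luohu_fixture("chc")     # calibrated 20-CHC fixture
cs <- cross_section(panel, "2021")
score_cross_section(cs, dea_config("sesbm"))
#> dea_scores (SESBM): 20 DMUs, mean 0.851, 7 efficient
#>    dmu     score efficient  status
#> 1   C1 0.7153269     FALSE optimal
#> 2   C2 1.2231540      TRUE optimal
#> 3   C3 0.8048608     FALSE optimal
#> ...
```

Scores above 1 (e.g. C2's 1.223) are super-efficiency values: C2 would
remain efficient even after tightening its inputs/outputs by that
margin relative to the frontier spanned by the other 19 centers.
Scores below 1 are ordinary SBM efficiencies.

The full two-stage study:

```r
report <- run_pipeline(panel)
report
#> study_report
#>   model: SESBM/CRS/non, aggregation arithmetic
#>   yearly mean scores:
#>   period mean_score n_efficient
#> 1   2015      0.978          15
#> 2   2016      1.008          15
#> ...
#>   mean-score growth 2015-2021: -12.95%
#>   Malmquist means (per DMU, trailing Mean row):
#>     dmu effch techch  pech  sech tfpch
#> 21 Mean 0.993  1.266 0.999 0.994 1.249
```

The yearly table gives the mean super-efficiency and the count of
DEA-efficient units per year; the trailing Malmquist row is the
cross-unit mean of each index (TFPCH > 1 means productivity growth,
decomposable into catch-up EFFCH and frontier-shift TECHCH). Note the
fixture's large TECHCH is driven by the published 2021 surge in the
health-education output total, which the calibration reproduces as
printed. Supplying a covariate table (`dmu`, `period`, covariates)
turns on the Tobit stage:

```r
report <- run_pipeline(panel, covariates = "covariates.csv")
tobit_report(report$tobit)
```

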