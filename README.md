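# mrsummary

Mendelian randomization (MR) uses genetic variants as instrumental variables
to assess whether an exposure causally affects an outcome. Because variants
are fixed at conception and assort independently of environmental
confounders, a variant that (i) associates with the exposure, (ii) shares no
confounding pathway with the outcome, and (iii) affects the outcome only
through the exposure behaves like a randomized treatment assignment.
`mrsummary` implements MR estimation from *summarized* data — per-variant
beta coefficients and standard errors from genome-wide association studies —
for epidemiologists and statistical geneticists who work from published
summary statistics rather than individual-level data.

## What the package computes

For variant *j*, let `bx_j` (SE `bxse_j`) be its association with the
exposure and `by_j` (SE `byse_j`) its association with the outcome, in a
two-sample design. All estimators target the causal effect θ in the model
`by_j = θ γ_j + α_j + error`, where `γ_j` is the true variant–exposure effect
and `α_j` is horizontal pleiotropy (zero for valid instruments).

* **IVW** (`mr_ivw`, `mr_mvivw`): weighted regression of `by` on `bx` through
  the origin with weights `1/byse²`; with a variant correlation (LD) matrix
  ρ, generalized weights from `Ω = (byse ⊗ byse) ∘ ρ`.
* **Instrument strength** (`f_statistic`, `conditional_f_statistics`): the
  first-stage F statistic `F = (1/J) Σ (bx_j/bxse_j)²`, Cholesky-decorrelated
  for correlated variants; per-exposure conditional F statistics for
  multivariable models (computed when exposure sample sizes are supplied).
* **Weak-instrument-robust IVW** (`mr_divw`, `mr_pivw`): the debiased IVW
  estimator `θ̂ = Σ(bx by/byse²) / Σ((bx²−bxse²)/byse²)` and its penalized
  extension with denominator bounded away from zero, optional weak-instrument
  screening, overdispersion, and bootstrap Fieller inference.
* **Continuously-updating GMM** (`mr_gmm`, `mr_mvgmm`): minimizes
  `g(θ)'Ω(θ)⁻¹g(θ)` with moments `g_j(θ) = by_j − bx_j'θ`; robust to weak
  instruments and exposure measurement error; overdispersion calibrated to
  the chi-square degrees of freedom.
* **Principal-component GMM** (`mr_pcgmm`, `mr_mvpcgmm`): for dense,
  highly-correlated variants from a single gene region, projects the summary
  statistics onto the leading eigenvectors of a weighted LD matrix
  (components explaining 99.9% of its variability by default) and runs
  CUE-GMM in component space.
* **Constrained maximum likelihood** (`mr_cml`, `mr_mvcml`): Gaussian
  likelihood maximized with exactly K invalid (pleiotropic) instruments, K
  selected by BIC, with model averaging and data perturbation.
* **Correlation-matrix hygiene** (`flip_correlation`, `prune_by_r2`,
  `validate_correlation`): harmonization of signed LD matrices to effect
  alleles, seeded random pruning of pairs with r² above a threshold, and
  detection of unsigned/r²-style matrices.
* **Synthetic data** (`simulate_univariable`, `simulate_multivariable`):
  seeded two-sample generators with known truth for calibration and testing.

## Worked example

The package ships a six-variant dataset from the *CASR* gene region:
associations with serum calcium (exposure, n = 6351) and fasting glucose
(outcome, n = 133010), plus the variants' signed 6×6 LD correlation matrix.

```r
library(mrsummary)
fx <- casr_fixtures()

# correlated-variant IVW
mr_ivw(fx$dataset)
#> Inverse-variance weighted (random-effects, correlated variants) (J = 6 variants)
#> Estimate 2.244  Std Error 0.642  95% CI 0.986, 3.502  p-value 0.000
#> F statistic = 11.6

# principal-component GMM using the same correlation matrix
mr_pcgmm(fx$dataset, nx = fx$nx, ny = fx$ny)
#> Principal-component GMM (J = 6 variants)
#> Estimate 2.302  Std Error 0.699  95% CI 0.932, 3.672  p-value 0.001
#> F statistic = 11.6
```

Both analyses indicate that higher serum calcium raises fasting glucose
(about 2.2–2.3 mmol/L glucose per mmol/L calcium, p < 0.01). The F statistic
of 11.6 says the six correlated variants are jointly strong enough that
weak-instrument bias should be modest; the PC-GMM run retains r = 6
components (its default keeps components explaining 99.9% of the weighted LD
matrix's variability, and at J = 6 nothing is discarded).

If the LD matrix had been computed with different effect alleles than the
summary statistics, it must be re-oriented first:

```r
harmonized <- flip_correlation(fx$rho, flip = c(+1, +1, -1, +1, -1, +1))
harmonized[1, 3]   # -0.094 (sign flipped once)
harmonized[3, 5]   #  0.349 (flipped twice: unchanged)
```

A command-line interface with the same functionality is installed at
`system.file("cli", "mrsummary.R", package = "mrsummary")`, e.g.
`Rscript mrsummary.R ivw --input assoc.csv --corr rho.csv --format table`.

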