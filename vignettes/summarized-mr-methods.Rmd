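---
title: "Models and methods for summarized-data Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for summarized-data Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsummary)
```

# The two-sample summary-data model

All estimators in `mrsummary` work from per-variant summary statistics: for
variant $j = 1, \dots, J$, a beta coefficient $\hat\beta_{Xj}$ with standard
error $\sigma_{Xj}$ from a regression of the exposure on the variant, and
$\hat\beta_{Yj}$, $\sigma_{Yj}$ from a regression of the outcome on the same
variant, oriented to the same effect allele. The working model is

$$\hat\beta_{Xj} \sim N(\gamma_j,\ \sigma_{Xj}^2), \qquad
  \hat\beta_{Yj} \sim N(\theta\,\gamma_j + \alpha_j,\ \sigma_{Yj}^2),$$

with $\gamma_j$ the true variant–exposure effect, $\theta$ the causal effect
of interest, and $\alpha_j$ a horizontal-pleiotropy term that is zero for a
valid instrument. Exposure and outcome associations are assumed estimated in
non-overlapping samples (two-sample design), so their errors are
independent. Linkage disequilibrium (LD) makes the errors of nearby variants
correlated across $j$ with a known signed correlation matrix $\rho$; when no
matrix is supplied, variants are treated as uncorrelated. In the
multivariable extension $\gamma_j$ is a $K$-vector, $\theta$ a $K$-vector,
and a separate $K \times K$ *exposure correlation matrix* describes
correlations between the exposure association estimates that arise when they
come from overlapping samples (identity by default, i.e. non-overlapping).

The two correlation matrices answer different questions and must not be
confused: the variant correlation matrix is about LD between variants; the
exposure correlation matrix is about phenotypic overlap between exposure
datasets.

# Correlation-matrix hygiene

Three practical hazards motivate the `harmonize` utilities.

**Signs.** LD tools often report squared correlations ($r^2$); MR requires
*signed* correlations. `validate_correlation()` enforces symmetry (within
$10^{-10}$), a unit diagonal, entries in $[-1, 1]$, and near-positive
semi-definiteness (smallest eigenvalue $\ge -10^{-8}$; empirical LD matrices
are often numerically indefinite at round-off level, but anything more
negative indicates a corrupted matrix and is a hard error). A matrix whose
off-diagonal entries are all non-negative is accepted but triggers a warning
as a likely unsigned or $r^2$ matrix.

**Allele orientation.** If the matrix was computed with different effect
alleles than the summary statistics, `flip_correlation(rho, flip)` applies
$\rho_{ij} \mapsto f_i f_j \rho_{ij}$ with $f \in \{\pm 1\}^J$. This is an
involution, preserves eigenvalues, and leaves an entry unchanged when both
of its variants flip.

**Extreme collinearity.** `prune_by_r2(rho, r2, seed)` repeatedly finds the
largest remaining absolute correlation in the upper triangle and, while it
exceeds $\sqrt{r^2}$, removes one member of the pair chosen by a fair coin
from a seeded RNG (success removes the row-index variant), zeroing its row
and column. Ties at the same maximum are broken by first occurrence in
row-major order — the first-match rule of an arg-max scan — and the result
is a pure function of the seed. On termination no surviving pair exceeds the
threshold, so re-pruning the kept set removes nothing. A caveat we document
rather than hide: because different thresholds consume the random stream
differently, keeping-set monotonicity across thresholds holds for the cases
we test but is not a structural guarantee of the coin-flip procedure.

`cholesky_decorrelate(z, rho)` returns $L^{-1} z$ for the lower Cholesky
factor $L$ of $\rho$, so that $\|L^{-1}z\|^2 = z^\top \rho^{-1} z$. If
$\rho$ is numerically singular a single ridge of $10^{-10} I$ is tried; if
that also fails the matrix is rejected rather than silently regularized
further, because spuriously precise correlated-variant results usually
signal a near-singular matrix rather than real information.

# Instrument strength

The first-stage F statistic is approximated from summary statistics by the
mean chi-square $F = \frac1J \sum_j (\hat\beta_{Xj}/\sigma_{Xj})^2$, since
each squared z-statistic estimates $1 + n r_j^2 \approx n r_j^2$ for
explained variance $r_j^2$. The exact F cannot be recovered from summary
data, and no finite-sample $(n-J-1)/n$ correction is applied even when $n$
is known — the approximation error is dominated by other terms and the
uncorrected statistic is the field's convention. With correlated variants
the same formula is applied to Cholesky-decorrelated z-scores (elementwise
ratio first, then decorrelation), which reproduces the uncorrelated formula
exactly at $\rho = I$ and is invariant to allele recoding.

**Conditional F.** In multivariable MR the relevant strength measure for
exposure $k$ is not its marginal F but the conditional F: the independent
instrument signal left after projecting out the other exposures'
associations. No closed formula is dictated by the summary data alone, and
the construction here is a design decision: z-statistics are standardized to
a common per-sample scale, $\tilde b_{jk} = (\hat\beta_{Xjk}/\sigma_{Xjk}) /
\sqrt{n_k}$ with known variance $1/n_k$ (this is where the per-exposure
sample sizes enter, and why the statistic is only computed when they are
supplied); exposure $k$'s column is regressed on the others by generalized
least squares whose residual variance accounts for the regression
coefficients and the exposure correlation matrix; and the minimized
heterogeneity statistic $Q_k$ is divided by $J - K + 1$ degrees of freedom:

$$F_k^{\mathrm{cond}} = \frac{1}{J-K+1}\; \min_{\delta}\;
  \sum_j \frac{(\tilde b_{jk} - \delta^\top \tilde b_{j,-k})^2}{v_j(\delta)}.$$

At $K = 1$ this reduces exactly to the univariable F. Collinear exposure
columns drive $Q_k$ to zero, and a conditional F below $10^{-6}$ raises a
non-identification warning. The degenerate case $J = K$ is refused outright
(zero residual degrees of freedom). The same engine, generalized to dense
covariance blocks, produces the component-space conditional F statistics
reported by the multivariable PC-GMM.

# Estimators

## IVW

Fixed-effects IVW is GLS of $\hat\beta_Y$ on $\hat\beta_X$ through the
origin with outcome covariance $\Omega = (\sigma_Y \sigma_Y^\top) \circ
\rho$. The random-effects model (the default) multiplies the SE by the
residual scale $\max\!\big(1, \sqrt{Q/(J-1)}\big)$ — floored at one so that
overdispersion can widen but never narrow intervals relative to
fixed-effects, matching standard summarized-data practice. Confidence
intervals use normal quantiles at a configurable level (default 95%).
Cochran's $Q$ and the attached F statistic are reported alongside.

## Debiased and penalized IVW

With weak instruments the IVW denominator $\sum \hat\beta_{Xj}^2 /
\sigma_{Yj}^2$ overstates the signal $\sum \gamma_j^2/\sigma_{Yj}^2$ by
$\sum \sigma_{Xj}^2/\sigma_{Yj}^2$, biasing $\hat\theta$ toward the null.
The debiased IVW estimator subtracts that excess:
$\hat\theta_{\mathrm{dIVW}} = A/B$ with $A = \sum \hat\beta_{Xj}
\hat\beta_{Yj}/\sigma_{Yj}^2$ and $B = \sum (\hat\beta_{Xj}^2 -
\sigma_{Xj}^2)/\sigma_{Yj}^2$. Its variance is computed by the delta method
on $A - \theta B$ under the two-sample normal model,

$$\widehat{\mathrm{Var}}(\hat\theta) = B^{-2} \sum_j
  \frac{(\hat\gamma_j^2 + \sigma_{Xj}^2)\,\tilde\sigma_{Yj}^2
        + \theta^2 \hat\gamma_j^2 \sigma_{Xj}^2
        + 2\theta^2 \sigma_{Xj}^4}{\tilde\sigma_{Yj}^4},$$

with plug-in $\hat\gamma_j^2 = \max(\hat\beta_{Xj}^2 - \sigma_{Xj}^2, 0)$
and $\tilde\sigma_{Yj}^2 = \sigma_{Yj}^2 + \tau^2$. The overdispersion
$\tau^2$ (balanced pleiotropy, analogous to a random-effects model) is
estimated by the method of moments — the weighted average excess of squared
residuals over their sampling variance — floored at zero, iterating between
$\theta$ and $\tau^2$. A non-positive $B$ means the instruments are
collectively too weak to separate signal from noise and is an explicit
error, not a silent sign flip.

The penalized IVW replaces $B$ with
$B^* = B/2 + \sqrt{B^2/4 + \lambda \widehat{\mathrm{Var}}(B)}$, which is
bounded away from zero: a small bias is accepted in exchange for taming the
variance explosion when $B$ is near zero. At $\lambda = 0$, $B^* = B$
exactly (for $B > 0$) and the estimator coincides with the debiased IVW;
$\lambda = 1$ is the default, the value recommended in the penalized-IVW
literature for smallest bias with valid inference. Weak-instrument
screening applies the rule verbatim: with threshold $\delta > 0$, variants
whose selection p-value exceeds $2\Phi(-\delta)$ are removed (selection
p-values must come from an independent sample to avoid winner's curse);
$\delta = 0$ keeps everything.

**Bootstrap Fieller inference.** The ratio structure makes normal theory
fragile when the denominator is noisy. The test statistic $S(\theta_0) =
(A - \theta_0 B^*)^2 / \widehat{\mathrm{Var}}(A - \theta_0 B)$ is calibrated
against a seeded parametric bootstrap of the summary statistics around their
observed values (default 1000 replicates — stable at desk-scale cost); the
confidence set $\{\theta_0 : S(\theta_0) \le q_{0.95}\}$ is solved as a
quadratic inequality in $\theta_0$, always contains the point estimate, and
is reported as unbounded (with a warning) when the leading coefficient is
not positive — the honest Fieller outcome for very weak denominators.

## Continuously-updating GMM

The CUE-GMM estimator minimizes $g(\theta)^\top \Omega(\theta)^{-1}
g(\theta)$ with moments $g_j(\theta) = \hat\beta_{Yj} -
\hat\beta_{Xj}^\top\theta$ and

$$\Omega(\theta) = \rho \circ \big(\sigma_Y\sigma_Y^\top
  + T(\theta)\,\rho_X\,T(\theta)^\top\big) + \tau^2 I,
  \qquad T(\theta)_{jk} = \sigma_{Xjk}\theta_k,$$

i.e. the full $\theta$-dependent covariance of the moments, including
variant correlations $\rho$ and exposure correlations $\rho_X$. Continuous
updating (rather than two-step weighting) is what confers weak-instrument
robustness. Because the CUE objective is non-convex, minimization uses
quasi-Newton iterations from five starts — the IVW estimate and symmetric
offsets of $\pm 2$ and $\pm 4$ IVW standard errors — keeping the best
optimum; an optimum no worse than the IVW starting value is asserted in the
test suite. Overdispersion cannot be profiled by joint minimization (the
objective vanishes as $\tau^2 \to \infty$), so in robust mode (the default)
$\tau^2$ is chosen by moment matching: if the minimized objective exceeds
its $\chi^2$ degrees of freedom $J - K$, $\tau^2$ is raised by root-finding
until they agree, and floored at zero otherwise. Standard errors come from
the GMM sandwich $(G^\top\Omega^{-1}G)^{-1}$ at the optimum. The sample
sizes `nx`/`ny` are required inputs of the GMM interfaces; the moment
variance itself uses the reported standard errors (which already encode
sample size), and the sample sizes feed the strength diagnostics and
metadata.

## Principal-component GMM

For hundreds of highly correlated variants from one gene region, inverting
$\rho$ is numerically hopeless and pruning throws data away. Instead the
summary statistics are projected onto the leading eigenvectors of a
*weighted* LD matrix $\Psi = \rho \circ (w w^\top)$ with weights $w_j =
|\hat\beta_{Xj}|/\sigma_{Yj}$ (multivariable: row norm of the exposure
associations over $\sigma_{Yj}$), so the retained subspace emphasizes
exposure-relevant, outcome-precise variation; this weighting is a design
choice sourced from the dimension-reduction literature for cis-instrument
MR, not something the summary data dictate. The number of components $r$ is
the smallest count whose cumulative eigenvalue fraction reaches `thres`
(default 0.999), or can be fixed via `r`. Associations and their full
covariance matrices are transformed by the orthonormal loadings $W$
($\Sigma^* = W^\top \Sigma W$), and the CUE machinery runs in component
space with dense covariances, overdispersion calibrated to $r - K$ degrees
of freedom, and a component-space F statistic
$\hat\beta_X^{*\top}\Sigma_X^{*-1}\hat\beta_X^*/r$ reported so users can see
how instrument strength responds to the choice of $r$.

Two numerical caveats. Eigenvalues that are negative at round-off level are
clipped to zero when computing cumulative fractions. And the retained
subspace is only stable under perturbations (e.g. duplicating a variant)
when $r$ captures the bulk of the weighted spectrum; at very small $r$ the
composition of the last retained component can swing on near-ties in the
eigenvalues, which is why the default threshold is conservative (99.9%).

## Constrained maximum likelihood

The cML estimators maximize the Gaussian likelihood of the summary data
subject to *exactly* $K$ variants carrying a free pleiotropy term $r_j$:

$$\min_{\theta, \gamma, r}\ \sum_j \Big[
  \frac{(\hat\beta_{Xj}-\gamma_j)^2}{\sigma_{Xj}^2} +
  \frac{(\hat\beta_{Yj}-\theta\gamma_j-r_j)^2}{\sigma_{Yj}^2} \Big]
  \quad \text{s.t. } \|r\|_0 = K.$$

Minimization alternates three exact block updates: support selection given
$\theta$ (the $K$ variants with the largest profile costs
$(\hat\beta_{Yj}-\theta\hat\beta_{Xj})^2 / (\sigma_{Yj}^2 +
\theta^2\sigma_{Xj}^2)$ are declared invalid), $\gamma$ given $\theta$ and
the support, and $\theta$ given $\gamma$. Because every block is an exact
minimizer the objective is non-increasing, and the implementation asserts
this at every iteration rather than trusting it. Convergence is declared at
a relative objective change below $10^{-7}$ or 100 iterations. Ten random
starts around the IVW estimate guard against the non-convexity introduced by
support switching, with objective ties broken toward the smallest $|\theta|$
(the most conservative causal claim).

$K$ ranges over $0, \dots, J-2$ by default ($K = J-1$ would leave a single
"valid" variant and an unidentified model) and is selected by
$\mathrm{BIC}(K) = \ell_K + K \log n$, where $\ell_K$ is the minimized
objective (twice the negative log-likelihood up to a constant) and $n$ is
the user-supplied sample size — the smaller of the exposure and outcome
sample sizes is the recommended choice, which we document but do not
enforce. Model averaging combines the per-$K$ estimates with weights
$\propto \exp(-\mathrm{BIC}_K/2)$ and the Buckland model-averaging standard
error; data perturbation re-noises the summary statistics by their standard
errors (default 200 seeded replicates) and reports the mean and spread of
the re-estimates, which absorbs selection uncertainty and generally widens
the intervals. Per-model standard errors come from the numerical curvature
of the profile objective. The multivariable version replaces the scalar
profile cost with $(\hat\beta_{Yj}-\theta^\top\hat\beta_{Xj})^2 /
(\sigma_{Yj}^2 + \theta^\top\Sigma_{Xj}\theta)$, where $\Sigma_{Xj}$ uses
the exposure correlation matrix.

# The synthetic-data generator

`simulate_univariable()` / `simulate_multivariable()` draw directly from the
working model above, on a standardized-trait scale where standard errors are
$1/\sqrt{n}$: $\gamma_j \sim N(0, \sigma_\gamma^2)$ with $\sigma_\gamma$ set
from a target mean F statistic via $E[F] = 1 +
\sigma_\gamma^2/\sigma_X^2$ — so tests can dial instrument strength in the
same units the package diagnoses it. The named regimes are weak (mean F 4,
the regime where IVW visibly attenuates), moderate (30), and strong (100);
default sample sizes are 50000 per trait, typical of consortium GWAS.
Pleiotropy follows the standard taxonomy: balanced ($\alpha_j \sim N(0,
\sigma_\alpha^2)$, default $\sigma_\alpha = 0.01$) or directional (mean
shifted by 0.01). LD correlates both the true effects and the estimation
errors through the supplied $\rho$; engineered collinearity between
multivariable exposure columns exercises the conditional-F warnings. Every
draw is a pure function of (parameters, seed).

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: winner's curse from in-sample variant
selection, sample overlap between exposure and outcome datasets,
non-Gaussian summary-statistic errors, allele-frequency-dependent standard
errors, mismatched-ancestry LD matrices, and binary-outcome
noncollapsibility. The estimators' operating characteristics are verified
under the model they assume, which is the appropriate calibration target but
not a field trial.

# Test and calibration scale

The test suite verifies exact identities (GLS oracles at $10^{-10}$,
closed-form Cholesky, flip involution, screening arithmetic,
cross-estimator limits) on instances of $J \le 10$, grid-search oracles at
step $10^{-4}$, and operating characteristics by seeded simulation: type-I
error of IVW/dIVW/pIVW at nominal 0.05 over 500 null replicates (accepted
band 0.02–0.09), recovery of $\theta = 0.5$ by dIVW with 100 weak
instruments over 200 replicates (within 3 Monte-Carlo SEs, and closer to
truth than IVW), modal selection of $K = 0$ by cML over 50 clean replicates,
recovery of 3 planted invalid instruments out of 30 in at least 80% of 25
replicates, and DP-versus-no-DP interval widening. These sizes were chosen
to make the Monte-Carlo error comfortably smaller than the tested margins
while keeping the default suite fast.

# Known limitations

* dIVW, pIVW, and cML assume uncorrelated variants and refuse a correlation
  matrix by design; use IVW or the GMM family for correlated variants.
* The bootstrap Fieller confidence set can be a bounded interval, a
  complement of an interval, or the whole line; only the bounded case is
  reported with finite limits, the others as infinite with a warning.
* The conditional-F construction is one member of a family of
  summary-data conditional strength statistics; different published
  implementations standardize differently and can differ at the first
  decimal on real data.
* Estimated exposure correlation matrices cannot be recovered from summary
  data; when exposure samples overlap and the matrix is unknown, a
  sensitivity analysis over plausible values is the recommended use of the
  `exposure_correlation` argument.
* No allele-string harmonization: the flip vector is an input, produced by
  comparing effect alleles upstream.
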