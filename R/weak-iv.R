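# Weak-instrument-robust IVW variants. Both estimators assume uncorrelated
# variants and correct the IVW denominator for the sampling variance of the
# exposure associations: the naive denominator sum(bx^2/byse^2) overstates
# the true signal sum(gamma^2/byse^2) by sum(bxse^2/byse^2), which is what
# drives weak-instrument bias towards the null in two-sample MR.

# Shared moment pieces on weights 1/(byse^2 + tau2).
divw_moments <- function(bx, bxse, by, byse, tau2 = 0) {
  vy <- byse^2 + tau2
  list(
    A = sum(bx * by / vy),                 # numerator
    B = sum((bx^2 - bxse^2) / vy),         # debiased denominator
    VB = sum((4 * bx^2 * bxse^2 + 2 * bxse^4) / vy^2),  # est. Var(B)
    vy = vy)
}

# Delta-method variance of the ratio estimator: Var(A - theta B) evaluated
# with plug-ins gamma^2 ~ bx^2 - bxse^2 (floored at 0), divided by denom^2.
# Derivation: A - theta B = sum (gamma+ex)(ey - theta ex)/vy with
# Var((gamma+ex)(ey-theta ex)) = (gamma^2+sx^2)vy + theta^2 gamma^2 sx^2
# + 2 theta^2 sx^4.
divw_var <- function(bx, bxse, byse, theta, denom, tau2 = 0) {
  vy <- byse^2 + tau2
  g2 <- pmax(bx^2 - bxse^2, 0)
  num <- sum(((g2 + bxse^2) * vy + theta^2 * g2 * bxse^2 +
                2 * theta^2 * bxse^4) / vy^2)
  num / denom^2
}

# Method-of-moments overdispersion: average standardized excess of squared
# residuals over their sampling variance, floored at zero.
estimate_tau2 <- function(bx, bxse, by, byse, theta) {
  w <- 1 / byse^2
  max(0, sum(w * ((by - theta * bx)^2 - byse^2 - theta^2 * bxse^2)) / sum(w))
}

#' Debiased inverse-variance weighted estimator
#'
#' Replaces the IVW denominator `sum(bx^2/byse^2)` with its unbiased analogue
#' `sum((bx^2 - bxse^2)/byse^2)`, removing the weak-instrument attenuation of
#' the two-sample IVW estimate. With `over_dispersion = TRUE` an
#' overdispersion variance `tau^2` (balanced pleiotropy, analogous to a
#' random-effects model) is estimated by method of moments, floored at zero,
#' and added to the outcome variances; estimation iterates between the effect
#' and `tau^2`.
#'
#' @param data an [mr_dataset] with uncorrelated variants (an error is raised
#'   if a correlation matrix is present).
#' @param over_dispersion estimate an overdispersion component (default TRUE).
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_estimate`; `$tau2` holds the overdispersion estimate.
#' @export
mr_divw <- function(data, over_dispersion = TRUE, ci_level = 0.95) {
  stopifnot(inherits(data, "mr_dataset"))
  if (!is.null(data$correlation)) {
    stopf("the debiased IVW estimator assumes uncorrelated variants; remove the correlation matrix")
  }
  bx <- data$bx; bxse <- data$bxse; by <- data$by; byse <- data$byse
  tau2 <- 0
  for (it in 1:10) {
    m <- divw_moments(bx, bxse, by, byse, tau2)
    if (m$B <= 0) {
      stopf("debiased denominator is non-positive: instruments are collectively too weak")
    }
    theta <- m$A / m$B
    if (!over_dispersion) break
    tau2_new <- estimate_tau2(bx, bxse, by, byse, theta)
    if (abs(tau2_new - tau2) < 1e-12) { tau2 <- tau2_new; break }
    tau2 <- tau2_new
  }
  m <- divw_moments(bx, bxse, by, byse, tau2)
  theta <- m$A / m$B
  se <- sqrt(divw_var(bx, bxse, byse, theta, m$B, tau2))
  new_mr_estimate("Debiased inverse-variance weighted", theta, se, ci_level,
                  strength = f_statistic(data),
                  options = list(over_dispersion = over_dispersion),
                  J = length(bx), extra = list(tau2 = tau2))
}

#' Options for the penalized IVW estimator
#'
#' @param lambda penalty parameter >= 0 (default 1, the recommended value for
#'   smallest bias with valid inference).
#' @param delta z-score threshold for screening out weak instruments
#'   (default 0 = no screening; variants with selection p-value above
#'   `2 * pnorm(delta, lower.tail = FALSE)` are removed).
#' @param sel_pval per-variant selection p-values for the exposure
#'   associations, from an independent selection sample; required when
#'   `delta > 0`.
#' @param over_dispersion allow overdispersion of variant-specific estimates
#'   (default TRUE).
#' @param boot_fieller compute the p-value and confidence interval by the
#'   bootstrap Fieller method (default FALSE).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (default 2020).
#' @return a list of class `pivw_options`.
#' @export
pivw_options <- function(lambda = 1, delta = 0, sel_pval = NULL,
                         over_dispersion = TRUE, boot_fieller = FALSE,
                         n_boot = 1000, seed = 2020) {
  if (lambda < 0) stopf("lambda must be >= 0")
  if (delta < 0) stopf("delta must be >= 0")
  structure(list(lambda = lambda, delta = delta, sel_pval = sel_pval,
                 over_dispersion = over_dispersion, boot_fieller = boot_fieller,
                 n_boot = n_boot, seed = seed),
            class = "pivw_options")
}

#' Penalized inverse-variance weighted estimator
#'
#' Extends the debiased IVW estimator with a penalized-likelihood denominator
#' that is bounded away from zero, trading a small bias for a large variance
#' reduction when instruments are weak:
#' `B* = B/2 + sqrt(B^2/4 + lambda * Vhat(B))`, where `B` is the debiased
#' denominator and `Vhat(B)` its estimated sampling variance. At
#' `lambda = 0` the estimator coincides with the debiased IVW. Optional
#' screening removes variants whose selection p-value exceeds
#' `2 * pnorm(delta, lower.tail = FALSE)` (with `delta = 0` all variants are
#' used). The bootstrap Fieller option avoids normal approximation of the
#' denominator: the quadratic test statistic `(A - theta0 B*)^2 / V(theta0)`
#' is calibrated against a seeded parametric bootstrap and the confidence set
#' solved as a quadratic inequality in `theta0`; it always contains the point
#' estimate.
#'
#' @param data an [mr_dataset] with uncorrelated variants.
#' @param opts a [pivw_options] object.
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_estimate`; extras include `tau2`, `n_kept` (variants
#'   retained after screening), `kept` (their indices), and `seed` when the
#'   bootstrap is used.
#' @export
mr_pivw <- function(data, opts = pivw_options(), ci_level = 0.95) {
  stopifnot(inherits(data, "mr_dataset"), inherits(opts, "pivw_options"))
  if (!is.null(data$correlation)) {
    stopf("the penalized IVW estimator assumes uncorrelated variants; remove the correlation matrix")
  }
  keep <- seq_along(data$bx)
  if (opts$delta > 0) {
    if (is.null(opts$sel_pval)) {
      stopf("`sel_pval` must be supplied when delta > 0")
    }
    if (length(opts$sel_pval) != length(data$bx) ||
        any(opts$sel_pval < 0 | opts$sel_pval > 1)) {
      stopf("`sel_pval` must be per-variant p-values in [0, 1]")
    }
    cutoff <- 2 * stats::pnorm(opts$delta, lower.tail = FALSE)
    keep <- which(opts$sel_pval <= cutoff)
    if (!length(keep)) stopf("screening at delta = %g removed all variants", opts$delta)
  }
  bx <- data$bx[keep]; bxse <- data$bxse[keep]
  by <- data$by[keep]; byse <- data$byse[keep]

  pen_denom <- function(m) m$B / 2 + sqrt(m$B^2 / 4 + opts$lambda * m$VB)
  tau2 <- 0
  for (it in 1:10) {
    m <- divw_moments(bx, bxse, by, byse, tau2)
    theta <- m$A / pen_denom(m)
    if (!opts$over_dispersion) break
    tau2_new <- estimate_tau2(bx, bxse, by, byse, theta)
    if (abs(tau2_new - tau2) < 1e-12) { tau2 <- tau2_new; break }
    tau2 <- tau2_new
  }
  m <- divw_moments(bx, bxse, by, byse, tau2)
  Bstar <- pen_denom(m)
  theta <- m$A / Bstar
  se <- sqrt(divw_var(bx, bxse, byse, theta, Bstar, tau2))
  extra <- list(tau2 = tau2, n_kept = length(keep), kept = keep,
                lambda = opts$lambda, delta = opts$delta)
  p_value <- NULL; ci <- NULL
  if (opts$boot_fieller) {
    bf <- pivw_boot_fieller(bx, bxse, by, byse, theta, tau2, opts, ci_level)
    p_value <- bf$p_value; ci <- bf$ci
    extra$seed <- opts$seed
    extra$boot_quantile <- bf$q
  }
  new_mr_estimate("Penalized inverse-variance weighted", theta, se, ci_level,
                  p_value = p_value, ci = ci,
                  strength = f_statistic(mr_dataset(bx, bxse, by, byse)),
                  options = unclass(opts)[c("lambda", "delta", "over_dispersion",
                                            "boot_fieller", "n_boot")],
                  J = length(bx), extra = extra)
}

# Bootstrap Fieller inference. V(theta0) = c0 + c2 * theta0^2 is the
# delta-method variance of A - theta0 * B; the test statistic
# S(theta0) = (A - theta0 B*)^2 / V(theta0) is calibrated by parametric
# bootstrap of the summary statistics around their observed values.
pivw_boot_fieller <- function(bx, bxse, by, byse, theta_hat, tau2, opts,
                              ci_level) {
  vy <- byse^2 + tau2
  g2 <- pmax(bx^2 - bxse^2, 0)
  c0 <- sum(((g2 + bxse^2) * vy) / vy^2)
  c2 <- sum((g2 * bxse^2 + 2 * bxse^4) / vy^2)
  m <- divw_moments(bx, bxse, by, byse, tau2)
  Bstar <- m$B / 2 + sqrt(m$B^2 / 4 + opts$lambda * m$VB)
  Sobs0 <- m$A^2 / c0  # statistic at theta0 = 0 (p-value)
  J <- length(bx)
  S_boot <- with_seed(opts$seed, {
    vapply(seq_len(opts$n_boot), function(b) {
      bx_b <- stats::rnorm(J, bx, bxse)
      by_b <- stats::rnorm(J, by, sqrt(vy))
      mb <- divw_moments(bx_b, bxse, by_b, byse, tau2)
      Bsb <- mb$B / 2 + sqrt(mb$B^2 / 4 + opts$lambda * mb$VB)
      vb <- c0 + c2 * theta_hat^2
      (mb$A - theta_hat * Bsb)^2 / vb
    }, numeric(1))
  })
  q <- unname(stats::quantile(S_boot, ci_level, type = 7))
  p_value <- mean(S_boot >= Sobs0)
  # CI: solve (A - theta B*)^2 <= q * (c0 + c2 theta^2) for theta.
  a <- Bstar^2 - q * c2
  b <- -2 * m$A * Bstar
  cc <- m$A^2 - q * c0
  disc <- b^2 - 4 * a * cc
  if (a > 0 && disc >= 0) {
    roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    ci <- cbind(lower = roots[1], upper = roots[2])
  } else {
    warnf("bootstrap Fieller confidence set is unbounded; reporting infinite limits")
    ci <- cbind(lower = -Inf, upper = Inf)
  }
  list(p_value = p_value, ci = ci, q = q)
}
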