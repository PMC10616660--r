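# Continuously-updating GMM (CUE) estimators. The moment for variant j is
# g_j(theta) = by_j - bx_j' theta, with a theta-dependent covariance
#   Omega(theta) = rho * (byse %o% byse + T(theta) rho_x T(theta)')
#                  + tau2 * I,
# where T(theta) = BXse * theta (columnwise) and rho / rho_x are the variant
# and exposure correlation matrices (identity when absent). CUE minimizes
# g' Omega(theta)^-1 g, which is markedly more robust to weak instruments
# than two-step GMM or IVW. Overdispersion (tau2, "robust" mode) is chosen by
# moment matching: the minimized objective is calibrated to its chi-square
# degrees of freedom, floored at zero.

cue_omega <- function(theta, byse, BXse, rho, rho_x, tau2) {
  TT <- BXse * matrix(theta, nrow(BXse), length(theta), byrow = TRUE)
  core <- byse %o% byse + TT %*% rho_x %*% t(TT)
  Om <- if (is.null(rho)) {
    diag(diag(core), nrow(core))
  } else {
    rho * core
  }
  Om + tau2 * diag(nrow(Om))
}

cue_objective <- function(theta, by, BX, byse, BXse, rho, rho_x, tau2) {
  g <- by - drop(BX %*% theta)
  Om <- cue_omega(theta, byse, BXse, rho, rho_x, tau2)
  out <- tryCatch(drop(crossprod(g, chol_solve(Om, g))), error = function(e) Inf)
  if (!is.finite(out)) Inf else out
}

# Minimize the CUE objective over theta for fixed tau2, from several starts.
cue_minimize <- function(by, BX, byse, BXse, rho, rho_x, tau2, starts,
                         reltol = 1e-12, maxit = 500) {
  f <- function(th) cue_objective(th, by, BX, byse, BXse, rho, rho_x, tau2)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- if (ncol(starts) == 1L) {
      o <- stats::optim(starts[s, ], f, method = "Brent",
                        lower = starts[s, ] - 10, upper = starts[s, ] + 10)
      o
    } else {
      stats::optim(starts[s, ], f, method = "BFGS",
                   control = list(reltol = reltol, maxit = maxit))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value)) stopf("CUE-GMM optimization failed to converge from all starts")
  best
}

# Build default multi-start matrix around an IVW-type starting estimate.
cue_starts <- function(theta0, se0, n_starts = 5) {
  K <- length(theta0)
  se0[!is.finite(se0) | se0 <= 0] <- 0.5
  offsets <- c(0, -2, 2, -4, 4)[seq_len(n_starts)]
  do.call(rbind, lapply(offsets, function(o) theta0 + o * se0))
}

#' Options for the GMM estimators
#'
#' @param robust estimate an overdispersion component so that inference is
#'   robust to heterogeneity of variant-specific estimates (default TRUE).
#' @param n_starts number of optimizer starts around the IVW estimate
#'   (default 5).
#' @param reltol optimizer relative tolerance (default 1e-12).
#' @param maxit maximum optimizer iterations (default 500).
#' @return a list of class `gmm_options`.
#' @export
gmm_options <- function(robust = TRUE, n_starts = 5, reltol = 1e-12,
                        maxit = 500) {
  structure(list(robust = robust, n_starts = n_starts, reltol = reltol,
                 maxit = maxit), class = "gmm_options")
}

# Shared driver: minimize over theta; if robust and the minimized objective
# exceeds the chi-square df, raise tau2 until they match (uniroot on the
# profiled objective, which is decreasing in tau2).
cue_fit <- function(by, BX, byse, BXse, rho, rho_x, opts, theta0, se0, df) {
  starts <- cue_starts(theta0, se0, opts$n_starts)
  run <- function(tau2) cue_minimize(by, BX, byse, BXse, rho, rho_x, tau2,
                                     starts, opts$reltol, opts$maxit)
  fit <- run(0)
  tau2 <- 0
  if (opts$robust && df > 0 && fit$value > df) {
    g <- function(t2) run(t2)$value - df
    upper <- stats::median(byse^2)
    while (g(upper) > 0 && upper < 1e6 * stats::median(byse^2)) upper <- upper * 4
    tau2 <- tryCatch(stats::uniroot(g, c(0, upper), tol = 1e-10)$root,
                     error = function(e) 0)
    fit <- run(tau2)
  }
  theta <- fit$par
  Om <- cue_omega(theta, byse, BXse, rho, rho_x, tau2)
  G <- BX
  V <- solve(crossprod(G, chol_solve(Om, G)))
  list(theta = theta, se = sqrt(diag(V)), vcov = V, tau2 = tau2,
       objective = fit$value, df = df)
}

#' Multivariable continuously-updating GMM estimator
#'
#' Estimates multivariable causal effects by minimizing the
#' continuously-updating GMM objective. Compared with multivariable IVW the
#' estimates are more robust to weak instruments and measurement error in the
#' exposures, which matters in the multivariable setting because
#' weak-instrument bias there can point in any direction. Requires the sample
#' sizes for the exposure and outcome associations. Variants are assumed
#' uncorrelated unless a correlation matrix is present in the dataset; the
#' exposure correlation matrix defaults to the identity.
#'
#' @param data an [mr_mvdataset] with J > K.
#' @param nx,ny sample sizes for the exposure (length 1 or K) and outcome
#'   associations (required).
#' @param opts a [gmm_options] object.
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_mvestimate`; extras include `tau2` and the minimized
#'   objective.
#' @export
mr_mvgmm <- function(data, nx, ny, opts = gmm_options(), ci_level = 0.95) {
  stopifnot(inherits(data, "mr_mvdataset"), inherits(opts, "gmm_options"))
  J <- nrow(data$BX); K <- ncol(data$BX)
  if (J <= K) stopf("need more variants than exposures (J = %d, K = %d)", J, K)
  nx <- broadcast_nx(nx, K)
  if (missing(ny) || is.null(ny)) stopf("outcome sample size `ny` is required")
  ivw0 <- mr_mvivw(data, model = "fixed")
  fit <- cue_fit(data$by, data$BX, data$byse, data$BXse, data$correlation,
                 data$exposure_correlation, opts, ivw0$estimate, ivw0$se,
                 df = J - K)
  strength <- conditional_f_statistics(data, nx)
  new_mr_mvestimate(
    "Multivariable continuously-updating GMM",
    exposures = data$exposures, estimate = fit$theta, se = fit$se,
    ci_level = ci_level,
    heterogeneity = list(Q = fit$objective, df = fit$df),
    strength = strength,
    options = list(robust = opts$robust, nx = nx, ny = ny), J = J,
    extra = list(tau2 = fit$tau2, objective = fit$objective))
}

#' Univariable continuously-updating GMM estimator
#'
#' Single-exposure version of [mr_mvgmm]; mainly a building block for
#' [mr_pcgmm] and for cross-checks against grid search of the CUE objective.
#'
#' @param data an [mr_dataset].
#' @param nx,ny exposure and outcome association sample sizes.
#' @param opts a [gmm_options] object.
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_estimate`.
#' @export
mr_gmm <- function(data, nx, ny, opts = gmm_options(), ci_level = 0.95) {
  stopifnot(inherits(data, "mr_dataset"))
  J <- length(data$bx)
  ivw0 <- mr_ivw(data, model = "fixed")
  fit <- cue_fit(data$by, cbind(data$bx), data$byse, cbind(data$bxse),
                 data$correlation, matrix(1, 1, 1), opts,
                 ivw0$estimate, ivw0$se, df = J - 1L)
  new_mr_estimate(
    "Continuously-updating GMM", fit$theta, fit$se, ci_level,
    heterogeneity = list(Q = fit$objective, df = fit$df),
    strength = f_statistic(data),
    options = list(robust = opts$robust, nx = nx, ny = ny), J = J,
    extra = list(tau2 = fit$tau2, objective = fit$objective))
}
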