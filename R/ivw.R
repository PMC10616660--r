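#' Inverse-variance weighted estimator
#'
#' The workhorse summarized-data MR estimator: a weighted regression of the
#' variant-outcome associations on the variant-exposure associations through
#' the origin, with weights `1/byse^2`. With a variant correlation matrix
#' `rho` the weighting generalizes to the full covariance
#' `Omega = (byse %o% byse) * rho` of the outcome associations, giving the
#' GLS estimate `(x' Omega^-1 x)^-1 x' Omega^-1 y`. Under the random-effects
#' model the standard error is inflated by the residual scale when it exceeds
#' one (overdispersion of variant-specific estimates is absorbed, but
#' precision is never allowed to exceed the fixed-effects analysis).
#'
#' @param data an [mr_dataset].
#' @param model `"random"` (default, requires J >= 2) or `"fixed"`.
#' @param ci_level confidence level (default 0.95, normal quantiles).
#' @return an `mr_estimate` with heterogeneity diagnostics (Cochran's Q) and
#'   the first-stage F statistic attached.
#' @examples
#' d <- mr_dataset(bx = c(0.1, 0.2, 0.15), bxse = rep(0.01, 3),
#'                 by = c(0.05, 0.1, 0.08), byse = rep(0.02, 3))
#' mr_ivw(d)
#' @export
mr_ivw <- function(data, model = c("random", "fixed"), ci_level = 0.95) {
  stopifnot(inherits(data, "mr_dataset"))
  model <- match.arg(model)
  J <- length(data$bx)
  if (model == "random" && J < 2L) model <- "fixed"
  fit <- gls_fit(cbind(data$bx), data$by, data$byse, data$correlation)
  se <- fit$se
  phi <- 1
  if (model == "random" && J > 1L) {
    phi <- max(1, sqrt(fit$rss / (J - 1)))
    se <- se * phi
  }
  het <- list(Q = fit$rss, df = J - 1L,
              p = if (J > 1L) stats::pchisq(fit$rss, J - 1L, lower.tail = FALSE) else NA_real_)
  new_mr_estimate(
    method = sprintf("Inverse-variance weighted (%s-effects%s)", model,
                     if (!is.null(data$correlation)) ", correlated variants" else ""),
    estimate = fit$coef[1L], se = se, ci_level = ci_level,
    heterogeneity = het, strength = f_statistic(data),
    options = list(model = model, correlated = !is.null(data$correlation)),
    J = J, extra = list(residual_scale = phi))
}

#' Multivariable inverse-variance weighted estimator
#'
#' Generalized weighted regression of the outcome associations on all
#' exposure-association columns jointly, without intercept. When exposure
#' sample sizes `nx` are supplied, per-exposure conditional F statistics are
#' computed and attached (see [conditional_f_statistics]); they are the
#' relevant instrument-strength measure in the multivariable setting.
#'
#' @param data an [mr_mvdataset] with J > K.
#' @param nx optional per-exposure sample sizes; conditional F statistics are
#'   only calculated when provided. A single value is broadcast.
#' @param model `"random"` (default) or `"fixed"` effects.
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_mvestimate`.
#' @export
mr_mvivw <- function(data, nx = NULL, model = c("random", "fixed"),
                     ci_level = 0.95) {
  stopifnot(inherits(data, "mr_mvdataset"))
  model <- match.arg(model)
  J <- nrow(data$BX); K <- ncol(data$BX)
  if (J <= K) stopf("need more variants than exposures (J = %d, K = %d)", J, K)
  qrX <- qr(data$BX / data$byse)
  if (qrX$rank < K) stopf("exposure association columns are collinear; effects not identified")
  fit <- gls_fit(data$BX, data$by, data$byse, data$correlation)
  se <- fit$se
  phi <- 1
  if (model == "random") {
    phi <- max(1, sqrt(fit$rss / (J - K)))
    se <- se * phi
  }
  strength <- if (!is.null(nx)) conditional_f_statistics(data, nx) else NULL
  het <- list(Q = fit$rss, df = J - K,
              p = stats::pchisq(fit$rss, J - K, lower.tail = FALSE))
  new_mr_mvestimate(
    method = sprintf("Multivariable inverse-variance weighted (%s-effects)", model),
    exposures = data$exposures, estimate = fit$coef, se = se,
    ci_level = ci_level, heterogeneity = het, strength = strength,
    options = list(model = model, nx = nx), J = J,
    extra = list(residual_scale = phi))
}

# Generalized least squares of y on columns of X with outcome covariance
# Omega = (byse %o% byse) * rho (rho = identity when NULL). Returns
# coefficients, their fixed-effects SEs, and the weighted residual sum of
# squares (Cochran's Q at the estimate).
gls_fit <- function(X, y, byse, rho = NULL) {
  X <- as.matrix(X)
  if (is.null(rho)) {
    w <- 1 / byse^2
    XtWX <- crossprod(X * sqrt(w))
    XtWy <- crossprod(X, w * y)
    V <- solve(XtWX)
    coef <- drop(V %*% XtWy)
    resid <- y - drop(X %*% coef)
    rss <- sum(w * resid^2)
  } else {
    Omega <- (byse %o% byse) * rho
    L <- chol_lower(Omega)
    Xs <- forwardsolve(L, X)
    ys <- forwardsolve(L, y)
    XtWX <- crossprod(Xs)
    V <- solve(XtWX)
    coef <- drop(V %*% crossprod(Xs, ys))
    resid <- ys - drop(Xs %*% coef)
    rss <- sum(resid^2)
  }
  list(coef = coef, se = sqrt(diag(V)), vcov = V, rss = rss)
}
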