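# Principal-component GMM for densely correlated variants from a single gene
# region. Instead of pruning hundreds of highly correlated variants down to a
# few, the full set of variant associations is projected onto the leading
# eigenvectors of a weighted version of the variant correlation matrix, and
# the CUE-GMM estimator is run in component space. This uses all the data
# while avoiding the numerical instability of inverting a near-singular LD
# matrix, and is less sensitive to misspecification of the correlation
# matrix.

#' Weighted principal-component transform of the variant correlation matrix
#'
#' Eigendecomposes `Psi = diag(w) %*% rho %*% diag(w)` where the weight
#' `w_j = |bx_j| / byse_j` (for multivariable data, the row norm of `BX` over
#' `byse_j`) up-weights variants whose associations are exposure-relevant and
#' outcome-precise. The number of retained components `r` is the smallest
#' count whose cumulative eigenvalue fraction reaches `thres` (default 0.999,
#' i.e. components explaining 99.9% of the variability of the weighted
#' matrix), unless `r` is fixed explicitly.
#'
#' @param data an [mr_dataset] or [mr_mvdataset] with a correlation matrix.
#' @param thres target cumulative eigenvalue fraction in (0, 1\]
#'   (default 0.999).
#' @param r optional explicit number of components (overrides `thres`).
#' @return a list of class `mr_pctransform` with `r`, `eigenvalues`
#'   (nonincreasing), `loadings` (J x r orthonormal), and `thres`.
#' @export
weighted_pc_transform <- function(data, thres = 0.999, r = NULL) {
  if (is.null(data$correlation)) {
    stopf("a variant correlation matrix is required for the PC transform")
  }
  rho <- data$correlation
  J <- nrow(rho)
  w <- if (inherits(data, "mr_mvdataset")) {
    sqrt(rowSums(data$BX^2)) / data$byse
  } else {
    abs(data$bx) / data$byse
  }
  Psi <- rho * (w %o% w)
  ed <- eigen(Psi, symmetric = TRUE)
  lam <- ed$values
  frac <- cumsum(pmax(lam, 0)) / sum(pmax(lam, 0))
  if (is.null(r)) {
    if (thres <= 0 || thres > 1) stopf("thres must lie in (0, 1]")
    r <- which(frac >= thres - 1e-12)[1L]
  } else {
    if (r < 1 || r > J) stopf("r must lie in 1..%d", J)
  }
  structure(list(r = as.integer(r), eigenvalues = lam,
                 loadings = ed$vectors[, seq_len(r), drop = FALSE],
                 thres = thres, J = J),
            class = "mr_pctransform")
}

# Project univariable summary data onto the retained components, returning
# component-space associations and their full covariance matrices.
pc_project_uni <- function(data, W) {
  rho <- data$correlation
  Sx <- rho * (data$bxse %o% data$bxse)
  Sy <- rho * (data$byse %o% data$byse)
  list(bx = drop(crossprod(W, data$bx)),
       by = drop(crossprod(W, data$by)),
       Sx = crossprod(W, Sx %*% W),
       Sy = crossprod(W, Sy %*% W))
}

# Component-space CUE objective with dense covariances (univariable):
# Omega*(theta) = Sy + theta^2 Sx + tau2 I_r (loadings are orthonormal).
cue_fit_pc_uni <- function(bx, by, Sx, Sy, opts, theta0, se0, df) {
  f <- function(theta, tau2) {
    g <- by - bx * theta
    Om <- Sy + theta^2 * Sx + tau2 * diag(length(g))
    out <- tryCatch(drop(crossprod(g, chol_solve(Om, g))), error = function(e) Inf)
    if (!is.finite(out)) Inf else out
  }
  starts <- cue_starts(theta0, se0, opts$n_starts)
  run <- function(tau2) {
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ], f, tau2 = tau2, method = "Brent",
                        lower = starts[s, ] - 10, upper = starts[s, ] + 10)
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }
  fit <- run(0); tau2 <- 0
  if (opts$robust && df > 0 && fit$value > df) {
    g2 <- function(t2) run(t2)$value - df
    upper <- stats::median(diag(Sy))
    while (g2(upper) > 0 && upper < 1e6 * stats::median(diag(Sy))) upper <- upper * 4
    tau2 <- tryCatch(stats::uniroot(g2, c(0, upper), tol = 1e-10)$root,
                     error = function(e) 0)
    fit <- run(tau2)
  }
  theta <- fit$par
  Om <- Sy + theta^2 * Sx + tau2 * diag(length(by))
  V <- 1 / drop(crossprod(bx, chol_solve(Om, bx)))
  list(theta = theta, se = sqrt(V), tau2 = tau2, objective = fit$value, df = df)
}

#' Principal-component GMM estimator (univariable)
#'
#' Projects the summary statistics and their covariance structure onto the
#' components retained by [weighted_pc_transform], then runs the
#' continuously-updating GMM estimator in component space. Reports the number
#' of components used and a component-space F statistic (the quadratic form
#' of the projected exposure associations against their projected covariance,
#' divided by `r`), which helps judge how varying the number of components
#' affects instrument strength.
#'
#' @param data an [mr_dataset] with a variant correlation matrix.
#' @param nx,ny sample sizes for the exposure and outcome associations
#'   (required).
#' @param opts a [gmm_options] object.
#' @param thres,r passed to [weighted_pc_transform].
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_estimate`; extras include `r`, `eigenvalues`, and `tau2`.
#' @export
mr_pcgmm <- function(data, nx, ny, opts = gmm_options(), thres = 0.999,
                     r = NULL, ci_level = 0.95) {
  stopifnot(inherits(data, "mr_dataset"))
  if (is.null(data$correlation)) stopf("mr_pcgmm requires a variant correlation matrix")
  if (missing(nx) || missing(ny)) stopf("sample sizes `nx` and `ny` are required")
  pc <- weighted_pc_transform(data, thres = thres, r = r)
  pr <- pc_project_uni(data, pc$loadings)
  ivw0 <- mr_ivw(data, model = "fixed")
  fit <- cue_fit_pc_uni(pr$bx, pr$by, pr$Sx, pr$Sy, opts,
                        ivw0$estimate, ivw0$se, df = pc$r - 1L)
  fpc <- drop(crossprod(pr$bx, chol_solve(pr$Sx, pr$bx))) / pc$r
  strength <- structure(list(f_stat = fpc, J = length(data$bx), K = 1L,
                             correlated = TRUE,
                             note = "component-space F statistic"),
                        class = "mr_strength")
  new_mr_estimate(
    "Principal-component GMM", fit$theta, fit$se, ci_level,
    heterogeneity = list(Q = fit$objective, df = fit$df),
    strength = strength,
    options = list(robust = opts$robust, thres = thres, nx = nx, ny = ny),
    J = length(data$bx),
    extra = list(r = pc$r, eigenvalues = pc$eigenvalues, tau2 = fit$tau2))
}

#' Principal-component GMM estimator (multivariable)
#'
#' Multivariable analogue of [mr_pcgmm]: the outcome and every exposure
#' association vector are projected onto the retained components and the
#' multivariable CUE-GMM moments are minimized in component space. The
#' exposure correlation matrix (correlations between exposure association
#' estimates from overlapping samples) defaults to the identity. Conditional
#' F statistics are computed in component space with `r - K + 1` denominator
#' degrees of freedom.
#'
#' @param data an [mr_mvdataset] with a variant correlation matrix.
#' @param nx,ny sample sizes (nx length 1 or K; required).
#' @param opts a [gmm_options] object.
#' @param thres,r passed to [weighted_pc_transform].
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_mvestimate`; extras include `r`, `eigenvalues`, `tau2`.
#' @export
mr_mvpcgmm <- function(data, nx, ny, opts = gmm_options(), thres = 0.999,
                       r = NULL, ci_level = 0.95) {
  stopifnot(inherits(data, "mr_mvdataset"))
  if (is.null(data$correlation)) stopf("mr_mvpcgmm requires a variant correlation matrix")
  if (missing(nx) || missing(ny)) stopf("sample sizes `nx` and `ny` are required")
  K <- ncol(data$BX)
  nx <- broadcast_nx(nx, K)
  pc <- weighted_pc_transform(data, thres = thres, r = r)
  if (pc$r <= K) stopf("retained components (r = %d) must exceed the number of exposures", pc$r)
  W <- pc$loadings
  rho <- data$correlation
  rho_x <- data$exposure_correlation
  bxs <- crossprod(W, data$BX)              # r x K
  bys <- drop(crossprod(W, data$by))
  Sy <- crossprod(W, (rho * (data$byse %o% data$byse)) %*% W)
  # Exposure covariance blocks in component space.
  Sxb <- lapply(seq_len(K), function(k) lapply(seq_len(K), function(l) {
    crossprod(W, (rho * (data$BXse[, k] %o% data$BXse[, l]) * rho_x[k, l]) %*% W)
  }))
  f <- function(theta, tau2) {
    g <- bys - drop(bxs %*% theta)
    Om <- Sy + tau2 * diag(length(g))
    for (k in seq_len(K)) for (l in seq_len(K)) {
      Om <- Om + theta[k] * theta[l] * Sxb[[k]][[l]]
    }
    out <- tryCatch(drop(crossprod(g, chol_solve(Om, g))), error = function(e) Inf)
    if (!is.finite(out)) Inf else out
  }
  ivw0 <- mr_mvivw(data, model = "fixed")
  starts <- cue_starts(ivw0$estimate, ivw0$se, opts$n_starts)
  run <- function(tau2) {
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- stats::optim(starts[s, ], f, tau2 = tau2, method = "BFGS",
                        control = list(reltol = opts$reltol, maxit = opts$maxit))
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }
  df <- pc$r - K
  fit <- run(0); tau2 <- 0
  if (opts$robust && df > 0 && fit$value > df) {
    g2 <- function(t2) run(t2)$value - df
    upper <- stats::median(diag(Sy))
    while (g2(upper) > 0 && upper < 1e6 * stats::median(diag(Sy))) upper <- upper * 4
    tau2 <- tryCatch(stats::uniroot(g2, c(0, upper), tol = 1e-10)$root,
                     error = function(e) 0)
    fit <- run(tau2)
  }
  theta <- fit$par
  Om <- Sy + tau2 * diag(length(bys))
  for (k in seq_len(K)) for (l in seq_len(K)) {
    Om <- Om + theta[k] * theta[l] * Sxb[[k]][[l]]
  }
  V <- solve(crossprod(bxs, chol_solve(Om, bxs)))
  cf <- cond_f_blocks(bxs, Sxb, df_denom = pc$r - K + 1)
  names(cf) <- data$exposures
  strength <- structure(list(conditional_f = cf, J = nrow(data$BX), K = K,
                             note = "component-space conditional F statistics"),
                        class = "mr_strength")
  new_mr_mvestimate(
    "Multivariable principal-component GMM",
    exposures = data$exposures, estimate = theta, se = sqrt(diag(V)),
    ci_level = ci_level,
    heterogeneity = list(Q = fit$value, df = df),
    strength = strength,
    options = list(robust = opts$robust, thres = thres, nx = nx, ny = ny),
    J = nrow(data$BX),
    extra = list(r = pc$r, eigenvalues = pc$eigenvalues, tau2 = tau2))
}
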