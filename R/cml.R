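# Constrained maximum likelihood (cML) estimators. The Gaussian
# log-likelihood of the summary data is maximized subject to a constraint
# that exactly K of the variants carry a free horizontal-pleiotropy term
# ("invalid instruments"); K is selected by BIC, which is asymptotically
# consistent. Model averaging (MA) across K and data perturbation (DP)
# account for selection uncertainty in finite samples and generally widen
# the confidence intervals to an appropriate size.

#' Options for the constrained maximum likelihood estimators
#'
#' @param n scalar sample size used in the BIC penalty (the smaller of the
#'   exposure and outcome association sample sizes is recommended).
#' @param K_range candidate numbers of invalid instruments (default 0..J-2).
#' @param MA model averaging over K with weights proportional to
#'   `exp(-BIC/2)` (default TRUE).
#' @param DP data perturbation: rerun the whole procedure on datasets
#'   re-noised by their standard errors and report the perturbation spread
#'   (default TRUE).
#' @param num_pert perturbation replicates (default 200).
#' @param seed RNG seed for starts and perturbation (default 2020).
#' @param n_starts random effect starts per K (default 10); ties in the
#'   objective are broken towards the smallest `|theta|`.
#' @param reltol convergence tolerance on the relative objective change
#'   (default 1e-7).
#' @param maxit maximum alternating-update iterations (default 100).
#' @return a list of class `cml_options`.
#' @export
cml_options <- function(n, K_range = NULL, MA = TRUE, DP = TRUE,
                        num_pert = 200, seed = 2020, n_starts = 10,
                        reltol = 1e-7, maxit = 100) {
  if (missing(n) || is.null(n) || n <= 0) stopf("a positive sample size `n` is required")
  structure(list(n = n, K_range = K_range, MA = MA, DP = DP,
                 num_pert = num_pert, seed = seed, n_starts = n_starts,
                 reltol = reltol, maxit = maxit),
            class = "cml_options")
}

# Alternating minimization for fixed invalid-count K and starting theta.
# Blocks: (a) support selection given theta (K largest profile costs), (b)
# gamma given theta and support, (c) theta given gamma and support. Every
# block is an exact minimizer, so the objective is non-increasing; this is
# asserted each iteration.
cml_fit_K <- function(bx, bxse, by, byse, K, theta0, reltol, maxit) {
  J <- length(bx)
  theta <- theta0
  obj_prev <- Inf
  invalid <- integer(0)
  for (it in seq_len(maxit)) {
    cost <- (by - theta * bx)^2 / (byse^2 + theta^2 * bxse^2)
    invalid <- if (K > 0) order(cost, decreasing = TRUE)[seq_len(K)] else integer(0)
    valid <- setdiff(seq_len(J), invalid)
    gamma <- numeric(J)
    gamma[valid] <- (bx[valid] / bxse[valid]^2 + theta * by[valid] / byse[valid]^2) /
      (1 / bxse[valid]^2 + theta^2 / byse[valid]^2)
    gamma[invalid] <- bx[invalid]
    denom <- sum(gamma[valid]^2 / byse[valid]^2)
    if (denom <= 0) return(NULL)  # degenerate: no usable valid instruments
    theta <- sum(gamma[valid] * by[valid] / byse[valid]^2) / denom
    obj <- sum((bx[valid] - gamma[valid])^2 / bxse[valid]^2 +
                 (by[valid] - theta * gamma[valid])^2 / byse[valid]^2)
    if (obj > obj_prev + 1e-8) {
      stopf("internal error: cML objective increased (%.6g -> %.6g)", obj_prev, obj)
    }
    if (is.finite(obj_prev) && abs(obj_prev - obj) <= reltol * max(1, abs(obj_prev))) {
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  # Profile objective in theta (gamma and pleiotropy maximized out) for the
  # selected support; used for the curvature-based standard error.
  valid <- setdiff(seq_len(J), invalid)
  h <- function(th) sum((by[valid] - th * bx[valid])^2 /
                          (byse[valid]^2 + th^2 * bxse[valid]^2))
  eps <- 1e-4 * max(1, abs(theta))
  h2 <- (h(theta + eps) - 2 * h(theta) + h(theta - eps)) / eps^2
  se <- if (h2 > 0) sqrt(2 / h2) else NA_real_
  list(theta = theta, se = se, objective = obj_prev, invalid = sort(invalid),
       converged = it < maxit)
}

# Run cML across K_range with multiple random starts; select K by BIC.
cml_core <- function(bx, bxse, by, byse, opts, starts) {
  J <- length(bx)
  K_range <- opts$K_range %||% 0:(J - 2)
  if (max(K_range) > J - 2) stopf("K_range cannot exceed J - 2 = %d", J - 2)
  fits <- list()
  for (K in K_range) {
    best <- NULL
    for (th0 in starts) {
      fit <- cml_fit_K(bx, bxse, by, byse, K, th0, opts$reltol, opts$maxit)
      if (is.null(fit)) next
      if (is.null(best) || fit$objective < best$objective - 1e-10 ||
          (abs(fit$objective - best$objective) <= 1e-10 &&
             abs(fit$theta) < abs(best$theta))) {
        best <- fit
      }
    }
    if (is.null(best)) {
      warnf("cML failed to converge for K = %d; skipping", K)
      next
    }
    best$K <- K
    best$BIC <- best$objective + K * log(opts$n)
    fits[[as.character(K)]] <- best
  }
  if (!length(fits)) stopf("cML failed for every K in K_range")
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  wts <- exp(-(bic - min(bic)) / 2)
  wts <- wts / sum(wts)
  sel <- fits[[which.min(bic)]]
  theta_k <- vapply(fits, `[[`, numeric(1), "theta")
  se_k <- vapply(fits, `[[`, numeric(1), "se")
  theta_ma <- sum(wts * theta_k)
  se_ma <- sum(wts * sqrt(se_k^2 + (theta_k - theta_ma)^2))  # Buckland
  list(selected = sel, fits = fits, bic = bic, weights = wts,
       theta_ma = theta_ma, se_ma = se_ma)
}

#' Constrained maximum likelihood estimator
#'
#' Maximizes the Gaussian likelihood of the summary data while constraining
#' the number of invalid instruments (variants with a free horizontal
#' pleiotropy term) to each candidate `K`, selects `K` by BIC, and optionally
#' performs model averaging (`MA`) and data perturbation (`DP`). Robust to
#' violation of any of the instrumental-variable assumptions in a plurality
#' sense: the valid variants need only form the largest consistent group.
#'
#' @param data an [mr_dataset] with uncorrelated variants and J >= 3.
#' @param opts a [cml_options] object (`n` is required).
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_estimate`; extras include `K_selected`, `invalid`
#'   (IDs of selected invalid instruments), `bic`, `ma_weights`, and the
#'   perturbation spread when `DP = TRUE`.
#' @export
mr_cml <- function(data, opts, ci_level = 0.95) {
  stopifnot(inherits(data, "mr_dataset"), inherits(opts, "cml_options"))
  if (!is.null(data$correlation)) {
    stopf("the constrained maximum likelihood method assumes uncorrelated variants")
  }
  J <- length(data$bx)
  if (J < 3L) stopf("cML needs at least 3 variants")
  bx <- data$bx; bxse <- data$bxse; by <- data$by; byse <- data$byse
  ivw0 <- mr_ivw(data, model = "fixed")
  starts <- with_seed(opts$seed, c(ivw0$estimate,
                                   ivw0$estimate + stats::rnorm(opts$n_starts - 1,
                                                                sd = 2 * max(ivw0$se, 1e-6))))
  core <- cml_core(bx, bxse, by, byse, opts, starts)
  est <- if (opts$MA) core$theta_ma else core$selected$theta
  se <- if (opts$MA) core$se_ma else core$selected$se
  extra <- list(K_selected = core$selected$K,
                invalid = data$snps[core$selected$invalid],
                bic = core$bic, ma_weights = core$weights,
                theta_by_K = vapply(core$fits, `[[`, numeric(1), "theta"),
                seed = opts$seed)
  if (opts$DP) {
    pert <- with_seed(opts$seed + 1L, {
      vapply(seq_len(opts$num_pert), function(b) {
        bx_b <- stats::rnorm(J, bx, bxse)
        by_b <- stats::rnorm(J, by, byse)
        cb <- tryCatch(cml_core(bx_b, bxse, by_b, byse, opts, starts),
                       error = function(e) NULL)
        if (is.null(cb)) return(NA_real_)
        if (opts$MA) cb$theta_ma else cb$selected$theta
      }, numeric(1))
    })
    pert <- pert[is.finite(pert)]
    est <- mean(pert)
    se <- stats::sd(pert)
    extra$num_pert <- length(pert)
  }
  new_mr_estimate(
    sprintf("Constrained maximum likelihood%s%s",
            if (opts$MA) " + model averaging" else "",
            if (opts$DP) " + data perturbation" else ""),
    est, se, ci_level, strength = f_statistic(data),
    options = unclass(opts)[c("n", "MA", "DP", "num_pert")],
    J = J, extra = extra)
}

# ---- multivariable ---------------------------------------------------------

# Profile cost of treating variant j as valid, for effect vector theta:
# (by_j - theta' bx_j)^2 / (byse_j^2 + theta' Sigma_xj theta).
mvcml_costs <- function(theta, BX, byse2, Sx_list, by) {
  pred <- drop(BX %*% theta)
  denom <- byse2 + vapply(Sx_list, function(S) drop(crossprod(theta, S %*% theta)),
                          numeric(1))
  (by - pred)^2 / denom
}

mvcml_fit_K <- function(BX, BXse, by, byse, rho_x, K, theta0, reltol, maxit) {
  J <- nrow(BX); Kx <- ncol(BX)
  Sx_list <- lapply(seq_len(J), function(j) {
    d <- BXse[j, ]
    (d %o% d) * rho_x
  })
  byse2 <- byse^2
  theta <- theta0
  obj_prev <- Inf
  invalid <- integer(0)
  for (it in seq_len(maxit)) {
    cost <- mvcml_costs(theta, BX, byse2, Sx_list, by)
    invalid <- if (K > 0) order(cost, decreasing = TRUE)[seq_len(K)] else integer(0)
    valid <- setdiff(seq_len(J), invalid)
    if (length(valid) <= Kx) return(NULL)
    G <- matrix(0, J, Kx)
    for (j in valid) {
      S <- Sx_list[[j]]
      resid <- by[j] - drop(crossprod(theta, BX[j, ]))
      dn <- byse2[j] + drop(crossprod(theta, S %*% theta))
      G[j, ] <- BX[j, ] + drop(S %*% theta) * resid / dn
    }
    G[invalid, ] <- BX[invalid, , drop = FALSE]
    A <- crossprod(G[valid, , drop = FALSE] / byse[valid])
    bvec <- crossprod(G[valid, , drop = FALSE], by[valid] / byse2[valid])
    theta_new <- tryCatch(drop(solve(A, bvec)), error = function(e) NULL)
    if (is.null(theta_new)) return(NULL)
    theta <- theta_new
    obj <- {
      gv <- G[valid, , drop = FALSE]
      s <- 0
      for (idx in seq_along(valid)) {
        j <- valid[idx]
        d <- BX[j, ] - gv[idx, ]
        s <- s + drop(crossprod(d, chol_solve(Sx_list[[j]], d))) +
          (by[j] - drop(crossprod(theta, gv[idx, ])))^2 / byse2[j]
      }
      s
    }
    if (is.finite(obj_prev) && abs(obj_prev - obj) <= reltol * max(1, abs(obj_prev))) {
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  valid <- setdiff(seq_len(J), invalid)
  h <- function(th) sum(mvcml_costs(th, BX, byse2, Sx_list, by)[valid])
  obj_prof <- h(theta)
  # Numerical Hessian of the profile objective for the covariance.
  eps <- 1e-4 * pmax(1, abs(theta))
  H <- matrix(0, Kx, Kx)
  for (a in seq_len(Kx)) for (b in seq_len(Kx)) {
    ea <- eb <- numeric(Kx); ea[a] <- eps[a]; eb[b] <- eps[b]
    H[a, b] <- (h(theta + ea + eb) - h(theta + ea - eb) -
                  h(theta - ea + eb) + h(theta - ea - eb)) / (4 * eps[a] * eps[b])
  }
  V <- tryCatch(2 * solve(H), error = function(e) matrix(NA_real_, Kx, Kx))
  list(theta = theta, se = sqrt(pmax(diag(V), 0)), objective = obj_prof,
       invalid = sort(invalid))
}

#' Multivariable constrained maximum likelihood estimator
#'
#' Multivariable analogue of [mr_cml]: a vector of causal effects is
#' estimated while exactly `K` variants carry free pleiotropy terms, `K`
#' selected by BIC. The K x K exposure correlation matrix of the dataset
#' (`rho_mat` in the field's usage; identity when the exposure associations
#' come from non-overlapping samples) enters each variant's exposure
#' covariance.
#'
#' @param data an [mr_mvdataset] with uncorrelated variants and J > K
#'   exposures.
#' @param opts a [cml_options] object.
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_mvestimate`; extras as for [mr_cml].
#' @export
mr_mvcml <- function(data, opts, ci_level = 0.95) {
  stopifnot(inherits(data, "mr_mvdataset"), inherits(opts, "cml_options"))
  if (!is.null(data$correlation)) {
    stopf("the constrained maximum likelihood method assumes uncorrelated variants")
  }
  J <- nrow(data$BX); Kx <- ncol(data$BX)
  if (J <= Kx + 1L) stopf("need J > K + 1 variants")
  ivw0 <- mr_mvivw(data, model = "fixed")
  K_range <- opts$K_range %||% 0:(J - Kx - 1)
  start_list <- with_seed(opts$seed, {
    c(list(ivw0$estimate),
      lapply(seq_len(opts$n_starts - 1),
             function(i) ivw0$estimate + stats::rnorm(Kx, sd = 2 * pmax(ivw0$se, 1e-6))))
  })
  run_core <- function(BX, by) {
    fits <- list()
    for (K in K_range) {
      best <- NULL
      for (th0 in start_list) {
        fit <- mvcml_fit_K(BX, data$BXse, by, data$byse,
                           data$exposure_correlation, K, th0,
                           opts$reltol, opts$maxit)
        if (is.null(fit)) next
        if (is.null(best) || fit$objective < best$objective - 1e-10 ||
            (abs(fit$objective - best$objective) <= 1e-10 &&
               sum(fit$theta^2) < sum(best$theta^2))) {
          best <- fit
        }
      }
      if (is.null(best)) { warnf("mvcML failed to converge for K = %d; skipping", K); next }
      best$K <- K
      best$BIC <- best$objective + K * log(opts$n)
      fits[[as.character(K)]] <- best
    }
    if (!length(fits)) stopf("mvcML failed for every K in K_range")
    bic <- vapply(fits, `[[`, numeric(1), "BIC")
    wts <- exp(-(bic - min(bic)) / 2); wts <- wts / sum(wts)
    sel <- fits[[which.min(bic)]]
    theta_k <- do.call(rbind, lapply(fits, `[[`, "theta"))
    se_k <- do.call(rbind, lapply(fits, `[[`, "se"))
    theta_ma <- drop(wts %*% theta_k)
    se_ma <- drop(wts %*% sqrt(se_k^2 + (theta_k - matrix(theta_ma, nrow(theta_k),
                                                          Kx, byrow = TRUE))^2))
    list(selected = sel, bic = bic, weights = wts,
         theta_ma = theta_ma, se_ma = se_ma)
  }
  core <- run_core(data$BX, data$by)
  est <- if (opts$MA) core$theta_ma else core$selected$theta
  se <- if (opts$MA) core$se_ma else core$selected$se
  extra <- list(K_selected = core$selected$K,
                invalid = data$snps[core$selected$invalid],
                bic = core$bic, ma_weights = core$weights, seed = opts$seed)
  if (opts$DP) {
    ch_x <- chol(data$exposure_correlation)
    pert <- with_seed(opts$seed + 1L, {
      out <- matrix(NA_real_, opts$num_pert, Kx)
      for (b in seq_len(opts$num_pert)) {
        E <- matrix(stats::rnorm(J * Kx), J, Kx) %*% ch_x
        BX_b <- data$BX + E * data$BXse
        by_b <- stats::rnorm(J, data$by, data$byse)
        cb <- tryCatch(run_core(BX_b, by_b), error = function(e) NULL)
        if (!is.null(cb)) out[b, ] <- if (opts$MA) cb$theta_ma else cb$selected$theta
      }
      out
    })
    pert <- pert[stats::complete.cases(pert), , drop = FALSE]
    est <- colMeans(pert)
    se <- apply(pert, 2L, stats::sd)
    extra$num_pert <- nrow(pert)
  }
  new_mr_mvestimate(
    sprintf("Multivariable constrained maximum likelihood%s%s",
            if (opts$MA) " + model averaging" else "",
            if (opts$DP) " + data perturbation" else ""),
    exposures = data$exposures, estimate = est, se = se, ci_level = ci_level,
    options = unclass(opts)[c("n", "MA", "DP", "num_pert")],
    J = J, extra = extra)
}
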