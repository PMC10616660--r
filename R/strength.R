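#' First-stage F statistic from summary statistics
#'
#' The first-stage F statistic measures instrument strength: it is roughly
#' the variance in the exposure explained by the variants times the sample
#' size over the number of instruments. From summary statistics it is
#' approximated by the mean chi-square statistic, `mean((bx/bxse)^2)`, since
#' each squared z-statistic approximates n times the per-variant explained
#' variance. When a variant correlation matrix is supplied, correlated
#' variants jointly explain less variance than the sum of their marginal
#' contributions; the same formula is then applied to Cholesky-decorrelated
#' z-scores (the z-scores premultiplied by the inverse lower Cholesky factor
#' of the correlation matrix). Larger F means stronger instruments; values
#' near or below 10 flag potential weak-instrument bias.
#'
#' @param data an [mr_dataset]; if `data$correlation` is present it must be
#'   positive definite.
#' @return a list of class `mr_strength` with `f_stat`, `J`, `K = 1`, and
#'   `correlated` (whether the correlation matrix was used).
#' @examples
#' d <- mr_dataset(bx = 2, bxse = 1, by = 1, byse = 1)
#' f_statistic(d)$f_stat  # 4
#' @export
f_statistic <- function(data) {
  stopifnot(inherits(data, "mr_dataset"))
  z <- data$bx / data$bxse
  correlated <- !is.null(data$correlation)
  if (correlated) z <- cholesky_decorrelate(z, data$correlation)
  structure(list(f_stat = mean(z^2), J = length(z), K = 1L,
                 correlated = correlated,
                 note = "mean chi-square approximation to the first-stage F"),
            class = "mr_strength")
}

#' @export
print.mr_strength <- function(x, ...) {
  if (!is.null(x$f_stat)) cat(sprintf("F statistic = %.1f\n", x$f_stat))
  if (!is.null(x$conditional_f)) {
    cat("Conditional F statistics:\n")
    print(round(x$conditional_f, 1))
  }
  invisible(x)
}

# Conditional instrument-strength engine on "blocks" form. B is an M x K
# matrix of (possibly transformed) exposure associations; cov_blocks[[k]][[l]]
# is the M x M covariance block between columns k and l of B. For exposure k
# the statistic is the minimized generalized heterogeneity
#   Q_k = min_delta (B_k - B_{-k} delta)' V(delta)^{-1} (B_k - B_{-k} delta),
# with V(delta) the covariance of the residual contrast, and the conditional
# F statistic is Q_k / df_denom (df_denom = M - K + 1).
cond_f_blocks <- function(B, cov_blocks, df_denom) {
  M <- nrow(B); K <- ncol(B)
  sapply(seq_len(K), function(k) {
    others <- setdiff(seq_len(K), k)
    a <- B[, k]
    X <- B[, others, drop = FALSE]
    Vfun <- function(delta) {
      V <- cov_blocks[[k]][[k]]
      for (i in seq_along(others)) {
        l <- others[i]
        V <- V - delta[i] * (cov_blocks[[k]][[l]] + cov_blocks[[l]][[k]])
        for (jj in seq_along(others)) {
          m <- others[jj]
          V <- V + delta[i] * delta[jj] * cov_blocks[[l]][[m]]
        }
      }
      V
    }
    Qfun <- function(delta) {
      r <- a - drop(X %*% delta)
      V <- Vfun(delta)
      out <- tryCatch(drop(crossprod(r, chol_solve(V, r))),
                      error = function(e) Inf)
      if (!is.finite(out)) Inf else out
    }
    delta0 <- tryCatch(qr.coef(qr(X), a), error = function(e) rep(0, ncol(X)))
    delta0[!is.finite(delta0)] <- 0
    opt <- stats::optim(delta0, Qfun, method = if (length(delta0) == 1L) "Brent" else "BFGS",
                        lower = if (length(delta0) == 1L) delta0 - 10 else -Inf,
                        upper = if (length(delta0) == 1L) delta0 + 10 else Inf)
    opt$value / df_denom
  })
}

#' Conditional F statistics for multivariable instruments
#'
#' In multivariable Mendelian randomization the relevant strength measure for
#' each exposure is not its univariable F statistic but the conditional F
#' statistic: the independent explained variance after accounting for the
#' genetic associations with the other exposures. If one exposure's
#' associations are (near-)collinear with another's, its effect is not
#' identified and the conditional F collapses towards zero even when the
#' univariable F is large.
#'
#' The statistic is computed from standardized associations: each column of
#' z-statistics is scaled by `1/sqrt(nx_k)` so associations are on a common
#' per-sample scale with known variance `1/nx_k` (this is where the exposure
#' sample sizes enter; they are required). For each exposure the standardized
#' column is regressed on the others by generalized least squares whose
#' residual variance accounts for the regression coefficients and the
#' exposure correlation matrix, and the minimized heterogeneity statistic is
#' divided by `J - K + 1` degrees of freedom. With a single exposure this
#' reduces exactly to [f_statistic].
#'
#' @param data an [mr_mvdataset] with uncorrelated variants.
#' @param nx per-exposure sample sizes (single value broadcast to all).
#' @return a list of class `mr_strength` with `conditional_f` (named per
#'   exposure), `J`, and `K`.
#' @export
conditional_f_statistics <- function(data, nx) {
  stopifnot(inherits(data, "mr_mvdataset"))
  J <- nrow(data$BX); K <- ncol(data$BX)
  nx <- broadcast_nx(nx, K)
  if (K == 1L) {
    out <- f_statistic(as_univariable(data))
    out$conditional_f <- stats::setNames(out$f_stat, data$exposures)
    return(out)
  }
  if (J <= K) stopf("conditional F needs more variants than exposures (J = %d, K = %d)", J, K)
  Bstd <- sweep(data$BX / data$BXse, 2L, sqrt(nx), "/")
  rho_x <- data$exposure_correlation
  cov_blocks <- lapply(seq_len(K), function(k) {
    lapply(seq_len(K), function(l) {
      diag(rep(rho_x[k, l] / sqrt(nx[k] * nx[l]), J))
    })
  })
  cf <- cond_f_blocks(Bstd, cov_blocks, df_denom = J - K + 1)
  names(cf) <- data$exposures
  weak <- cf < 1e-6
  if (any(weak)) {
    warnf("conditional F near zero for %s: exposure associations are collinear, effect not identified",
          paste(data$exposures[weak], collapse = ", "))
  }
  structure(list(conditional_f = cf, J = J, K = K,
                 note = "GLS conditional instrument-strength statistic, df = J - K + 1"),
            class = "mr_strength")
}
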