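#' Harmonize a signed correlation matrix to the effect alleles
#'
#' A variant correlation matrix computed with different effect alleles than
#' the association estimates must be re-oriented before use: for every variant
#' whose alleles are swapped relative to the summary statistics, the signs of
#' its row and column are flipped. With a flip vector `f` of +1/-1 entries the
#' harmonized matrix is `rho * f %o% f`, i.e. entry (i, j) becomes
#' `f[i] * f[j] * rho[i, j]`. The diagonal is unchanged and an entry whose two
#' variants both flip keeps its sign (double flip cancels). Failing to
#' harmonize the matrix can produce erroneous causal estimates.
#'
#' @param rho signed variant correlation matrix.
#' @param flip numeric vector of +1/-1 entries, one per variant in matrix
#'   order; +1 = alleles already aligned, -1 = alleles swapped.
#' @return the harmonized correlation matrix.
#' @examples
#' fx <- casr_fixtures()
#' harmonized <- flip_correlation(fx$rho, fx$flip)
#' harmonized[1, 3]  # -0.094: single flip changes sign
#' harmonized[3, 5]  #  0.349: double flip cancels
#' @export
flip_correlation <- function(rho, flip) {
  rho <- validate_correlation(rho, warn_unsigned = FALSE)
  if (length(flip) != nrow(rho)) stopf("flip vector length != matrix dimension")
  if (!all(flip %in% c(-1, 1))) stopf("flip entries must be +1 or -1")
  out <- rho * (flip %o% flip)
  dimnames(out) <- dimnames(rho)
  out
}

#' Prune highly correlated variants at an r-squared threshold
#'
#' Extremely highly correlated variants contribute little information and can
#' destabilize correlated-variant analyses. This routine repeatedly finds the
#' largest remaining absolute correlation in the upper triangle and, while it
#' exceeds `sqrt(r2_threshold)`, removes one member of the offending pair at
#' random (a fair coin from a seeded RNG: success removes the row-index
#' variant of the maximal entry, failure the column-index variant), zeroing
#' that variant's row and column. It stops when no pair exceeds the threshold,
#' so all surviving pairwise squared correlations are at most `r2_threshold`.
#' Ties at the same maximum are broken by first occurrence in row-major scan
#' order. The result is deterministic given the seed.
#'
#' @param rho signed variant correlation matrix.
#' @param r2_threshold squared-correlation threshold in (0, 1] (default 0.95).
#' @param seed integer RNG seed (default 496).
#' @return a list of class `mr_prune` with `kept_ids`, `omitted_ids`,
#'   `kept`, `omitted` (indices), `r2_threshold`, and `seed`.
#' @export
prune_by_r2 <- function(rho, r2_threshold = 0.95, seed = 496) {
  rho <- validate_correlation(rho, warn_unsigned = FALSE)
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold <= 0 || r2_threshold > 1) {
    stopf("r2_threshold must lie in (0, 1]")
  }
  thres <- sqrt(r2_threshold)
  ids <- rownames(rho) %||% paste0("snp_", seq_len(nrow(rho)))
  upper <- abs(rho)
  upper[lower.tri(upper, diag = TRUE)] <- 0
  omit <- integer(0)
  with_seed(seed, {
    while (nrow(upper) > 0 && max(upper) > thres) {
      idx <- if (stats::rbinom(1L, 1L, 0.5) == 1L) {
        which.max(apply(upper, 1L, max))  # row index of the maximal pair
      } else {
        which.max(apply(upper, 2L, max))  # column index of the maximal pair
      }
      omit <- c(omit, idx)
      upper[idx, ] <- 0
      upper[, idx] <- 0
    }
  })
  omit <- unname(omit)
  kept <- setdiff(seq_len(nrow(rho)), omit)
  structure(list(kept_ids = ids[kept], omitted_ids = ids[omit],
                 kept = kept, omitted = omit,
                 r2_threshold = r2_threshold, seed = seed),
            class = "mr_prune")
}

#' @export
print.mr_prune <- function(x, ...) {
  cat(sprintf("Pruning at r^2 > %g (seed %d): kept %d, omitted %d variant(s)\n",
              x$r2_threshold, x$seed, length(x$kept), length(x$omitted)))
  if (length(x$omitted)) cat("omitted:", paste(x$omitted_ids, collapse = ", "), "\n")
  invisible(x)
}

# Lower Cholesky factor of rho, with a single 1e-10 ridge retry when rho is
# numerically singular; errors if still not positive definite.
chol_lower <- function(rho) {
  U <- tryCatch(chol(rho), error = function(e) NULL)
  if (is.null(U)) {
    U <- tryCatch(chol(rho + 1e-10 * diag(nrow(rho))), error = function(e) NULL)
    if (is.null(U)) stopf("correlation matrix is singular (not PD even after 1e-10 ridge)")
  }
  t(U)
}

#' Decorrelate per-variant statistics with the Cholesky transform
#'
#' Returns `solve(L, z)` where `L` is the lower Cholesky factor of the
#' correlation matrix, so that the decorrelated statistics satisfy
#' `sum(z_star^2) == t(z) %*% solve(rho) %*% z`. Used to extend
#' mean-chi-square instrument-strength statistics to correlated variants.
#'
#' @param z numeric vector of per-variant statistics (e.g. z-scores).
#' @param rho signed variant correlation matrix (positive definite; a one-off
#'   1e-10 ridge is applied if numerically singular).
#' @return numeric vector of decorrelated statistics.
#' @export
cholesky_decorrelate <- function(z, rho) {
  rho <- validate_correlation(rho, warn_unsigned = FALSE)
  if (length(z) != nrow(rho)) stopf("length(z) != matrix dimension")
  L <- chol_lower(rho)
  drop(forwardsolve(L, z))
}
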