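#' Validate a signed variant correlation matrix
#'
#' Checks that a matrix is a valid signed correlation matrix between genetic
#' variant association estimates: square, symmetric (within 1e-10), unit
#' diagonal, entries in \[-1, 1\], and positive semi-definite up to a small
#' numerical tolerance on the smallest eigenvalue (empirical linkage
#' disequilibrium matrices are often near-PSD). Many LD tools report the
#' squared-correlation (r^2) matrix; Mendelian randomization requires the
#' signed correlation matrix, so a matrix whose off-diagonal entries are all
#' non-negative triggers a diagnostic warning as a likely unsigned or r^2
#' matrix.
#'
#' @param mat square numeric matrix, optionally with variant IDs as
#'   dimnames.
#' @param ids optional character vector of variant IDs; defaults to the
#'   matrix rownames.
#' @param min_eigen most negative smallest eigenvalue tolerated
#'   (default -1e-8); anything more negative is a hard error.
#' @param warn_unsigned emit the possible-r^2-matrix warning (default TRUE);
#'   internal re-validations disable it to avoid repeating the diagnostic.
#' @return the validated matrix (invisibly unchanged apart from dimnames set
#'   from `ids`).
#' @examples
#' validate_correlation(diag(3))
#' @export
validate_correlation <- function(mat, ids = NULL, min_eigen = -1e-8,
                                 warn_unsigned = TRUE) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stopf("correlation must be a numeric matrix")
  }
  if (nrow(mat) != ncol(mat)) stopf("correlation matrix must be square")
  ids <- ids %||% rownames(mat)
  if (!is.null(ids)) {
    if (length(ids) != nrow(mat)) stopf("correlation ids length != dimension")
    dimnames(mat) <- list(ids, ids)
  }
  if (anyNA(mat)) stopf("correlation matrix contains missing values")
  if (max(abs(mat - t(mat))) > 1e-10) {
    stopf("correlation matrix is not symmetric (tolerance 1e-10)")
  }
  if (any(abs(diag(mat) - 1) > 1e-12)) {
    stopf("correlation matrix diagonal must be exactly 1")
  }
  if (any(abs(mat) > 1 + 1e-12)) {
    stopf("correlation entries must lie in [-1, 1]")
  }
  ev_min <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < min_eigen) {
    stopf("correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
          ev_min)
  }
  off <- mat[upper.tri(mat)]
  if (warn_unsigned && length(off) && all(off >= 0) && any(off > 0)) {
    warnf(paste("all off-diagonal correlations are non-negative;",
                "this may be an unsigned or squared-correlation (r^2) matrix.",
                "Signed correlations are required."))
  }
  mat
}

# Reorder a correlation matrix so rows/columns follow `ids`; matching is by
# variant ID when dimnames are available, positional otherwise.
align_correlation <- function(mat, ids) {
  if (is.null(rownames(mat))) {
    if (nrow(mat) != length(ids)) {
      stopf("correlation matrix dimension (%d) != number of variants (%d) and no IDs to match on",
            nrow(mat), length(ids))
    }
    dimnames(mat) <- list(ids, ids)
    return(mat)
  }
  missing <- setdiff(ids, rownames(mat))
  if (length(missing)) {
    stopf("correlation matrix lacks variants: %s", paste(missing, collapse = ", "))
  }
  mat[ids, ids, drop = FALSE]
}
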