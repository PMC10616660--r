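#' Construct a univariable summarized-data MR dataset
#'
#' Bundles per-variant summary statistics for one exposure and one outcome:
#' the beta coefficient and standard error of the variant-exposure association
#' (`bx`, `bxse`) and of the variant-outcome association (`by`, `byse`), all
#' oriented to the same effect alleles. An optional signed variant correlation
#' matrix captures linkage disequilibrium between the association estimates;
#' absence means the variants are treated as uncorrelated.
#'
#' @param bx,bxse numeric vectors: variant-exposure associations and their
#'   standard errors (exposure units per effect allele; SEs strictly positive).
#' @param by,byse numeric vectors: variant-outcome associations and SEs.
#' @param snps character vector of variant IDs (defaults to snp_1, snp_2, ...).
#' @param correlation optional signed correlation matrix over the same
#'   variants; reordered to match `snps` by ID when dimnames are present.
#' @return an object of class `mr_dataset`.
#' @examples
#' d <- mr_dataset(bx = c(0.1, 0.2), bxse = c(0.02, 0.03),
#'                 by = c(0.05, 0.11), byse = c(0.01, 0.02))
#' @export
mr_dataset <- function(bx, bxse, by, byse, snps = NULL, correlation = NULL) {
  J <- length(bx)
  if (J < 1L) stopf("at least one variant is required")
  snps <- snps %||% paste0("snp_", seq_len(J))
  fields <- list(snps = snps, bx = bx, bxse = bxse, by = by, byse = byse)
  len <- vapply(fields, length, 1L)
  if (any(len != J)) stopf("per-variant fields have unequal lengths")
  if (anyNA(bx) || anyNA(bxse) || anyNA(by) || anyNA(byse)) {
    stopf("missing values are not allowed in summary statistics")
  }
  if (anyDuplicated(snps)) stopf("duplicate variant IDs")
  if (any(bxse <= 0) || any(byse <= 0)) stopf("standard errors must be strictly positive")
  if (!is.null(correlation)) {
    correlation <- align_correlation(correlation, snps)
    correlation <- validate_correlation(correlation, warn_unsigned = FALSE)
  }
  structure(
    list(snps = as.character(snps), bx = as.numeric(bx), bxse = as.numeric(bxse),
         by = as.numeric(by), byse = as.numeric(byse), correlation = correlation),
    class = "mr_dataset")
}

#' Construct a multivariable summarized-data MR dataset
#'
#' Holds a J x K matrix of variant-exposure associations (`BX`) with matching
#' standard errors (`BXse`), variant-outcome associations, an optional variant
#' correlation matrix (linkage disequilibrium between variants), and an
#' optional K x K exposure correlation matrix describing correlations between
#' the exposure association *estimates* that arise when they were obtained in
#' overlapping samples. When absent, the exposure correlation defaults to the
#' identity (non-overlapping samples).
#'
#' @param BX,BXse numeric J x K matrices of exposure associations and SEs.
#' @param by,byse numeric vectors of outcome associations and SEs.
#' @param snps optional variant IDs.
#' @param exposures optional exposure labels (default exposure_1, ...).
#' @param correlation optional signed variant correlation matrix.
#' @param exposure_correlation optional K x K symmetric unit-diagonal matrix.
#' @return an object of class `mr_mvdataset`.
#' @export
mr_mvdataset <- function(BX, BXse, by, byse, snps = NULL, exposures = NULL,
                         correlation = NULL, exposure_correlation = NULL) {
  BX <- as.matrix(BX); BXse <- as.matrix(BXse)
  J <- nrow(BX); K <- ncol(BX)
  if (!all(dim(BX) == dim(BXse))) stopf("BX and BXse must have the same shape")
  if (length(by) != J || length(byse) != J) stopf("outcome vectors must have one entry per variant")
  if (anyNA(BX) || anyNA(BXse) || anyNA(by) || anyNA(byse)) {
    stopf("missing values are not allowed in summary statistics")
  }
  if (any(BXse <= 0) || any(byse <= 0)) stopf("standard errors must be strictly positive")
  snps <- snps %||% rownames(BX) %||% paste0("snp_", seq_len(J))
  if (anyDuplicated(snps)) stopf("duplicate variant IDs")
  exposures <- exposures %||% colnames(BX) %||% paste0("exposure_", seq_len(K))
  dimnames(BX) <- dimnames(BXse) <- list(snps, exposures)
  if (!is.null(correlation)) {
    correlation <- align_correlation(correlation, snps)
    correlation <- validate_correlation(correlation, warn_unsigned = FALSE)
  }
  if (is.null(exposure_correlation)) {
    exposure_correlation <- diag(K)
    dimnames(exposure_correlation) <- list(exposures, exposures)
  } else {
    exposure_correlation <- as.matrix(exposure_correlation)
    if (!all(dim(exposure_correlation) == K)) {
      stopf("exposure_correlation must be %d x %d", K, K)
    }
    exposure_correlation <- validate_correlation(exposure_correlation, ids = exposures)
  }
  structure(
    list(snps = as.character(snps), exposures = as.character(exposures),
         BX = BX, BXse = BXse, by = as.numeric(by), byse = as.numeric(byse),
         correlation = correlation, exposure_correlation = exposure_correlation),
    class = "mr_mvdataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("Univariable MR dataset: %d variants, correlation matrix %s\n",
              length(x$snps), if (is.null(x$correlation)) "absent" else "present"))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
print.mr_mvdataset <- function(x, ...) {
  cat(sprintf("Multivariable MR dataset: %d variants, %d exposures (%s)\n",
              length(x$snps), length(x$exposures),
              paste(x$exposures, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.mr_dataset <- function(x, ...) {
  data.frame(snp = x$snps, bx = x$bx, bxse = x$bxse, by = x$by, byse = x$byse,
             stringsAsFactors = FALSE)
}

#' Convert a single-exposure multivariable dataset to univariable form
#'
#' A K = 1 multivariable dataset carries exactly the information of a
#' univariable one; this embedding is lossless.
#'
#' @param data an `mr_mvdataset` with one exposure.
#' @return an `mr_dataset`.
#' @export
as_univariable <- function(data) {
  stopifnot(inherits(data, "mr_mvdataset"))
  if (ncol(data$BX) != 1L) stopf("dataset has %d exposures; need exactly 1", ncol(data$BX))
  mr_dataset(bx = data$BX[, 1L], bxse = data$BXse[, 1L], by = data$by,
             byse = data$byse, snps = data$snps, correlation = data$correlation)
}

#' Sample sizes for summarized genetic associations
#'
#' @param nx per-exposure sample size(s) for the exposure associations; a
#'   single value is broadcast to all exposures.
#' @param ny sample size for the outcome associations.
#' @param n a single scalar sample size (used by the constrained maximum
#'   likelihood BIC); when exposure and outcome sample sizes differ the
#'   smaller is recommended.
#' @return an object of class `mr_samplesizes`.
#' @export
mr_samplesizes <- function(nx = NULL, ny = NULL, n = NULL) {
  chk <- function(v, nm) {
    if (!is.null(v)) {
      if (any(v <= 0) || any(v != round(v))) stopf("`%s` must be positive integer(s)", nm)
    }
    v
  }
  structure(list(nx = chk(nx, "nx"), ny = chk(ny, "ny"), n = chk(n, "n")),
            class = "mr_samplesizes")
}

# Broadcast nx to K exposures.
broadcast_nx <- function(nx, K) {
  if (is.null(nx)) stopf("exposure sample sizes `nx` are required")
  if (length(nx) == 1L) nx <- rep(nx, K)
  if (length(nx) != K) stopf("`nx` must have length 1 or %d", K)
  nx
}
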