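# Delimited-file readers and writers for summarized association data and
# correlation matrices. Association tables are CSV/TSV with a header;
# correlation matrices are square CSV/TSV with a variant-ID header row and an
# ID first column. Delimiter is inferred from the file extension (.tsv/.txt
# use tab) unless given.

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_checked <- function(path, sep) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a univariable summarized-data file
#'
#' Expects header columns `snp, bx, bxse, by, byse` (names remappable through
#' `columns`). An optional correlation-matrix file is aligned to the
#' association rows by variant ID.
#'
#' @param assoc_path path to the association table (CSV/TSV with header).
#' @param corr_path optional path to a square signed correlation matrix with
#'   variant-ID header row and ID first column.
#' @param columns named character vector remapping canonical names to the
#'   file's column names, e.g. `c(bx = "beta.exposure")`.
#' @param sep field separator; inferred from the extension when NULL.
#' @return an [mr_dataset].
#' @export
read_univariable <- function(assoc_path, corr_path = NULL, columns = NULL,
                             sep = NULL) {
  sep <- infer_sep(assoc_path, sep)
  tab <- read_table_checked(assoc_path, sep)
  nm <- c(snp = "snp", bx = "bx", bxse = "bxse", by = "by", byse = "byse")
  if (!is.null(columns)) nm[names(columns)] <- columns
  missing <- setdiff(nm, names(tab))
  if (length(missing)) stopf("missing columns in %s: %s", assoc_path,
                             paste(missing, collapse = ", "))
  corr <- if (!is.null(corr_path)) read_correlation(corr_path) else NULL
  mr_dataset(bx = tab[[nm["bx"]]], bxse = tab[[nm["bxse"]]],
             by = tab[[nm["by"]]], byse = tab[[nm["byse"]]],
             snps = as.character(tab[[nm["snp"]]]), correlation = corr)
}

#' Read a multivariable summarized-data file
#'
#' Expects header columns `snp`, `bx_<name>` and `bxse_<name>` for each
#' exposure, and `by`, `byse`. Exposures appear in file column order.
#'
#' @inheritParams read_univariable
#' @param exposure_corr_path optional path to a K x K exposure correlation
#'   matrix; absent means identity (non-overlapping exposure samples).
#' @return an [mr_mvdataset].
#' @export
read_multivariable <- function(assoc_path, corr_path = NULL,
                               exposure_corr_path = NULL, sep = NULL) {
  sep <- infer_sep(assoc_path, sep)
  tab <- read_table_checked(assoc_path, sep)
  for (col in c("snp", "by", "byse")) {
    if (!col %in% names(tab)) stopf("missing column `%s` in %s", col, assoc_path)
  }
  bx_cols <- grep("^bx_", names(tab), value = TRUE)
  exposures <- sub("^bx_", "", bx_cols)
  se_cols <- paste0("bxse_", exposures)
  if (!length(bx_cols)) stopf("no `bx_<exposure>` columns found in %s", assoc_path)
  if (!all(se_cols %in% names(tab))) {
    stopf("ragged exposure columns: every bx_<name> needs a matching bxse_<name>")
  }
  corr <- if (!is.null(corr_path)) read_correlation(corr_path) else NULL
  ecorr <- if (!is.null(exposure_corr_path)) {
    m <- as.matrix(read_table_checked(exposure_corr_path, infer_sep(exposure_corr_path, sep))[, -1])
    m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = list(exposures, exposures))
    m
  } else NULL
  mr_mvdataset(BX = as.matrix(tab[, bx_cols, drop = FALSE]),
               BXse = as.matrix(tab[, se_cols, drop = FALSE]),
               by = tab$by, byse = tab$byse,
               snps = as.character(tab$snp), exposures = exposures,
               correlation = corr, exposure_correlation = ecorr)
}

#' Read a square signed correlation matrix
#'
#' @param path CSV/TSV with a variant-ID header row and ID first column.
#' @param sep field separator; inferred from extension when NULL.
#' @return validated numeric matrix with variant IDs as dimnames.
#' @export
read_correlation <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  tab <- read_table_checked(path, sep)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m)) stopf("correlation matrix in %s is not square", path)
  if (!identical(ids, colnames(m))) {
    stopf("correlation row IDs do not match column header in %s", path)
  }
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = list(ids, ids))
  validate_correlation(m)
}

#' Write a univariable dataset to a delimited file
#'
#' Inverse of [read_univariable] for the association table; field values
#' round-trip exactly for finite decimal inputs.
#'
#' @param data an [mr_dataset].
#' @param path output file path.
#' @param sep field separator; inferred from extension when NULL.
#' @return `path`, invisibly.
#' @export
write_univariable <- function(data, path, sep = NULL) {
  stopifnot(inherits(data, "mr_dataset"))
  sep <- infer_sep(path, sep)
  utils::write.table(format(as.data.frame(data), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a correlation matrix to a delimited file
#'
#' @param mat square correlation matrix with variant-ID dimnames.
#' @param path output file path.
#' @param sep field separator; inferred from extension when NULL.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(mat, path, sep = NULL) {
  sep <- infer_sep(path, sep)
  df <- data.frame(snp = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
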