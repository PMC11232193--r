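#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values must be finite numbers
#' (RNA-seq expression in any non-negative unit); missing or non-numeric
#' entries are rejected — imputation, if needed, must happen upstream because
#' the partial-correlation model has no missing-data semantics.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    psnet_error(sprintf("expression file %s needs a gene column plus samples", path),
                "psnet_parse_error")
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_expression(mat, where = path)
  mat
}

validate_expression <- function(mat, where = "expression matrix") {
  if (is.null(rownames(mat)) || is.null(colnames(mat)) ||
      any(!nzchar(rownames(mat))) || any(!nzchar(colnames(mat))))
    psnet_error(sprintf("%s: missing gene or sample identifiers", where),
                "psnet_validate_error")
  if (anyDuplicated(rownames(mat)))
    psnet_error(sprintf("%s: duplicated gene identifiers (e.g. %s)", where,
                        rownames(mat)[duplicated(rownames(mat))][1L]),
                "psnet_validate_error")
  if (anyDuplicated(colnames(mat)))
    psnet_error(sprintf("%s: duplicated sample identifiers", where),
                "psnet_validate_error")
  if (any(!is.finite(mat)))
    psnet_error(sprintf("%s: non-finite or missing values; impute upstream", where),
                "psnet_validate_error")
  invisible(mat)
}

#' Write an expression matrix to TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_column name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample class labels
#'
#' Two-column TSV `sample_id<TAB>class` with class in `normal`/`tumor`.
#'
#' @param path path to the TSV file (no header, or a header line with
#'   non-class labels which is dropped).
#' @return named character vector of `"normal"`/`"tumor"`, names = sample ids.
#' @export
read_sample_class <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    psnet_error("sample class file must have two tab-separated columns",
                "psnet_parse_error")
  if (!df[1L, 2L] %in% c("normal", "tumor")) df <- df[-1L, , drop = FALSE]
  cls <- trimws(df[[2L]])
  if (!all(cls %in% c("normal", "tumor")))
    psnet_error("sample classes must be 'normal' or 'tumor'",
                "psnet_parse_error")
  setNames(cls, trimws(df[[1L]]))
}

#' Read a clinical survival table
#'
#' Tab-separated file with columns `sample_id`, `time` (days) and `event`
#' (1 = death observed, 0 = censored); a header line is required.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    psnet_error("clinical file needs columns sample_id, time, event",
                "psnet_parse_error")
  df <- df[need]
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  if (any(!is.finite(df$time)) || any(df$time < 0))
    psnet_error("survival times must be finite and non-negative",
                "psnet_validate_error")
  if (!all(df$event %in% c(0L, 1L)))
    psnet_error("event indicator must be 0 (censored) or 1 (death)",
                "psnet_validate_error")
  df
}
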