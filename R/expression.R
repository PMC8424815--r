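#' Construct an expression matrix
#'
#' Features x samples abundance table carrying a condition label per sample
#' and a unit tag.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   dimnames required; no negative entries.
#' @param condition named character vector mapping every sample id to
#'   `"control"` or `"treated"`.
#' @param unit `"count"`, `"RPKM"` or `"TPM"`.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, condition, unit = c("count", "RPKM", "TPM")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("negative expression value")
  miss <- setdiff(colnames(values), names(condition))
  if (length(miss)) stop("sample without condition label: ", miss[1])
  condition <- condition[colnames(values)]
  if (!all(condition %in% c("control", "treated")))
    stop("condition labels must be 'control' or 'treated'")
  if (any(table(factor(condition, c("control", "treated"))) < 2L))
    stop("need at least 2 samples per condition")
  structure(list(values = values, condition = condition, unit = unit),
            class = "expression_matrix")
}

#' Read an expression matrix from TSV
#'
#' First column feature id, remaining columns samples, header row mandatory.
#' Tab-separated, `.` decimal, no quoting.
#'
#' @param path TSV file.
#' @param condition_map named character vector sample id -> condition.
#' @param unit unit tag for the stored values.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, condition_map, unit = "count") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  ncol_expect <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  ncols <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(ncols != ncol_expect))
    stop("ragged row at line ", which(ncols != ncol_expect)[1])
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression value")
  rownames(m) <- as.character(tab[[1]])
  if (any(m < 0)) stop("negative expression value in ", path)
  expression_matrix(m, condition_map, unit = unit)
}

#' Write an expression matrix to TSV
#' @param expr an `expression_matrix`.
#' @param path output file.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                   table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}
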