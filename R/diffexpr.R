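#' RPKM normalisation
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (column_total * length)`.
#'
#' @param counts `expression_matrix` of unit `"count"`.
#' @param lengths named numeric vector, feature -> length in bp.
#' @return `expression_matrix` of unit `"RPKM"`.
#' @export
rpkm <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count") stop("rpkm() expects counts")
  v <- counts$values
  miss <- setdiff(rownames(v), names(lengths))
  if (length(miss)) stop("missing length for feature: ", miss[1])
  len <- lengths[rownames(v)]
  if (any(len <= 0)) stop("non-positive feature length")
  tot <- colSums(v)
  if (any(tot == 0)) stop("zero column total in sample: ",
                          colnames(v)[tot == 0][1])
  out <- sweep(v, 2, tot, "/") * 1e9 / len
  expression_matrix(out, counts$condition, unit = "RPKM")
}

#' TPM normalisation
#'
#' Transcripts per million: length-normalised rates rescaled so every sample
#' column sums to 1e6.
#'
#' @inheritParams rpkm
#' @return `expression_matrix` of unit `"TPM"`.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$unit != "count") stop("tpm() expects counts")
  v <- counts$values
  miss <- setdiff(rownames(v), names(lengths))
  if (length(miss)) stop("missing length for feature: ", miss[1])
  len <- lengths[rownames(v)]
  if (any(len <= 0)) stop("non-positive feature length")
  rate <- v / len
  tot <- colSums(rate)
  if (any(tot == 0)) stop("zero column total in sample: ",
                          colnames(v)[tot == 0][1])
  out <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(out, counts$condition, unit = "TPM")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in `[0, 1]`.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Welch two-sample t-test on a matrix of log-scale values, by row.
# Handles the degenerate zero-variance case (constant groups): p = 0 when the
# means differ, p = 1 when they coincide.
welch_rows <- function(m, grp1, grp2) {
  n1 <- length(grp1); n2 <- length(grp2)
  x1 <- m[, grp1, drop = FALSE]; x2 <- m[, grp2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

#' Differential expression between conditions
#'
#' For each feature, the fold change is
#' `log2((mean_treated + pseudo) / (mean_control + pseudo))` on the abundance
#' scale, the p-value comes from a two-sided Welch t-test on
#' `log2(value + pseudo)`, and adjusted p-values are Benjamini-Hochberg over
#' all tested features. Status is `up` when `log2fc > 1 & padj < 0.05`,
#' `down` when `log2fc < -1 & padj < 0.05`, else `ns`.
#'
#' @param expr `expression_matrix` with at least 2 samples per condition.
#' @param pseudo pseudo-count added before logging (default 1).
#' @param log2fc_min log2 fold-change cutoff (default 1).
#' @param padj_max adjusted p-value cutoff (default 0.05).
#' @return data frame: feature_id, mean_control, mean_treated, log2fc,
#'   pvalue, padj, status.
#' @export
differential_expression <- function(expr, pseudo = 1.0,
                                    log2fc_min = 1.0, padj_max = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  ctrl <- which(expr$condition == "control")
  trt <- which(expr$condition == "treated")
  if (length(ctrl) < 2L || length(trt) < 2L)
    stop("need at least 2 samples per condition")
  v <- expr$values
  mc <- rowMeans(v[, ctrl, drop = FALSE])
  mt <- rowMeans(v[, trt, drop = FALSE])
  l2fc <- log2((mt + pseudo) / (mc + pseudo))
  p <- welch_rows(log2(v + pseudo), ctrl, trt)
  padj <- bh_adjust(p)
  status <- ifelse(padj < padj_max & l2fc > log2fc_min, "up",
                   ifelse(padj < padj_max & l2fc < -log2fc_min, "down", "ns"))
  data.frame(feature_id = rownames(v), mean_control = mc, mean_treated = mt,
             log2fc = l2fc, pvalue = p, padj = padj, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}
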