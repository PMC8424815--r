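#' Pearson correlation with significance
#'
#' Sample Pearson coefficient with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Perfect correlation (`|r| = 1`) yields p = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return list with `r`, `pvalue`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  r <- stats::cor(x, y)
  list(r = r, pvalue = cor_pvalue(r, n), n = n)
}

cor_pvalue <- function(r, n) {
  p <- numeric(length(r))
  perfect <- abs(r) >= 1 - 1e-15
  p[perfect] <- 0
  ok <- !perfect
  tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  p
}

# all-pairs correlation between two feature blocks of an expression matrix,
# returned as long-format data frame
cor_pairs <- function(expr, ids_a, ids_b) {
  va <- t(expr$values[ids_a, , drop = FALSE])
  vb <- t(expr$values[ids_b, , drop = FALSE])
  n <- nrow(va)
  r <- suppressWarnings(stats::cor(va, vb))
  data.frame(id_a = rep(ids_a, times = length(ids_b)),
             id_b = rep(ids_b, each = length(ids_a)),
             r = as.vector(r),
             pvalue = cor_pvalue(as.vector(r), n),
             n = n, stringsAsFactors = FALSE)
}

#' Co-expression-supported miRNA-target interactions
#'
#' Intersects sequence-predicted MREs with negative co-expression: a pair is
#' retained iff it has at least one MRE, its Pearson r is strictly below
#' `r_max` and its p-value strictly below `p_max`. Correlations are computed
#' across all samples, conditions pooled.
#'
#' @param mre_counts data frame from [count_mres()] (mirna_id, target_id,
#'   mre_count).
#' @param expr `expression_matrix` containing every pair member.
#' @param target_kind label for the targets, `"mRNA"` or `"lncRNA"`.
#' @param r_max correlation upper bound (default -0.7, strict).
#' @param p_max p-value upper bound (default 0.01, strict).
#' @return data frame: mirna_id, target_id, target_kind, mre_count, pcc,
#'   pcc_pvalue.
#' @export
mirna_target_interactions <- function(mre_counts, expr, target_kind = "mRNA",
                                      r_max = -0.7, p_max = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(mre_counts) == 0L)
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), mre_count = integer(0),
                      pcc = numeric(0), pcc_pvalue = numeric(0),
                      stringsAsFactors = FALSE))
  miss <- setdiff(unique(c(mre_counts$mirna_id, mre_counts$target_id)),
                  rownames(expr$values))
  if (length(miss)) stop("feature missing from expression matrix: ", miss[1])
  n <- ncol(expr$values)
  r <- mapply(function(m, t)
    suppressWarnings(stats::cor(expr$values[m, ], expr$values[t, ])),
    mre_counts$mirna_id, mre_counts$target_id)
  p <- cor_pvalue(r, n)
  keep <- !is.na(r) & r < r_max & p < p_max
  out <- data.frame(mirna_id = mre_counts$mirna_id[keep],
                    target_id = mre_counts$target_id[keep],
                    target_kind = rep_len(target_kind, sum(keep)),
                    mre_count = mre_counts$mre_count[keep],
                    pcc = unname(r[keep]), pcc_pvalue = p[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$mirna_id, out$target_id), , drop = FALSE]
}

#' Positively co-expressed lncRNA-mRNA pairs
#'
#' All lncRNA x mRNA pairs with Pearson r strictly above `r_min` and p-value
#' strictly below `p_max`, across all samples pooled.
#'
#' @param expr `expression_matrix`.
#' @param lnc_ids,mrna_ids feature ids present in `expr`.
#' @param r_min correlation lower bound (default 0.7, strict).
#' @param p_max p-value upper bound (default 0.01, strict).
#' @return data frame: lncrna_id, mrna_id, pcc, pcc_pvalue, n.
#' @export
lncrna_mrna_pairs <- function(expr, lnc_ids, mrna_ids, r_min = 0.7, p_max = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"))
  miss <- setdiff(c(lnc_ids, mrna_ids), rownames(expr$values))
  if (length(miss)) stop("feature missing from expression matrix: ", miss[1])
  if (length(lnc_ids) == 0L || length(mrna_ids) == 0L)
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      pcc = numeric(0), pcc_pvalue = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE))
  cc <- cor_pairs(expr, lnc_ids, mrna_ids)
  keep <- !is.na(cc$r) & cc$r > r_min & cc$pvalue < p_max
  out <- data.frame(lncrna_id = cc$id_a[keep], mrna_id = cc$id_b[keep],
                    pcc = cc$r[keep], pcc_pvalue = cc$pvalue[keep],
                    n = cc$n[keep], row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
}

#' Expression-trait correlation
#'
#' Pearson correlation between one feature's expression profile and a
#' physiological trait measured on the same samples (e.g. hormone content).
#'
#' @param expr_feature numeric vector of one feature's values across samples.
#' @param trait numeric vector of trait values, same sample order.
#' @return list with `r`, `pvalue`, `n` as in [pearson_cor()].
#' @export
trait_correlation <- function(expr_feature, trait) {
  pearson_cor(expr_feature, trait)
}
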