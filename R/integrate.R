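## Result intersection and diagnostics ---------------------------------------

#' Intersect result sets into the key-gene report
#'
#' The key set is the intersection of the hub genes (A), the
#' chi-square-confirmed grade-consistent DEGs (B) and the grade-monotone
#' replication DEGs (D). Membership in the survival set (C) is reported per
#' gene, not enforced: key genes outside C stay in the report with the flag
#' set to `FALSE`.
#'
#' @param result_a,result_b,result_c,result_d character vectors of gene ids,
#'   or data frames with a `gene` column.
#' @param deg_d optional [build_result_d()] table supplying per-step log2
#'   fold changes.
#' @param screen optional [screen_survival()] table supplying the survival
#'   p-value and mortality ratio.
#' @param connectivity optional named numeric vector of subnetwork
#'   connectivities.
#' @param test which survival p-value column to report from `screen`.
#' @return data frame, one row per key gene, sorted by connectivity (when
#'   available) then gene id.
#' @export
intersect_results <- function(result_a, result_b, result_c, result_d,
                              deg_d = NULL, screen = NULL,
                              connectivity = NULL,
                              test = c("cox", "logrank")) {
  test <- match.arg(test)
  a <- as_gene_set(result_a); b <- as_gene_set(result_b)
  cset <- as_gene_set(result_c); d <- as_gene_set(result_d)
  if (!length(unique(c(a, b, cset, d)))) stop("empty gene universe")
  key <- Reduce(intersect, list(a, b, d))
  out <- data.frame(gene = key, in_a = rep(TRUE, length(key)),
                    in_b = rep(TRUE, length(key)), in_c = key %in% cset,
                    in_d = rep(TRUE, length(key)), stringsAsFactors = FALSE)
  if (!is.null(deg_d)) {
    out$lfc_3v2 <- deg_d$lfc_3v2[match(key, deg_d$gene)]
    out$lfc_4v3 <- deg_d$lfc_4v3[match(key, deg_d$gene)]
  }
  if (!is.null(screen)) {
    pcol <- if (test == "cox") "cox_lrt_p" else "logrank_p"
    out$survival_p <- screen[[pcol]][match(key, screen$gene)]
    out$rr <- screen$rr[match(key, screen$gene)]
  }
  if (!is.null(connectivity)) {
    out$connectivity <- unname(connectivity[match(key, names(connectivity))])
    out <- out[order(-ifelse(is.na(out$connectivity), -Inf,
                             out$connectivity), out$gene), , drop = FALSE]
  } else {
    out <- out[order(out$gene), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Rank-based ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a positive-class sample
#' outranks a negative-class one, with ties contributing one half. The value
#' is reported directionally -- genes expressed lower in the positive class
#' score below 0.5; no automatic flip is applied.
#'
#' @param values numeric marker values.
#' @param labels class labels.
#' @param positive label treated as the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Correlation of key genes with marker genes
#'
#' Pairwise Pearson correlation between each gene of interest and each marker
#' gene, with two-sided t-transform p-values.
#'
#' @param expr genes x samples matrix containing all genes and markers.
#' @param gene_set gene ids of interest.
#' @param marker_set marker gene ids.
#' @return list with matrices `r` and `p` (genes x markers).
#' @export
marker_correlation <- function(expr, gene_set, marker_set) {
  missing_g <- setdiff(c(gene_set, marker_set), rownames(expr))
  if (length(missing_g))
    stop("gene(s) missing from expression matrix: ",
         paste(missing_g, collapse = ", "))
  r <- stats::cor(t(expr[gene_set, , drop = FALSE]),
                  t(expr[marker_set, , drop = FALSE]))
  list(r = r, p = cor_pvalue(r, ncol(expr)))
}
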