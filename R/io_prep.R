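## Reading, normalization and cleaning ---------------------------------------

#' Read a gene-level expression matrix
#'
#' Expects a rectangular delimited table whose first column holds gene ids and
#' whose header row holds sample ids. Duplicate gene ids are collapsed by
#' keeping the row with the highest mean expression (with a warning), the
#' standard convention for array data.
#'
#' @param path file path.
#' @param sep field separator (tab by default).
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, fill = FALSE,
                      comment.char = ""),
    error = function(e) stop("malformed expression table '", path, "': ",
                             conditionMessage(e)))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty expression matrix in '", path, "'")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad))
        stop("non-numeric expression value at gene '", ids[bad[1]],
             "', sample '", names(vals)[j], "'")
      vals[[j]] <- num
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    warning("collapsing ", length(dup),
            " duplicated gene id(s) by highest mean expression")
    keep <- rep(TRUE, nrow(mat))
    means <- rowMeans(mat, na.rm = TRUE)
    for (d in dup) {
      idx <- which(ids == d)
      keep[idx[-which.max(means[idx])]] <- FALSE
    }
    mat <- mat[keep, , drop = FALSE]
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with required columns `sample_id` and `grade`; optional `os_time`,
#' `os_event` and `age`. Grade labels are normalized case-insensitively. A
#' survival time without an event indicator is a format error.
#'
#' @param path file path.
#' @return data frame with one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "grade")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("clinical table has duplicated sample ids")
  df$grade <- normalize_grade(df$grade)
  if (is.null(df$os_time)) df$os_time <- NA_real_
  if (is.null(df$os_event)) df$os_event <- NA_integer_
  if (is.null(df$age)) df$age <- NA_real_
  bad <- !is.na(df$os_time) & is.na(df$os_event)
  if (any(bad))
    stop("os_time present without os_event for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  if (any(!df$os_event[!is.na(df$os_event)] %in% c(0L, 1L)))
    stop("os_event must be 0 or 1")
  if (any(df$os_time[!is.na(df$os_time)] < 0))
    stop("os_time must be non-negative")
  df
}

#' Quantile normalization
#'
#' Maps every sample (column) onto the common reference distribution given by
#' the row means of the column-sorted matrix, so all samples share one sorted
#' value vector afterwards. Within-sample rank ties receive the mean of the
#' reference values they span.
#'
#' @param expr genes x samples numeric matrix with at least two samples.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(expr) {
  if (ncol(expr) < 2) stop("quantile normalization needs at least 2 samples")
  if (any(!is.finite(expr))) stop("quantile_normalize: non-finite values in input")
  ref <- rowMeans(apply(expr, 2, sort))
  out <- expr
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    assigned <- numeric(length(x))
    assigned[order(x)] <- ref
    # tie groups (equal input values) share the mean of the spanned refs
    out[, j] <- stats::ave(assigned, match(x, x), FUN = mean)
  }
  out
}

#' Remove near-zero genes and samples
#'
#' Drops genes whose mean expression or variance falls below the thresholds
#' and samples whose mean expression falls below `min_mean`; removals are
#' reported via `message()`.
#'
#' @param expr genes x samples matrix.
#' @param min_mean minimum mean expression for genes and samples.
#' @param min_variance minimum gene variance.
#' @return list with `expr`, `removed_genes`, `removed_samples`.
#' @export
clean_genes_samples <- function(expr, min_mean = 1, min_variance = 1e-8) {
  if (min_mean < 0 || min_variance < 0) stop("thresholds must be >= 0")
  gm <- rowMeans(expr)
  gv <- apply(expr, 1, stats::var)
  bad_g <- gm < min_mean | gv < min_variance
  if (all(bad_g)) stop("all genes removed by cleaning thresholds")
  expr2 <- expr[!bad_g, , drop = FALSE]
  sm <- colMeans(expr2)
  bad_s <- sm < min_mean
  if (all(bad_s)) stop("all samples removed by cleaning thresholds")
  if (any(bad_g)) message("clean_genes_samples: removed ", sum(bad_g), " gene(s)")
  if (any(bad_s)) message("clean_genes_samples: removed ", sum(bad_s), " sample(s)")
  list(expr = expr2[, !bad_s, drop = FALSE],
       removed_genes = rownames(expr)[bad_g],
       removed_samples = colnames(expr2)[bad_s])
}

#' Remove outlier samples by dendrogram height
#'
#' Samples are clustered on the Euclidean distance between their expression
#' profiles; cutting the dendrogram at `height_threshold`, every sample
#' outside the largest cluster is removed.
#'
#' @param expr genes x samples matrix (at least 3 samples).
#' @param height_threshold positive cut height.
#' @param linkage_method linkage for [stats::hclust()]; average linkage is the
#'   co-expression workflow convention.
#' @return list with `expr` and `removed_samples`.
#' @export
remove_outlier_samples <- function(expr, height_threshold,
                                   linkage_method = "average") {
  if (ncol(expr) < 3) stop("need at least 3 samples for outlier detection")
  if (height_threshold <= 0) stop("height_threshold must be positive")
  hc <- stats::hclust(stats::dist(t(expr)), method = linkage_method)
  cl <- stats::cutree(hc, h = height_threshold)
  sizes <- table(cl)
  if (max(sizes) == 1)
    stop("all samples fall into singleton clusters at this height; ",
         "increase height_threshold")
  main <- as.integer(names(sizes)[which.max(sizes)])
  removed <- colnames(expr)[cl != main]
  if (length(removed))
    message("remove_outlier_samples: removed ", length(removed),
            " sample(s): ", paste(removed, collapse = ", "))
  list(expr = expr[, cl == main, drop = FALSE], removed_samples = removed)
}
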