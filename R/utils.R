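#' @keywords internal
"_PACKAGE"

## Grade handling ------------------------------------------------------------

GRADE_LEVELS <- c("normal", "I", "II", "III", "IV")

#' Normalize WHO grade labels
#'
#' Accepts case-insensitive roman-numeral grades plus `"normal"` and maps
#' them onto the canonical levels `normal, I, II, III, IV`.
#'
#' @param x character vector of grade labels.
#' @return character vector on the canonical levels.
#' @export
normalize_grade <- function(x) {
  key <- toupper(trimws(as.character(x)))
  key[key %in% c("NORMAL", "N", "CONTROL")] <- "normal"
  bad <- !key %in% GRADE_LEVELS
  if (any(bad)) {
    stop("unrecognized grade label(s): ",
         paste(unique(key[bad]), collapse = ", "))
  }
  key
}

#' Numeric WHO grade codes
#'
#' `normal` codes to 0 and grades I--IV to 1--4, the coding used for the
#' grade trait throughout the screen.
#'
#' @param grade character vector of grade labels.
#' @return integer vector of codes.
#' @export
grade_code <- function(grade) {
  g <- normalize_grade(grade)
  unname(c(normal = 0L, I = 1L, II = 2L, III = 3L, IV = 4L)[g])
}

# Malignancy steps used for planted expression shifts: normal and grade I sit
# at 0, then one step per grade II -> III -> IV.
grade_steps <- function(grade) {
  pmax(grade_code(grade) - 1L, 0L)
}

## Misc ----------------------------------------------------------------------

# Correlation p-value from the t transform with n - 2 df.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Deterministic RNG scope: runs `expr` under `seed` and restores the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Intersect an expression matrix and a clinical table on sample ids, keeping
# the expression column order. Dropped samples are reported via message().
#' Align an expression matrix with a clinical table
#'
#' Samples are matched by id intersection; samples present in only one of the
#' two inputs are dropped with a message.
#'
#' @param expr genes x samples numeric matrix with sample ids as column names.
#' @param clinical data frame with a `sample_id` column.
#' @return list with the aligned `expr` and `clinical`.
#' @export
align_cohort <- function(expr, clinical) {
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (length(shared) == 0) stop("no shared sample ids between expression and clinical table")
  drop_e <- setdiff(colnames(expr), shared)
  drop_c <- setdiff(clinical$sample_id, shared)
  if (length(drop_e))
    message("align_cohort: dropping ", length(drop_e), " expression sample(s) without clinical rows")
  if (length(drop_c))
    message("align_cohort: dropping ", length(drop_c), " clinical row(s) without expression")
  keep <- colnames(expr)[colnames(expr) %in% shared]
  list(expr = expr[, keep, drop = FALSE],
       clinical = clinical[match(keep, clinical$sample_id), , drop = FALSE])
}

as_gene_set <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("gene" %in% names(x))
    as.character(x$gene)
  } else {
    as.character(x)
  }
}
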