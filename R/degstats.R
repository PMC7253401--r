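## Differential expression ----------------------------------------------------

# Newton inversion of the trigamma function, used when moment-matching the
# scaled inverse-chi-square prior on gene variances.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per gene, the pooled two-group residual variance `s_g^2` on `d = n - 2`
#' degrees of freedom is shrunk towards a common prior: the prior degrees of
#' freedom `d0` and scale `s0^2` are estimated by moment matching of
#' `log s_g^2` (digamma/trigamma inversion), the posterior variance is
#' `(d0 s0^2 + d s_g^2) / (d0 + d)`, and the moderated t statistic is referred
#' to a t distribution with `d0 + d` degrees of freedom. With `prior_df = 0`
#' the test reduces to the ordinary pooled t; with `prior_df = Inf` every gene
#' uses the common variance `s0^2`.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param groups two-level factor (or coercible) over the samples; the log2
#'   fold change is level 2 minus level 1.
#' @param prior_df optional fixed prior degrees of freedom overriding the
#'   moment-matched estimate.
#' @param p_max,lfc_min strict thresholds used only to label the `direction`
#'   column (defaults 0.001 and 1).
#' @return data frame with gene, log2fc, t, df, p, direction.
#' @export
moderated_ttest <- function(expr, groups, prior_df = NULL,
                            p_max = 0.001, lfc_min = 1) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (length(groups) != ncol(expr))
    stop("groups length must match number of samples")
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  ss1 <- rowSums((expr[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  if (all(s2 == 0)) stop("all genes have zero residual variance")

  ok <- s2 > 0
  if (is.null(prior_df)) {
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- if (sum(ok) > 1) stats::var(e) else 0
    rhs <- evar - trigamma(d / 2)
    if (is.finite(rhs) && rhs > 0) {
      d0 <- 2 * trigamma_inverse(rhs)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(e))
    }
  } else {
    d0 <- prior_df
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    s02 <- if (is.finite(d0) && d0 > 0)
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(e))
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  lfc <- m2 - m1
  tt <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  direction <- ifelse(p < p_max & lfc > lfc_min, "up",
                      ifelse(p < p_max & lfc < -lfc_min, "down", "flat"))
  out <- data.frame(gene = rownames(expr), log2fc = lfc, t = tt,
                    df = df_total, p = p, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Threshold a differential-expression table
#'
#' Strict inequalities, matching a `P < p_max`, `|log2FC| > lfc_min` screen:
#' boundary values are excluded.
#'
#' @param table a [moderated_ttest()] result.
#' @param p_max p-value threshold (default 0.001).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @return list with character vectors `up` and `down`.
#' @export
filter_degs <- function(table, p_max = 0.001, lfc_min = 1) {
  if (p_max <= 0 || lfc_min <= 0) stop("thresholds must be positive")
  list(up = table$gene[table$p < p_max & table$log2fc > lfc_min],
       down = table$gene[table$p < p_max & table$log2fc < -lfc_min])
}

#' Intersect two screens keeping trend-consistent genes
#'
#' Up genes of both screens intersect with up, down with down; genes
#' significant in both but with opposite trends are dropped and counted.
#'
#' @param degs_a,degs_b lists with `up` and `down` sets ([filter_degs()]).
#' @return list with `up`, `down` and `n_inconsistent`.
#' @export
consistent_trend <- function(degs_a, degs_b) {
  up <- intersect(degs_a$up, degs_b$up)
  down <- intersect(degs_a$down, degs_b$down)
  flipped <- union(intersect(degs_a$up, degs_b$down),
                   intersect(degs_a$down, degs_b$up))
  if (length(flipped))
    message("consistent_trend: dropped ", length(flipped),
            " gene(s) with opposite trends")
  list(up = up, down = down, n_inconsistent = length(flipped))
}

#' Chi-square test of expression tertile versus grade group
#'
#' The gene's expression range `[min, max]` is divided into `n_bins`
#' equal-width intervals (right-open except the last); the resulting
#' bin-by-group contingency table is tested with Pearson's chi-square without
#' continuity correction. Empty bin rows are dropped with the degrees of
#' freedom adjusted accordingly.
#'
#' @param expr genes x samples matrix, or a numeric expression vector (then
#'   leave `gene` as `NULL`).
#' @param gene gene id when `expr` is a matrix.
#' @param groups two-level grouping (e.g. high/low grade) over the samples.
#' @param n_bins number of expression intervals (default 3).
#' @return list with `statistic`, `p`, `df` and the contingency `table`.
#' @export
grade_chisq <- function(expr, gene = NULL, groups, n_bins = 3) {
  x <- if (is.matrix(expr)) {
    if (is.null(gene) || !gene %in% rownames(expr))
      stop("gene not found in expression matrix")
    expr[gene, ]
  } else as.numeric(expr)
  groups <- factor(groups)
  ok <- !is.na(x) & !is.na(groups)
  x <- x[ok]; groups <- droplevels(groups[ok])
  if (length(x) < 6) stop("need at least 6 labeled samples")
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (diff(range(x)) == 0) stop("constant expression; bins undefined")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- pmin(findInterval(x, breaks), n_bins)
  tab <- table(factor(bin, levels = seq_len(n_bins)), groups)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    message("grade_chisq: dropping ", sum(empty), " empty expression bin(s)")
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("fewer than 2 non-empty expression bins")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter), table = tab)
}

## Result sets ----------------------------------------------------------------

#' Grade-consistent differential genes with chi-square confirmation (result B)
#'
#' On a cohort containing normal and tumor samples: genes differentially
#' expressed with the same trend in tumor-vs-normal and in high-grade
#' (III/IV) vs low-grade (I/II), then confirmed by the expression-tertile
#' chi-square against grade group at `chisq_p_max`.
#'
#' @param expr genes x samples matrix.
#' @param clinical clinical table with `sample_id` and `grade`.
#' @param p_max,lfc_min DEG thresholds (defaults 0.001, 1).
#' @param chisq_p_max chi-square gate (default 0.001).
#' @param n_bins expression bins for the chi-square (default 3).
#' @return data frame with gene and direction; attributes carry the raw
#'   intersection and trend-consistent counts.
#' @export
build_result_b <- function(expr, clinical, p_max = 0.001, lfc_min = 1,
                           chisq_p_max = 0.001, n_bins = 3) {
  al <- align_cohort(expr, clinical)
  expr <- al$expr; clinical <- al$clinical
  grade <- normalize_grade(clinical$grade)
  if (!any(grade == "normal")) stop("result B needs normal samples")
  tumor <- grade != "normal"
  g_tn <- factor(ifelse(tumor, "tumor", "normal"),
                 levels = c("normal", "tumor"))
  deg_tn <- moderated_ttest(expr, g_tn, p_max = p_max, lfc_min = lfc_min)
  hl <- ifelse(grade %in% c("III", "IV"), "high",
               ifelse(grade %in% c("I", "II"), "low", NA))
  tt <- !is.na(hl)
  g_hl <- factor(hl[tt], levels = c("low", "high"))
  deg_hl <- moderated_ttest(expr[, tt, drop = FALSE], g_hl,
                            p_max = p_max, lfc_min = lfc_min)
  f_tn <- filter_degs(deg_tn, p_max, lfc_min)
  f_hl <- filter_degs(deg_hl, p_max, lfc_min)
  tr <- consistent_trend(f_tn, f_hl)
  raw_n <- length(intersect(unlist(f_tn), unlist(f_hl)))

  cand <- data.frame(gene = c(tr$up, tr$down),
                     direction = rep(c("up", "down"),
                                     c(length(tr$up), length(tr$down))),
                     stringsAsFactors = FALSE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cs <- grade_chisq(expr[, tt, drop = FALSE], cand$gene[i], g_hl,
                      n_bins = n_bins)
    keep[i] <- cs$p < chisq_p_max
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_raw_intersection") <- raw_n
  attr(out, "n_trend_consistent") <- nrow(cand)
  out
}

#' Grade-monotone differential genes in the replication cohort (result D)
#'
#' Genes with the same differential trend in WHO III vs II and WHO IV vs III;
#' no chi-square stage is applied, to avoid over-mining the replication
#' cohort.
#'
#' @inheritParams build_result_b
#' @return data frame with gene, direction, lfc_3v2, lfc_4v3.
#' @export
build_result_d <- function(expr, clinical, p_max = 0.001, lfc_min = 1) {
  al <- align_cohort(expr, clinical)
  expr <- al$expr; clinical <- al$clinical
  grade <- normalize_grade(clinical$grade)
  for (g in c("II", "III", "IV"))
    if (!any(grade == g)) stop("result D needs grade ", g, " samples")
  s32 <- grade %in% c("II", "III")
  deg32 <- moderated_ttest(expr[, s32, drop = FALSE],
                           factor(grade[s32], levels = c("II", "III")),
                           p_max = p_max, lfc_min = lfc_min)
  s43 <- grade %in% c("III", "IV")
  deg43 <- moderated_ttest(expr[, s43, drop = FALSE],
                           factor(grade[s43], levels = c("III", "IV")),
                           p_max = p_max, lfc_min = lfc_min)
  tr <- consistent_trend(filter_degs(deg32, p_max, lfc_min),
                         filter_degs(deg43, p_max, lfc_min))
  genes <- c(tr$up, tr$down)
  out <- data.frame(gene = genes,
                    direction = rep(c("up", "down"),
                                    c(length(tr$up), length(tr$down))),
                    lfc_3v2 = deg32$log2fc[match(genes, deg32$gene)],
                    lfc_4v3 = deg43$log2fc[match(genes, deg43$gene)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
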