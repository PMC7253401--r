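## Expression-stratified survival screen --------------------------------------

#' Split samples into low/high expression groups
#'
#' Samples are sorted by the gene's expression (ties broken by sample id for
#' determinism); the lowest `floor(low_frac * n)` form the low-expression
#' group, the rest the high-expression group. The default 30/70 split follows
#' the screen's convention.
#'
#' @param expr genes x samples matrix, or a named numeric vector.
#' @param gene gene id when `expr` is a matrix.
#' @param low_frac fraction assigned to the low group (default 0.3).
#' @return factor (levels `low`, `high`) named by sample id.
#' @export
split_high_low <- function(expr, gene = NULL, low_frac = 0.3) {
  x <- if (is.matrix(expr)) {
    if (is.null(gene) || !gene %in% rownames(expr))
      stop("gene not found in expression matrix")
    expr[gene, ]
  } else expr
  if (length(x) < 10) stop("need at least 10 samples for the survival split")
  if (diff(range(x)) == 0) stop("all expression values identical; split undefined")
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  ord <- order(x, ids)
  n_low <- floor(low_frac * length(x))
  lab <- rep("high", length(x))
  lab[ord[seq_len(n_low)]] <- "low"
  stats::setNames(factor(lab, levels = c("low", "high")), ids)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in the second group are
#' compared with their hypergeometric expectation given the risk sets; the
#' summed deviation over its summed variance is referred to a chi-square
#' distribution with one degree of freedom.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = death, 0 = censored).
#' @param groups two-level factor.
#' @return list with `statistic`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (sum(event) < 1) stop("log-rank test needs at least one event")
  ev_times <- sort(unique(time[event == 1]))
  g2 <- groups == levels(groups)[2]
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    r <- sum(at_risk)
    r1 <- sum(at_risk & g2)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g2)
    O <- O + d1
    E <- E + d * r1 / r
    if (r > 1)
      V <- V + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Cox proportional-hazards likelihood-ratio test for a binary group
#'
#' Partial likelihood with Breslow tie handling, maximized by Newton-Raphson
#' to a gradient below `tol`. The likelihood-ratio statistic
#' `2 (l(beta_hat) - l(0))` is referred to a chi-square with one degree of
#' freedom. Monotone likelihoods (e.g. all events in one group) are flagged
#' as non-converged with the statistic taken at the last iterate.
#'
#' @inheritParams logrank_test
#' @param max_iter Newton-Raphson iteration cap (default 50).
#' @param tol gradient convergence tolerance (default 1e-8).
#' @return list with `beta`, `se`, `lrt_statistic`, `p`, `converged`.
#' @export
cox_group_lrt <- function(time, event, groups, max_iter = 50, tol = 1e-8) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (sum(event) < 1) stop("Cox fit needs at least one event")
  x <- as.integer(groups == levels(groups)[2])
  ev_times <- sort(unique(time[event == 1]))
  d <- d1 <- r0 <- r1 <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    at_risk <- time >= t
    r1[i] <- sum(at_risk & x == 1)
    r0[i] <- sum(at_risk & x == 0)
    d[i] <- sum(time == t & event == 1)
    d1[i] <- sum(time == t & event == 1 & x == 1)
  }
  D1 <- sum(d1)
  loglik <- function(b) b * D1 - sum(d * log(r0 + r1 * exp(b)))
  beta <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eb <- exp(beta)
    denom <- r0 + r1 * eb
    score <- D1 - sum(d * r1 * eb / denom)
    info <- sum(d * r0 * r1 * eb / denom^2)
    if (abs(score) < tol) { converged <- TRUE; break }
    if (info <= 0) break
    step <- score / info
    # damp huge steps (monotone likelihood drifts towards +/- Inf)
    if (abs(step) > 5) step <- sign(step) * 5
    beta <- beta + step
    if (abs(beta) > 20) { beta <- sign(beta) * 20; break }
  }
  eb <- exp(beta)
  info <- sum(d * r0 * r1 * eb / (r0 + r1 * eb)^2)
  if (!converged)
    message("cox_group_lrt: Newton-Raphson did not converge ",
            "(monotone likelihood?); statistic taken at last iterate")
  lrt <- 2 * (loglik(beta) - loglik(0))
  list(beta = beta, se = if (info > 0) 1 / sqrt(info) else NA_real_,
       lrt_statistic = lrt,
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       converged = converged)
}

#' Mortality-rate ratio between expression groups
#'
#' The death proportion of the high-expression group divided by that of the
#' low-expression group. `RR > 1` means high expression accompanies death;
#' `0 < RR < 1` means low expression does. A zero low-group death count makes
#' the ratio undefined; it is flagged and reported as `Inf`.
#'
#' @param event event indicators.
#' @param groups factor with levels `low`, `high` ([split_high_low()]).
#' @return list with `rr`, `defined`, and the group death counts and sizes.
#' @export
relative_risk <- function(event, groups) {
  groups <- factor(groups, levels = c("low", "high"))
  n_low <- sum(groups == "low"); n_high <- sum(groups == "high")
  if (n_low == 0 || n_high == 0) stop("both expression groups must be non-empty")
  d_low <- sum(event[groups == "low"])
  d_high <- sum(event[groups == "high"])
  if (d_low == 0) {
    warning("relative_risk: no deaths in the low-expression group; RR undefined")
    rr <- Inf
    defined <- FALSE
  } else {
    rr <- (d_high / n_high) / (d_low / n_low)
    defined <- TRUE
  }
  list(rr = rr, defined = defined, deaths_low = d_low, deaths_high = d_high,
       n_low = n_low, n_high = n_high)
}

#' Chi-square test of expression group versus death status
#'
#' Pearson chi-square without continuity correction on the 2x2 table of
#' low/high expression against death/alive.
#'
#' @inheritParams relative_risk
#' @return list with `statistic`, `p` and the `table`.
#' @export
death_chisq <- function(event, groups) {
  tab <- table(factor(groups), factor(event, levels = c(0, 1)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("death_chisq: zero margin in the 2x2 table")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value), table = tab)
}

#' Per-gene expression-stratified survival screen
#'
#' For every gene: 30/70 expression split, log-rank test, Cox likelihood-ratio
#' test, mortality-rate ratio, and the death/alive chi-square. Genes with a
#' constant expression profile are skipped with a message.
#'
#' @param expr genes x samples matrix.
#' @param clinical clinical table with `sample_id`, `os_time`, `os_event`.
#' @param low_frac low-expression fraction (default 0.3).
#' @param p_max significance threshold for the `significant` flag (default
#'   0.001).
#' @param test which p-value drives the `significant` flag: `"logrank"` or
#'   `"cox"`.
#' @return data frame, one row per screened gene.
#' @export
screen_survival <- function(expr, clinical, low_frac = 0.3, p_max = 0.001,
                            test = c("logrank", "cox")) {
  test <- match.arg(test)
  al <- align_cohort(expr, clinical)
  ok <- !is.na(al$clinical$os_time) & !is.na(al$clinical$os_event)
  expr <- al$expr[, ok, drop = FALSE]
  time <- al$clinical$os_time[ok]
  event <- al$clinical$os_event[ok]
  if (ncol(expr) < 10) stop("need at least 10 samples with survival data")
  rows <- vector("list", nrow(expr))
  skipped <- character(0)
  for (i in seq_len(nrow(expr))) {
    g <- rownames(expr)[i]
    if (diff(range(expr[i, ])) == 0) { skipped <- c(skipped, g); next }
    grp <- split_high_low(expr[i, ], low_frac = low_frac)
    lr <- logrank_test(time, event, grp)
    cx <- suppressMessages(cox_group_lrt(time, event, grp))
    rr <- suppressWarnings(relative_risk(event, grp))
    cs <- tryCatch(death_chisq(event, grp), error = function(e) NULL)
    rows[[i]] <- data.frame(
      gene = g, n_low = rr$n_low, n_high = rr$n_high,
      deaths_low = rr$deaths_low, deaths_high = rr$deaths_high,
      rr = rr$rr, rr_defined = rr$defined,
      logrank_p = lr$p, cox_beta = cx$beta, cox_lrt_p = cx$p,
      chisq_p = if (is.null(cs)) NA_real_ else cs$p,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message("screen_survival: skipped ", length(skipped),
            " constant gene(s)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  pcol <- if (test == "logrank") out$logrank_p else out$cox_lrt_p
  out$significant <- pcol < p_max
  attr(out, "test") <- test
  out
}

#' Cross-dataset survival consistency (result C)
#'
#' Genes significant in both screens (chosen test `p < p_max`), with the
#' death/alive chi-square below `chisq_p_max` in both, a defined mortality
#' ratio in both, and the same mortality-ratio direction (both above or both
#' below 1). Direction-inconsistent genes are counted and reported.
#'
#' @param screen_x,screen_y [screen_survival()] tables over a shared gene set.
#' @param p_max survival-test threshold (default 0.001).
#' @param chisq_p_max chi-square threshold (default 0.001).
#' @param test `"logrank"` or `"cox"` p-value column.
#' @return data frame with gene, rr_x, rr_y, direction; the number of
#'   direction-inconsistent genes is attached as an attribute.
#' @export
cross_dataset_consistent <- function(screen_x, screen_y, p_max = 0.001,
                                     chisq_p_max = 0.001,
                                     test = c("logrank", "cox")) {
  test <- match.arg(test)
  pcol <- if (test == "logrank") "logrank_p" else "cox_lrt_p"
  m <- merge(screen_x, screen_y, by = "gene", suffixes = c("_x", "_y"))
  sig <- m[[paste0(pcol, "_x")]] < p_max & m[[paste0(pcol, "_y")]] < p_max &
    !is.na(m$chisq_p_x) & m$chisq_p_x < chisq_p_max &
    !is.na(m$chisq_p_y) & m$chisq_p_y < chisq_p_max &
    m$rr_defined_x & m$rr_defined_y
  same_dir <- (m$rr_x > 1 & m$rr_y > 1) | (m$rr_x < 1 & m$rr_y < 1)
  n_flip <- sum(sig & !same_dir, na.rm = TRUE)
  if (n_flip)
    message("cross_dataset_consistent: ", n_flip,
            " significant gene(s) with inconsistent mortality-ratio direction")
  keep <- which(sig & same_dir)
  out <- data.frame(gene = m$gene[keep], rr_x = m$rr_x[keep],
                    rr_y = m$rr_y[keep],
                    direction = ifelse(m$rr_x[keep] > 1, "risk", "protective"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_inconsistent") <- n_flip
  out
}
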