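make_two_group <- function(n_genes = 40, n1 = 8, n2 = 8, seed = 1,
                           shift = 0) {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * (n1 + n2), sd = runif(n_genes, 0.5, 2)),
                 n_genes, n1 + n2)
  expr[, (n1 + 1):(n1 + n2)] <- expr[, (n1 + 1):(n1 + n2)] + shift
  dimnames(expr) <- list(sprintf("g%03d", 1:n_genes),
                         sprintf("s%02d", 1:(n1 + n2)))
  list(expr = expr, groups = factor(rep(c("a", "b"), c(n1, n2))))
}

test_that("moderated t reduces to the classical pooled t at zero prior df", {
  d <- make_two_group(seed = 2)
  tab <- moderated_ttest(d$expr, d$groups, prior_df = 0)
  for (i in c(1, 7, 23)) {
    tt <- t.test(d$expr[i, d$groups == "b"], d$expr[i, d$groups == "a"],
                 var.equal = TRUE)
    expect_equal(tab$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("infinite prior df pools every gene to the common variance", {
  d <- make_two_group(seed = 3)
  tab <- moderated_ttest(d$expr, d$groups, prior_df = Inf)
  s0 <- sqrt(attr(tab, "prior_var"))
  m1 <- rowMeans(d$expr[, d$groups == "a"])
  m2 <- rowMeans(d$expr[, d$groups == "b"])
  expect_equal(tab$t, unname((m2 - m1) / (s0 * sqrt(1 / 8 + 1 / 8))),
               tolerance = 1e-10)
  expect_true(all(is.infinite(tab$df)))
})

test_that("moderated t agrees with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  d <- make_two_group(n_genes = 120, n1 = 10, n2 = 10, seed = 4, shift = 0.4)
  tab <- moderated_ttest(d$expr, d$groups)
  design <- stats::model.matrix(~d$groups)
  fit <- limma::eBayes(limma::lmFit(d$expr, design))
  expect_equal(attr(tab, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(tab$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("label swap negates fold changes and mirrors directions", {
  d <- make_two_group(seed = 5, shift = 2)
  tab1 <- moderated_ttest(d$expr, d$groups)
  tab2 <- moderated_ttest(d$expr, factor(d$groups, levels = c("b", "a")))
  expect_equal(tab1$log2fc, -tab2$log2fc, tolerance = 1e-12)
  f1 <- filter_degs(tab1); f2 <- filter_degs(tab2)
  expect_setequal(f1$up, f2$down)
  expect_setequal(f1$down, f2$up)
  expect_length(intersect(f1$up, f1$down), 0)
})

test_that("DEG thresholds are strict inequalities", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    log2fc = c(1.5, 1.0, 3.0),
                    t = 0, df = 10,
                    p = c(0.0005, 0.0005, 0.01))
  f <- filter_degs(tab)
  expect_equal(f$up, "a")  # b excluded at |log2FC| = 1, c at p = 0.01
  expect_length(f$down, 0)
})

test_that("trend consistency intersects by direction and drops flips", {
  expect_length(consistent_trend(list(up = "a", down = "b"),
                                 list(up = "c", down = "d"))$up, 0)
  same <- list(up = c("a", "b"), down = "c")
  out <- consistent_trend(same, same)
  expect_equal(out$up, c("a", "b")); expect_equal(out$down, "c")
  expect_message(
    fl <- consistent_trend(list(up = "a", down = character(0)),
                           list(up = character(0), down = "a")),
    "opposite")
  expect_equal(fl$n_inconsistent, 1)
  expect_length(fl$up, 0)
})

test_that("grade chi-square equals the hand-computed statistic", {
  counts <- matrix(c(10, 5, 0, 0, 5, 10), ncol = 2,
                   dimnames = list(NULL, c("low", "high")))
  fx <- expr_for_table(counts)
  res <- grade_chisq(fx$x, groups = fx$groups, n_bins = 3)
  expect_equal(res$statistic, 20.0, tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$statistic, chisq_oracle(res$table), tolerance = 1e-10)

  # perfectly grade-separated expression at n = 100
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  g <- rep(c("low", "high"), each = 50)
  expect_lt(grade_chisq(x, groups = g)$p, 1e-10)

  expect_error(grade_chisq(rep(1, 20), groups = rep(c("a", "b"), 10)),
               "constant")
})

test_that("empty expression bins are dropped with the df adjusted", {
  x <- c(rep(0.5, 20), rep(2.5, 20))  # middle third of the range empty
  g <- rep(c("low", "high"), 20)
  expect_message(res <- grade_chisq(x, groups = g, n_bins = 3), "empty")
  expect_equal(res$df, 1)
  expect_equal(res$statistic, chisq_oracle(res$table), tolerance = 1e-10)
})

test_that("result B recovers planted grade-trend genes", {
  co <- small_cohort()
  b <- suppressMessages(build_result_b(co$expr, co$clinical))
  g <- co$truth$genes
  planted <- g$gene[abs(g$step_lfc) > 1]
  expect_gt(mean(planted %in% b$gene), 0.9)
  # directions match the planted signs
  dir_match <- b$direction[match(planted, b$gene)] ==
    ifelse(g$de_direction[match(planted, g$gene)] > 0, "up", "down")
  expect_true(all(dir_match, na.rm = TRUE))
  # background genes essentially never qualify
  bg <- g$gene[g$module == "background"]
  expect_lt(mean(bg %in% b$gene), 0.01)
})

test_that("result B without the chi-square gate is the trend intersection", {
  co <- small_cohort()
  gated <- suppressMessages(build_result_b(co$expr, co$clinical))
  open <- suppressMessages(build_result_b(co$expr, co$clinical,
                                          chisq_p_max = 1))
  expect_equal(nrow(open), attr(open, "n_trend_consistent"))
  expect_true(all(gated$gene %in% open$gene))
})

test_that("a null cohort yields an almost empty result B", {
  cfg <- synth_config(module_grade_cor = rep(0, 6), grade_shift = 0,
                      n_modules = 6, genes_per_module = 20,
                      n_background = 180)
  co <- generate_cohort(cfg, seed = 13)
  b <- suppressMessages(build_result_b(co$expr, co$clinical))
  expect_lte(nrow(b), 3)
})

test_that("result D intersects the two grade contrasts without a gate", {
  # replication-style cohort: tumor grades only, as in an RNA-seq series
  co <- generate_cohort(synth_config(n_normal = 0), seed = 5)
  d <- suppressMessages(build_result_d(co$expr, co$clinical))
  g <- co$truth$genes
  planted <- g$gene[abs(g$step_lfc) > 1]
  expect_gt(mean(planted %in% d$gene), 0.9)
  expect_true(all(sign(d$lfc_3v2) == sign(d$lfc_4v3)))
  expect_error(build_result_d(co$expr[, 1:20],
                              co$clinical[1:20, ]), "grade")
})
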