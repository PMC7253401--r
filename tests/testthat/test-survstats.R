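sim_surv <- function(n = 200, hr = 1, seed = 1, censor = 3) {
  set.seed(seed)
  g <- factor(rep(c("low", "high"), length.out = n), levels = c("low", "high"))
  rate <- 0.4 * ifelse(g == "high", hr, 1)
  t_raw <- rexp(n, rate)
  list(time = pmin(t_raw, censor), event = as.integer(t_raw <= censor),
       groups = g)
}

test_that("the 30/70 split is deterministic and respects the fraction", {
  x <- setNames(c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10), paste0("s", 1:10))
  sp <- split_high_low(x, low_frac = 0.3)
  expect_equal(sum(sp == "low"), 3)
  expect_equal(sum(sp == "high"), 7)
  expect_setequal(names(sp)[sp == "low"], names(sort(x)[1:3]))

  sp5 <- split_high_low(x, low_frac = 0.5)
  expect_equal(sum(sp5 == "low"), 5)

  # boundary tie: assignment fixed by sample id order, identical across runs
  y <- setNames(c(1, 2, 2, 2, 5, 6, 7, 8, 9, 10), paste0("s", 1:10))
  s1 <- split_high_low(y, low_frac = 0.3)
  s2 <- split_high_low(y[sample(10)], low_frac = 0.3)
  expect_equal(s1[order(names(s1))], s2[order(names(s2))])
  expect_setequal(names(s1)[s1 == "low"], c("s1", "s2", "s3"))

  expect_error(split_high_low(rep(1, 10)), "identical")
  expect_error(split_high_low(x[1:5]), "at least 10")
})

test_that("log-rank matches the survival-package statistic", {
  skip_if_not_installed("survival")
  # identical data in both groups: statistic 0, p 1
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 1, 0, 1, 1, 0)
  gr <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  same <- logrank_test(tm, ev, gr)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # toy separated groups vs the reference implementation
  tm2 <- c(1, 2, 3, 4, 5, 6); ev2 <- rep(1, 6)
  gr2 <- factor(rep(c("a", "b"), each = 3))
  mine <- logrank_test(tm2, ev2, gr2)
  ref <- survival::survdiff(survival::Surv(tm2, ev2) ~ gr2)
  expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)

  # random censored data, with ties
  d <- sim_surv(n = 80, hr = 1.7, seed = 3)
  d$time <- round(d$time, 1)
  mine2 <- logrank_test(d$time, d$event, d$groups)
  ref2 <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$groups)
  expect_equal(mine2$statistic, ref2$chisq, tolerance = 1e-10)

  expect_error(logrank_test(c(1, 2), c(0, 0), factor(c("a", "b"))), "event")
})

test_that("Cox fit matches coxph with Breslow ties", {
  skip_if_not_installed("survival")
  for (s in 1:3) {
    d <- sim_surv(n = 120, hr = 2, seed = s)
    d$time <- round(d$time, 1)  # induce ties
    mine <- cox_group_lrt(d$time, d$event, d$groups)
    ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$groups,
                           ties = "breslow")
    expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(mine$lrt_statistic,
                 2 * diff(ref$loglik), tolerance = 1e-6)
    expect_true(mine$converged)
  }
})

test_that("monotone likelihood is flagged rather than silently returned", {
  tm <- c(1, 2, 3, 10, 11, 12, 13, 14)
  ev <- c(1, 1, 1, 0, 0, 0, 0, 0)
  gr <- factor(c(rep("high", 3), rep("low", 5)), levels = c("low", "high"))
  expect_message(res <- cox_group_lrt(tm, ev, gr), "did not converge")
  expect_false(res$converged)
  expect_true(is.finite(res$p))
})

test_that("mortality ratio follows the stated definition and symmetry", {
  ev <- c(rep(1, 6), rep(0, 4), rep(1, 2), rep(0, 8))
  gr <- factor(rep(c("high", "low"), each = 10), levels = c("low", "high"))
  rr <- relative_risk(ev, gr)
  expect_equal(rr$rr, (6 / 10) / (2 / 10))  # 3.0
  expect_true(rr$defined)

  swapped <- relative_risk(ev, factor(ifelse(gr == "low", "high", "low"),
                                      levels = c("low", "high")))
  expect_equal(swapped$rr, 1 / rr$rr, tolerance = 1e-12)

  ev0 <- c(rep(1, 3), rep(0, 7), rep(0, 10))
  expect_warning(u <- relative_risk(ev0, gr), "undefined")
  expect_false(u$defined)
  expect_equal(u$rr, Inf)
})

test_that("death chi-square equals the hand statistic", {
  gr <- factor(rep(c("low", "high"), each = 50), levels = c("low", "high"))
  ev_flat <- rep(c(1, 0), 50)
  flat <- death_chisq(ev_flat, gr)
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1)

  gr2 <- factor(rep(c("low", "high"), each = 40), levels = c("low", "high"))
  ev2 <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  res <- death_chisq(ev2, gr2)
  expect_equal(res$statistic, 20.0, tolerance = 1e-10)
  expect_equal(res$statistic, chisq_oracle(res$table), tolerance = 1e-10)

  expect_error(death_chisq(rep(1, 80), gr2), "margin")
})

test_that("the survival screen is deterministic and rank-invariant", {
  co <- small_cohort()
  sub <- co$expr[1:30, ]
  s1 <- suppressMessages(screen_survival(sub, co$clinical))
  s2 <- suppressMessages(screen_survival(sub, co$clinical))
  expect_identical(s1, s2)
  # strictly increasing transform of expression leaves the screen unchanged
  s3 <- suppressMessages(screen_survival(2^sub, co$clinical))
  expect_equal(s1$logrank_p, s3$logrank_p, tolerance = 1e-12)
  expect_equal(s1$rr, s3$rr, tolerance = 1e-12)
  expect_equal(s1$n_low + s1$n_high,
               rep(sum(!is.na(co$clinical$os_time)), nrow(s1)))
})

test_that("planted prognostic genes are flagged with the right direction", {
  cfg <- synth_config(n_normal = 0, n_grade2 = 100, n_grade3 = 100,
                      n_grade4 = 100)
  co <- generate_cohort(cfg, seed = 17)
  g <- co$truth$genes
  strong <- g$gene[g$module == "M1" &
                     g$loading >= stats::median(g$loading[g$module == "M1"])]
  sc <- suppressMessages(screen_survival(co$expr[strong, ], co$clinical))
  expect_gte(mean(sc$rr > 1 & sc$logrank_p < 0.001), 0.95)
})

test_that("cross-dataset consistency keeps shared-direction hits only", {
  sc <- data.frame(gene = c("a", "b", "c", "d"),
                   rr = c(2.0, 0.5, 2.0, 1.5), rr_defined = TRUE,
                   logrank_p = c(1e-5, 1e-5, 1e-5, 0.5),
                   cox_lrt_p = 1e-5, chisq_p = 1e-5)
  ident <- suppressMessages(cross_dataset_consistent(sc, sc))
  expect_setequal(ident$gene, c("a", "b", "c"))  # d fails the p gate

  sc2 <- sc; sc2$rr[1] <- 0.4  # direction flip for gene a
  expect_message(out <- cross_dataset_consistent(sc, sc2), "inconsistent")
  expect_setequal(out$gene, c("b", "c"))
  expect_equal(attr(out, "n_inconsistent"), 1)
  expect_equal(out$direction[out$gene == "b"], "protective")
})
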