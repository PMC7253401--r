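test_that("similarity follows the unsigned and signed transforms exactly", {
  v <- vectors_with_cor(-0.8, n = 40)
  expr <- rbind(g1 = v$x, g2 = v$y)
  colnames(expr) <- sprintf("s%02d", 1:40)
  expect_equal(cor(v$x, v$y), -0.8, tolerance = 1e-12)
  S_u <- similarity(expr, "unsigned")
  S_s <- similarity(expr, "signed")
  expect_equal(S_u["g1", "g2"], 0.8, tolerance = 1e-12)
  expect_equal(S_s["g1", "g2"], -0.8 / 2 + 0.5, tolerance = 1e-12)

  expr2 <- rbind(g1 = v$x, g2 = v$x)
  colnames(expr2) <- colnames(expr)
  expect_equal(similarity(expr2, "unsigned")["g1", "g2"], 1)
  expect_equal(similarity(expr2, "signed")["g1", "g2"], 1)

  expr3 <- rbind(g1 = v$x, flat = rep(2, 40))
  expect_error(similarity(expr3), "flat")
})

test_that("soft-threshold adjacency is an elementwise power", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(adjacency(S, 2)[1, 2], 0.25)
  S9 <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  expect_equal(adjacency(S9, 9)[1, 2], 0.9^9)
  expect_equal(adjacency(S, 1)[1, 2], 0.5)
  expect_error(adjacency(S, 0), "power")
})

test_that("scale-free fit sign convention follows the regression slope", {
  # weights w give k_i = w_i (sum(w) - w_i); two connectivity groups make
  # the two-bin log-log regression exactly collinear
  w <- c(rep(0.2, 30), rep(0.8, 5))
  A <- outer(w, w); diag(A) <- 1
  dimnames(A) <- list(paste0("g", 1:35), paste0("g", 1:35))
  fit <- scale_free_fit(A, n_bins = 2)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)  # more low-k genes
  expect_lt(fit$slope, 0)

  w2 <- c(rep(0.2, 5), rep(0.8, 30))  # frequency rises with k
  A2 <- outer(w2, w2); diag(A2) <- 1
  fit2 <- scale_free_fit(A2, n_bins = 2)
  expect_equal(fit2$r_squared, -1, tolerance = 1e-12)
  expect_gt(fit2$slope, 0)

  expect_error(scale_free_fit(matrix(0.5, 4, 4)), "degenerate")
})

test_that("binomial-degree random graphs are not scale-free", {
  bad <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    A <- matrix(rbinom(n * n, 1, 0.05), n, n)
    A <- 1 * ((A + t(A)) > 0); diag(A) <- 1
    fit <- scale_free_fit(A)
    if (fit$r_squared >= 0.9) bad <- bad + 1
  }
  expect_lte(bad, 1)  # Poisson-like degrees reach 0.9 in at most rare seeds
})

test_that("power selection returns the smallest qualifying power", {
  set.seed(3)
  expr <- matrix(rnorm(60 * 30), 60, 30,
                 dimnames = list(paste0("g", 1:60), paste0("s", 1:30)))
  res <- pick_power(expr, candidate_powers = 2:6, r2_min = 0)
  expect_equal(res$power, 2)  # all qualify; mean connectivity decreasing
  expect_true(all(diff(res$scan$mean_k) < 0))
})

test_that("power selection qualifies on planted cohorts and carries its scan", {
  co <- small_cohort()
  res <- pick_power(co$expr)
  expect_true(res$power %in% 1:20)
  expect_gte(res$scan$r_squared[res$scan$power == res$power], 0.9)

  # when no candidate reaches the fit threshold, the error carries the scan
  err <- tryCatch(pick_power(co$expr, r2_min = 0.999999),
                  error = function(e) e)
  expect_s3_class(err, "hubscreen_no_power")
  expect_true(is.data.frame(err$scan))
  expect_equal(nrow(err$scan), 20)
})

test_that("topological overlap matches hand evaluation and the loop oracle", {
  A <- matrix(1, 3, 3)
  expect_equal(tom(A)[1, 2], 1)  # (1 + 1) / (min(2,2) + 1 - 1)

  A0 <- diag(3)
  W0 <- tom(A0)
  expect_equal(diag(W0), rep(1, 3))
  expect_equal(W0[upper.tri(W0)], rep(0, 3))

  A1 <- random_adjacency(10, seed = 4)
  expect_lt(max(abs(tom(A1) - tom_oracle(A1))), 1e-12)
})

test_that("block-diagonal topological overlap recovers blocks exactly", {
  n <- 75
  W <- matrix(0, n, n)
  for (b in 0:2) {
    idx <- b * 25 + 1:25
    W[idx, idx] <- 0.9
  }
  diag(W) <- 1
  dimnames(W) <- list(paste0("g", 1:n), paste0("g", 1:n))
  asg <- detect_modules(W, min_module_size = 20)
  expect_setequal(unique(asg), c("M1", "M2", "M3"))
  expect_equal(unname(table(asg)), rep(25L, 3), ignore_attr = TRUE)
  # all genes of one block share one label
  expect_length(unique(asg[1:25]), 1)
})

test_that("all-noise cohorts are left almost entirely unassigned", {
  set.seed(6)
  expr <- matrix(rnorm(400 * 100), 400, 100,
                 dimnames = list(paste0("g", 1:400), paste0("s", 1:100)))
  W <- tom(adjacency(similarity(expr), 9))
  asg <- suppressWarnings(detect_modules(W, min_module_size = 20))
  expect_gte(mean(asg == "grey"), 0.9)
})

test_that("module eigengenes summarize members with the stated orientation", {
  set.seed(7)
  profile <- rnorm(30)
  expr <- matrix(rep(profile, each = 5), 5, 30) +
    matrix(rnorm(150, sd = 1e-6), 5, 30)
  rownames(expr) <- paste0("g", 1:5); colnames(expr) <- paste0("s", 1:30)
  asg <- setNames(rep("M1", 5), rownames(expr))
  me <- module_eigengenes(expr, asg)
  expect_equal(sum(me[, "M1"]^2), 1, tolerance = 1e-9)  # unit norm
  expect_equal(abs(cor(expr[1, ], me[, "M1"])), 1, tolerance = 1e-6)
  expect_gt(cor(expr[1, ], me[, "M1"]), 0)  # oriented along the members
  # negating every member negates the eigengene
  me_neg <- module_eigengenes(-expr, asg)
  expect_equal(me_neg[, "M1"], -me[, "M1"], tolerance = 1e-9)
})

test_that("eigengenes track the generating factor and survive reordering", {
  set.seed(8)
  n <- 500
  f <- rnorm(n)
  lam <- runif(40, 0.5, 0.9)
  expr <- sapply(seq_len(n), function(i) lam * f[i] +
                   sqrt(1 - lam^2) * rnorm(40))
  rownames(expr) <- paste0("g", 1:40); colnames(expr) <- paste0("s", 1:n)
  asg <- setNames(rep("M1", 40), rownames(expr))
  me <- module_eigengenes(expr, asg)
  expect_gte(abs(cor(me[, "M1"], f)), 0.95)
  perm <- sample(n)
  me_perm <- module_eigengenes(expr[, perm], asg)
  expect_equal(unname(me_perm[, "M1"]), unname(me[perm, "M1"]),
               tolerance = 1e-9)
})

test_that("module-trait correlation reproduces the analytic p-value", {
  set.seed(9)
  me <- cbind(M1 = scale(rnorm(30))[, 1])
  rownames(me) <- paste0("s", 1:30)
  tr <- data.frame(self = me[, "M1"], noise = rnorm(30))
  out <- module_trait_correlation(me, tr)
  self_row <- out[out$trait == "self", ]
  expect_equal(self_row$cor, 1, tolerance = 1e-12)
  expect_lt(self_row$p, 1e-200)

  # n = 3 with r = 0.5: t = 0.5 * sqrt(1 / 0.75), df = 1
  v <- vectors_with_cor(0.5, n = 3, seed = 2)
  me3 <- cbind(M1 = v$x); rownames(me3) <- paste0("s", 1:3)
  out3 <- module_trait_correlation(me3, data.frame(t = v$y))
  t_stat <- 0.5 * sqrt(1 / (1 - 0.25))
  expect_equal(out3$p, 2 * pt(-t_stat, df = 1), tolerance = 1e-10)
  expect_error(module_trait_correlation(me3, data.frame(k = rep(1, 3))),
               "constant")
})

test_that("membership and significance behave like correlations", {
  co <- small_cohort()
  sub <- co$expr[1:50, ]
  asg <- setNames(rep("M1", 50), rownames(sub))
  me <- module_eigengenes(sub, asg)
  # a synthetic gene equal to the eigengene profile has MM = 1
  expr2 <- rbind(sub, ME_GENE = me[, "M1"])
  mmgs <- membership_and_significance(expr2, me,
                                      grade_code(co$clinical$grade))
  expect_equal(unname(mmgs$mm["ME_GENE", "M1"]), 1, tolerance = 1e-9)
  expect_true(all(abs(mmgs$mm) <= 1 + 1e-12))
  expect_true(all(mmgs$gs_p >= 0 & mmgs$gs_p <= 1))

  # a gene orthogonal to grade has |GS| within null sampling range
  g <- grade_code(co$clinical$grade)
  ortho <- resid(lm(rnorm(length(g)) ~ g))
  mmgs2 <- membership_and_significance(rbind(sub, O = ortho), me, g)
  expect_lt(abs(mmgs2$gs["O"]), 0.2)
})

test_that("hub selection intersects the MM and GS top fractions", {
  genes <- paste0("g", sprintf("%02d", 1:10))
  mm <- matrix(seq(0.9, 0.0, length.out = 10), ncol = 1,
               dimnames = list(genes, "M1"))
  aligned <- list(mm = mm, gs = setNames(seq(0.9, 0.0, length.out = 10),
                                         genes))
  asg <- setNames(rep("M1", 10), genes)
  expect_equal(select_module_hubs(aligned, asg, "M1", 0.2),
               sort(genes[1:2]))  # rankings coincide: exactly ceil(0.2 * 10)

  anti <- list(mm = mm, gs = setNames(seq(0.0, 0.9, length.out = 10), genes))
  expect_length(select_module_hubs(anti, asg, "M1", 0.2), 0)

  expect_error(select_module_hubs(aligned, asg, "M9"), "absent")
  expect_error(select_module_hubs(aligned, asg, "M1", 0), "top_frac")
})

test_that("trait-module picking ranks by |r| with the stated tie rules", {
  tab <- data.frame(module = c("M1", "M2", "M3", "grey"),
                    trait = "grade",
                    cor = c(0.9, -0.9, 0.5, 0.95),
                    p = c(1e-8, 1e-9, 1e-3, 1e-20),
                    n = 100)
  out <- pick_trait_modules(tab, "grade", n_top = 2)
  # tie on |r| = 0.9 broken by smaller p; grey always excluded
  expect_equal(out, c("M2", "M1"))
  out3 <- suppressMessages(pick_trait_modules(tab, "grade", n_top = 4))
  expect_equal(out3, c("M2", "M1", "M3"))
  tab$p <- 0.5
  expect_message(res <- pick_trait_modules(tab, "grade", 4), "0 of 4")
  expect_length(res, 0)
})

test_that("subnetwork extraction applies the edge and node fractions", {
  W <- random_adjacency(10, seed = 11)
  # seed at an endpoint of the single strongest edge
  ut <- which(upper.tri(W), arr.ind = TRUE)
  top_edge <- ut[which.max(W[ut]), ]
  seeds <- rownames(W)[top_edge]
  sub <- extract_subnetwork(W, seeds, edge_top_frac = 0.01,
                            node_top_frac = 1)
  expect_equal(nrow(sub$edges), ceiling(0.01 * choose(10, 2)))  # 1 edge
  expect_equal(sub$edges$weight, max(W[upper.tri(W)]))

  # full fractions: graph restricted to seeds and their neighbours
  sub2 <- extract_subnetwork(W, seeds, edge_top_frac = 1, node_top_frac = 1)
  expect_setequal(sub2$nodes$gene, rownames(W))  # top edges touch everything

  # star graph: the hub has maximal connectivity
  n <- 6
  star <- diag(n)
  star[1, 2:n] <- star[2:n, 1] <- 0.9
  dimnames(star) <- list(paste0("g", 1:n), paste0("g", 1:n))
  sub3 <- extract_subnetwork(star, "g1", edge_top_frac = 1, node_top_frac = 1)
  expect_equal(sub3$nodes$gene[which.max(sub3$nodes$connectivity)], "g1")

  lone <- setdiff(rownames(W), seeds)[1]
  expect_warning(
    empty <- extract_subnetwork(W, lone, edge_top_frac = 0.01,
                                node_top_frac = 1),
    "no kept edge")
  expect_equal(nrow(empty$edges), 0)
  expect_error(extract_subnetwork(W, "missing"), "not in network")
})
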