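## Weighted co-expression network --------------------------------------------

#' Pairwise expression similarity
#'
#' Unsigned similarity is `|cor(x_i, x_j)|`; signed similarity is
#' `cor(x_i, x_j)/2 + 0.5`. Pearson correlation throughout.
#'
#' @param expr genes x samples matrix, no constant gene, at least 3 samples.
#' @param mode `"unsigned"` (default, the mode used by the screen) or
#'   `"signed"`.
#' @return similarity matrix with unit diagonal and a `mode` attribute.
#' @export
similarity <- function(expr, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (ncol(expr) < 3) stop("similarity needs at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("constant gene(s), correlation undefined: ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  r <- stats::cor(t(expr))
  S <- if (mode == "unsigned") abs(r) else r / 2 + 0.5
  diag(S) <- 1
  attr(S, "mode") <- mode
  S
}

#' Soft-threshold adjacency
#'
#' Raises the similarity matrix elementwise to an integer power, the soft
#' threshold that pushes the network towards scale-free topology.
#'
#' @param S similarity matrix.
#' @param power integer power, at least 1.
#' @return adjacency matrix (unit diagonal retained; connectivity computations
#'   ignore the diagonal).
#' @export
adjacency <- function(S, power) {
  if (length(power) != 1 || is.na(power) || power < 1)
    stop("power must be a single integer >= 1")
  A <- unclass(S)^power
  attr(A, "power") <- as.integer(power)
  A
}

#' Node connectivity
#'
#' Weighted degree `k_i = sum_{j != i} A_ij`.
#'
#' @param A adjacency matrix.
#' @return numeric vector of connectivities.
#' @export
connectivity <- function(A) {
  colSums(A) - diag(A)
}

#' Scale-free topology fit
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins and
#' regresses `log10(frequency)` on `log10(mean connectivity)` over non-empty
#' bins. Returns the R-squared signed by the negated slope sign, so a
#' scale-free (decreasing) degree law scores towards +1.
#'
#' @param A adjacency matrix.
#' @param n_bins number of connectivity bins (default 10).
#' @return list with `r_squared` (signed), `slope`, and the bin table.
#' @export
scale_free_fit <- function(A, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  k <- connectivity(A)
  if (diff(range(k)) == 0)
    stop("degenerate fit: all connectivities identical")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- pmin(findInterval(k, breaks), n_bins)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- vapply(seq_len(n_bins),
                  function(b) if (freq[b] > 0) mean(k[bin == b]) else NA_real_,
                  numeric(1))
  ok <- freq > 0 & kmean > 0
  if (sum(ok) < 2) stop("degenerate fit: fewer than 2 usable bins")
  x <- log10(kmean[ok]); y <- log10(freq[ok])
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r_squared = -sign(slope) * r2, slope = slope,
       bins = data.frame(k_mean = kmean, frequency = freq))
}

#' Select the soft-threshold power by scale-free fit
#'
#' Scans candidate powers; among those whose signed scale-free fit reaches
#' `r2_min`, the power with the largest mean connectivity (equivalently the
#' smallest qualifying power, since mean connectivity decreases strictly in
#' the power) is returned together with the full scan table.
#'
#' @param expr genes x samples matrix.
#' @param candidate_powers ascending integer powers to scan (default 1..20).
#' @param r2_min signed R-squared threshold (default 0.9).
#' @param mode similarity mode.
#' @param n_bins connectivity bins for the fit.
#' @return list with `power` and `scan` (power, r_squared, slope, mean_k,
#'   median_k).
#' @export
pick_power <- function(expr, candidate_powers = 1:20, r2_min = 0.9,
                       mode = "unsigned", n_bins = 10) {
  if (!length(candidate_powers)) stop("candidate_powers must be non-empty")
  if (is.unsorted(candidate_powers, strictly = TRUE))
    stop("candidate_powers must be strictly ascending")
  S <- similarity(expr, mode = mode)
  scan <- data.frame(power = candidate_powers, r_squared = NA_real_,
                     slope = NA_real_, mean_k = NA_real_, median_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    A <- adjacency(S, candidate_powers[i])
    k <- connectivity(A)
    scan$mean_k[i] <- mean(k)
    scan$median_k[i] <- stats::median(k)
    fit <- tryCatch(scale_free_fit(A, n_bins = n_bins), error = function(e) NULL)
    if (!is.null(fit)) {
      scan$r_squared[i] <- fit$r_squared
      scan$slope[i] <- fit$slope
    }
  }
  ok <- which(!is.na(scan$r_squared) & scan$r_squared >= r2_min)
  if (!length(ok)) {
    stop(errorCondition(
      paste0("no candidate power reaches signed R^2 >= ", r2_min),
      scan = scan, class = c("hubscreen_no_power", "error", "condition")))
  }
  best <- ok[which.max(scan$mean_k[ok])]
  list(power = scan$power[best], scan = scan)
}

#' Topological overlap matrix
#'
#' Unsigned topological overlap
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j`, and unit diagonal. Two genes
#' overlap strongly when they are connected and share neighbors.
#'
#' @param A adjacency matrix (entries in `[0, 1]`).
#' @return TOM matrix with unit diagonal.
#' @export
tom <- function(A) {
  A <- unclass(A)
  diag(A) <- 0
  L <- A %*% A          # includes u = i and u = j terms, which are 0 here
  k <- colSums(A)
  kmin <- outer(k, k, pmin)
  W <- (L + A) / (kmin + 1 - A)
  diag(W) <- 1
  dimnames(W) <- dimnames(A)
  W
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`.
#' The tree is cut at a single height chosen automatically: among candidate
#' heights (the merge heights), the one maximizing the number of clusters
#' with at least `min_module_size` members, taking the largest such height so
#' each module is as complete as possible before any module-module merge.
#' A fixed `cut_height` can be supplied instead. Clusters below
#' `min_module_size` are relabeled `"grey"`. When `expr` is supplied, modules
#' whose eigengene dissimilarity `1 - cor` falls below `merge_cut` are merged
#' iteratively. Surviving modules are labeled `M1, M2, ...` by decreasing
#' size.
#'
#' @param tom_mat TOM matrix.
#' @param min_module_size smallest retained module (default 20).
#' @param merge_cut eigengene-dissimilarity merge threshold (default 0.25);
#'   only applied when `expr` is given.
#' @param cut_height optional fixed cut height on the `1 - TOM` scale;
#'   `NULL` (default) selects the height automatically as described above.
#' @param cohesion a size-qualified cluster only becomes a module if its mean
#'   within-cluster dissimilarity is below `cohesion` times the mean overall
#'   dissimilarity; loose chains on structureless data stay grey.
#' @param expr optional genes x samples matrix for eigengene-based merging.
#' @return named character vector: gene -> module label (`"grey"` =
#'   unassigned).
#' @export
detect_modules <- function(tom_mat, min_module_size = 20, merge_cut = 0.25,
                           cut_height = NULL, cohesion = 0.95, expr = NULL) {
  n <- nrow(tom_mat)
  if (n < 2 * min_module_size)
    stop("need at least 2 * min_module_size genes")
  d <- stats::as.dist(1 - tom_mat)
  if (max(d) - min(d) < .Machine$double.eps^0.5) {
    warning("degenerate TOM (all dissimilarities equal): single module")
    return(stats::setNames(rep("M1", n), rownames(tom_mat)))
  }
  hc <- stats::hclust(d, method = "average")
  # guard against floating-point height inversions that break cutree
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  diss <- 1 - tom_mat
  mean_overall <- mean(diss[upper.tri(diss)])
  gate <- cohesion * mean_overall
  # count clusters that are both large and cohesive at one cut height
  n_modules_at <- function(cl) {
    sizes <- tabulate(cl)
    ok <- 0L
    for (lab in which(sizes >= min_module_size)) {
      idx <- which(cl == lab)
      k <- length(idx)
      if ((sum(diss[idx, idx]) / (k * (k - 1))) < gate) ok <- ok + 1L
    }
    ok
  }
  if (is.null(cut_height)) {
    hs <- unique(hc$height)
    if (length(hs) > 120)
      hs <- unique(stats::quantile(hc$height, seq(0, 1, length.out = 120),
                                   type = 1))
    cl_mat <- stats::cutree(hc, h = hs)
    if (is.null(dim(cl_mat))) cl_mat <- matrix(cl_mat, ncol = 1)
    counts <- apply(cl_mat, 2, n_modules_at)
    cut_height <- max(hs[counts == max(counts)])
  }
  cl <- stats::cutree(hc, h = cut_height)
  genes <- rownames(tom_mat)
  labels <- as.character(cl)
  sizes <- table(labels)
  labels[labels %in% names(sizes)[sizes < min_module_size]] <- "grey"
  # cohesion gate: a module must be tighter than the matrix at large
  for (lab in setdiff(unique(labels), "grey")) {
    idx <- which(labels == lab)
    k <- length(idx)
    if ((sum(diss[idx, idx]) / (k * (k - 1))) >= gate)
      labels[idx] <- "grey"
  }

  if (!is.null(expr) && length(setdiff(unique(labels), "grey")) > 1) {
    repeat {
      mods <- setdiff(unique(labels), "grey")
      if (length(mods) < 2) break
      me <- module_eigengenes(expr, stats::setNames(labels, genes))
      cc <- stats::cor(me)
      diss <- 1 - cc
      diag(diss) <- Inf
      if (min(diss) >= merge_cut) break
      idx <- which(diss == min(diss), arr.ind = TRUE)[1, ]
      a <- colnames(me)[idx[1]]; b <- colnames(me)[idx[2]]
      labels[labels == b] <- a
    }
  }

  mods <- setdiff(unique(labels), "grey")
  ord <- mods[order(-as.integer(table(factor(labels, levels = mods))[mods]),
                    mods)]
  relab <- stats::setNames(sprintf("M%d", seq_along(ord)), ord)
  out <- ifelse(labels == "grey", "grey", relab[labels])
  stats::setNames(out, genes)
}

#' Module eigengenes
#'
#' First principal component across samples of each module's gene-standardized
#' expression, scaled to unit norm and sign-oriented so that the summed
#' member-gene correlation is non-negative.
#'
#' @param expr genes x samples matrix.
#' @param assignment named gene -> module vector ([detect_modules()]).
#' @return samples x modules matrix of eigengene values.
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- setdiff(unique(assignment), "grey")
  if (!length(mods)) stop("no non-grey modules in assignment")
  me <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
               dimnames = list(colnames(expr), mods))
  for (m in mods) {
    genes <- names(assignment)[assignment == m]
    genes <- intersect(genes, rownames(expr))
    if (length(genes) < 2) stop("module ", m, " has fewer than 2 genes")
    X <- expr[genes, , drop = FALSE]
    sds <- apply(X, 1, stats::sd)
    if (any(sds == 0)) stop("constant gene in module ", m)
    Xs <- (X - rowMeans(X)) / sds
    sv <- svd(Xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (sum(Xs %*% v) < 0) v <- -v
    me[, m] <- v
  }
  me[, order(colnames(me)), drop = FALSE]
}

#' Module-trait correlations
#'
#' Pearson correlation between each module eigengene and each numeric
#' clinical trait, with the two-sided p-value from the t transform on `n - 2`
#' degrees of freedom. Missing trait values are dropped pairwise.
#'
#' @param me samples x modules eigengene matrix.
#' @param traits data frame of per-sample numeric traits, rows aligned to
#'   the eigengene rows.
#' @return data frame with module, trait, cor, p, n.
#' @export
module_trait_correlation <- function(me, traits) {
  traits <- as.data.frame(traits)
  out <- expand.grid(module = colnames(me), trait = names(traits),
                     stringsAsFactors = FALSE)
  out$cor <- NA_real_; out$p <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    tv <- traits[[out$trait[i]]]
    ok <- !is.na(tv)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for trait ", out$trait[i])
    if (stats::sd(tv[ok]) == 0) stop("constant trait: ", out$trait[i])
    r <- stats::cor(me[ok, out$module[i]], tv[ok])
    out$cor[i] <- r
    out$p[i] <- cor_pvalue(r, sum(ok))
    out$n[i] <- sum(ok)
  }
  out
}

#' Module membership and trait significance per gene
#'
#' Module membership (MM) is the Pearson correlation of each gene's profile
#' with each module eigengene; gene significance (GS) is its correlation with
#' the clinical trait. Both come with two-sided t-transform p-values.
#'
#' @param expr genes x samples matrix.
#' @param me samples x modules eigengene matrix.
#' @param trait numeric per-sample trait aligned to the samples.
#' @return list with matrices `mm`, `mm_p` (genes x modules) and vectors
#'   `gs`, `gs_p`.
#' @export
membership_and_significance <- function(expr, me, trait) {
  if (length(trait) != ncol(expr))
    stop("trait length must match the number of samples")
  if (stats::sd(trait, na.rm = TRUE) == 0) stop("constant trait")
  mm <- stats::cor(t(expr), me)
  gs <- as.numeric(stats::cor(t(expr), trait, use = "pairwise.complete.obs"))
  n <- ncol(expr)
  list(mm = mm, mm_p = cor_pvalue(mm, n),
       gs = stats::setNames(gs, rownames(expr)),
       gs_p = stats::setNames(cor_pvalue(gs, sum(!is.na(trait))),
                              rownames(expr)))
}

#' Select hub genes from chosen modules
#'
#' Within each chosen module, the top `ceiling(top_frac * size)` genes by
#' absolute module membership are intersected with the top
#' `ceiling(top_frac * size)` by absolute trait significance; the union over
#' modules is the hub set. The intersection makes the result at most
#' `top_frac` of the module genes, and typically fewer.
#'
#' @param mmgs a [membership_and_significance()] result.
#' @param assignment gene -> module vector.
#' @param chosen_modules module labels to harvest.
#' @param top_frac fraction of each module to rank (default 0.2).
#' @return character vector of hub gene ids.
#' @export
select_module_hubs <- function(mmgs, assignment, chosen_modules,
                               top_frac = 0.2) {
  if (!length(chosen_modules)) stop("chosen_modules must be non-empty")
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must lie in (0, 1]")
  missing_mod <- setdiff(chosen_modules, unique(assignment))
  if (length(missing_mod))
    stop("module(s) absent from assignment: ",
         paste(missing_mod, collapse = ", "))
  hubs <- character(0)
  for (m in chosen_modules) {
    genes <- names(assignment)[assignment == m]
    k <- ceiling(top_frac * length(genes))
    mm <- abs(mmgs$mm[genes, m])
    gs <- abs(mmgs$gs[genes])
    top_mm <- genes[order(-mm, genes)][seq_len(k)]
    top_gs <- genes[order(-gs, genes)][seq_len(k)]
    hubs <- union(hubs, intersect(top_mm, top_gs))
  }
  sort(hubs)
}

#' Pick the modules most correlated with a trait
#'
#' Ranks modules by absolute eigengene-trait correlation, keeps those with
#' `p < p_max`, excludes `"grey"`, and returns up to `n_top` labels. Ties in
#' absolute correlation break by smaller p, then label order.
#'
#' @param mt_table a [module_trait_correlation()] table.
#' @param trait trait name to rank on.
#' @param n_top number of modules to return (default 4).
#' @param p_max significance gate (default 0.05).
#' @return character vector of module labels (may be shorter than `n_top`).
#' @export
pick_trait_modules <- function(mt_table, trait, n_top = 4, p_max = 0.05) {
  tab <- mt_table[mt_table$trait == trait & mt_table$module != "grey", ]
  if (!nrow(tab)) stop("trait not present in module-trait table: ", trait)
  tab <- tab[tab$p < p_max, ]
  tab <- tab[order(-abs(tab$cor), tab$p, tab$module), ]
  out <- utils::head(tab$module, n_top)
  if (length(out) < n_top)
    message("pick_trait_modules: only ", length(out), " of ", n_top,
            " requested modules reach p < ", p_max)
  out
}

#' Extract a key-gene subnetwork from the TOM
#'
#' Keeps the globally top `edge_top_frac` of edges by TOM weight, takes the
#' seed genes plus their neighbors in that thresholded graph, ranks the nodes
#' by within-subgraph weighted connectivity and retains the top
#' `node_top_frac`.
#'
#' @param tom_mat TOM matrix.
#' @param seed_genes genes to grow the subnetwork from (must be in the
#'   network).
#' @param edge_top_frac fraction of all gene pairs kept as edges (default
#'   0.01).
#' @param node_top_frac fraction of subgraph nodes retained (default 0.3).
#' @return list with `edges` (gene_a, gene_b, weight) and `nodes`
#'   (gene, connectivity).
#' @export
extract_subnetwork <- function(tom_mat, seed_genes, edge_top_frac = 0.01,
                               node_top_frac = 0.3) {
  genes <- rownames(tom_mat)
  missing_g <- setdiff(seed_genes, genes)
  if (length(missing_g))
    stop("seed gene(s) not in network: ", paste(missing_g, collapse = ", "))
  ut <- which(upper.tri(tom_mat), arr.ind = TRUE)
  w <- tom_mat[ut]
  n_keep <- ceiling(edge_top_frac * nrow(ut))
  ord <- order(-w, ut[, 1], ut[, 2])[seq_len(n_keep)]
  edges <- data.frame(gene_a = genes[ut[ord, 1]], gene_b = genes[ut[ord, 2]],
                      weight = w[ord], stringsAsFactors = FALSE)
  touch <- edges$gene_a %in% seed_genes | edges$gene_b %in% seed_genes
  if (!any(touch)) {
    warning("no kept edge touches a seed gene; empty subnetwork")
    return(list(edges = edges[0, ],
                nodes = data.frame(gene = character(0),
                                   connectivity = numeric(0))))
  }
  nb <- unique(c(edges$gene_a[touch], edges$gene_b[touch]))
  sub_nodes <- union(seed_genes, nb)
  sub_edges <- edges[edges$gene_a %in% sub_nodes & edges$gene_b %in% sub_nodes, ]
  conn <- stats::setNames(numeric(length(sub_nodes)), sub_nodes)
  for (i in seq_len(nrow(sub_edges))) {
    conn[sub_edges$gene_a[i]] <- conn[sub_edges$gene_a[i]] + sub_edges$weight[i]
    conn[sub_edges$gene_b[i]] <- conn[sub_edges$gene_b[i]] + sub_edges$weight[i]
  }
  n_nodes <- ceiling(node_top_frac * length(sub_nodes))
  keep <- names(conn)[order(-conn, names(conn))][seq_len(n_nodes)]
  kept_edges <- sub_edges[sub_edges$gene_a %in% keep &
                            sub_edges$gene_b %in% keep, ]
  rownames(kept_edges) <- NULL
  list(edges = kept_edges,
       nodes = data.frame(gene = keep, connectivity = unname(conn[keep]),
                          stringsAsFactors = FALSE))
}
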