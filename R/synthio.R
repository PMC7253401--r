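## Synthetic cohort generator -------------------------------------------------
##
## Latent-factor model of a glioma-like expression cohort. Each module m has a
## per-sample factor f_m = alpha_m * z + sqrt(1 - alpha_m^2) * eps, where z is
## the standardized WHO-grade code. A member gene g with loading lambda_g is
## x_g = lambda_g * f_m + sqrt(1 - lambda_g^2) * noise + delta_g * steps + mu_g,
## with `steps` the malignancy step count (II -> III -> IV) so the planted
## per-contrast log2 fold change is delta_g. Survival times for tumor samples
## are exponential with hazard h0 * exp(beta_s * z_t + gamma * f_prog),
## administratively censored at C; z_t is standardized over tumors only.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a glioma cohort of 200 samples (20 normal brain, 60 each
#' WHO II/III/IV) measured on a log2-like continuous scale, with 6 latent
#' co-expression modules of 100 genes plus 600 background genes. Four modules
#' track WHO grade (correlations 0.6, -0.5, 0.45, -0.35); module 1 additionally
#' carries a prognostic hazard. Genes in grade-linked modules shift by
#' `grade_shift` log2 units per malignancy step, signed like their module's
#' grade correlation.
#'
#' @param n_normal,n_grade2,n_grade3,n_grade4 sample counts per grade class.
#' @param n_modules number of latent modules.
#' @param genes_per_module genes per module.
#' @param n_background pure-noise background genes.
#' @param module_grade_cor numeric vector (length `n_modules`) of module-factor
#'   vs grade correlations, in `[-1, 1]`.
#' @param loading_range range `(min, max)` in `(0, 1)` for gene loadings.
#' @param loading_shape shape of the loading density within the range: with
#'   `u ~ U(0, 1)`, loadings are `min + (max - min) * u^loading_shape`, so
#'   values above 1 concentrate genes at low loadings with a thin
#'   high-loading (hub) tail, the connectivity profile real co-expression
#'   modules show.
#' @param grade_shift scale of the planted expression shift per malignancy
#'   step (log2 units) for genes in grade-linked modules; each gene's shift
#'   is `grade_shift * loading`, signed like the module's grade correlation,
#'   so strongly loaded genes are also the most grade-responsive (the
#'   module-membership vs trait-significance coupling trait-linked modules
#'   show in practice).
#' @param noise_sd standard deviation, in log2 units, of the latent
#'   (module factor + gene noise) part of each expression profile. Strongly
#'   variable tumor transcripts span several log2 units; the default 2.5 keeps
#'   planted fold changes of 1--2 log2 units from dominating every module
#'   gene's variance.
#' @param hub_frac top-loading fraction of each module designated planted hubs.
#' @param baseline_range range of per-gene baseline expression (log2 units).
#' @param baseline_hazard exponential baseline hazard (events per time unit).
#' @param grade_log_hazard log hazard ratio per SD of tumor grade.
#' @param prognostic_module index of the module whose factor enters the hazard.
#' @param prognostic_log_hazard log hazard ratio per unit of the prognostic
#'   module factor.
#' @param censoring_time administrative censoring time (time units).
#' @param seed default integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_normal = 20L, n_grade2 = 60L, n_grade3 = 60L,
                         n_grade4 = 60L,
                         n_modules = 6L, genes_per_module = 100L,
                         n_background = 600L,
                         module_grade_cor = c(0.6, -0.5, 0.45, -0.35, 0, 0),
                         loading_range = c(0.6, 0.95),
                         loading_shape = 1,
                         grade_shift = 2.0,
                         noise_sd = 2.5,
                         hub_frac = 0.2,
                         baseline_range = c(5, 11),
                         baseline_hazard = 0.1,
                         grade_log_hazard = 1.0,
                         prognostic_module = 1L,
                         prognostic_log_hazard = 0.6,
                         censoring_time = 10,
                         seed = 1L) {
  cfg <- list(n_normal = as.integer(n_normal), n_grade2 = as.integer(n_grade2),
              n_grade3 = as.integer(n_grade3), n_grade4 = as.integer(n_grade4),
              n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              n_background = as.integer(n_background),
              module_grade_cor = as.numeric(module_grade_cor),
              loading_range = as.numeric(loading_range),
              loading_shape = as.numeric(loading_shape),
              grade_shift = as.numeric(grade_shift),
              noise_sd = as.numeric(noise_sd),
              hub_frac = as.numeric(hub_frac),
              baseline_range = as.numeric(baseline_range),
              baseline_hazard = as.numeric(baseline_hazard),
              grade_log_hazard = as.numeric(grade_log_hazard),
              prognostic_module = as.integer(prognostic_module),
              prognostic_log_hazard = as.numeric(prognostic_log_hazard),
              censoring_time = as.numeric(censoring_time),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_normal, cfg$n_grade2, cfg$n_grade3, cfg$n_grade4,
              cfg$n_modules, cfg$genes_per_module, cfg$n_background)
  if (any(counts < 0) || any(is.na(counts)))
    stop("synth_config: all counts must be non-negative")
  n_total <- cfg$n_normal + cfg$n_grade2 + cfg$n_grade3 + cfg$n_grade4
  if (n_total < 4) stop("synth_config: need at least 4 samples in total")
  if (cfg$n_modules * cfg$genes_per_module + cfg$n_background < 2)
    stop("synth_config: need at least 2 genes in total")
  if (length(cfg$module_grade_cor) != cfg$n_modules)
    stop("synth_config: module_grade_cor must have one entry per module")
  if (any(abs(cfg$module_grade_cor) > 1))
    stop("synth_config: module_grade_cor entries must lie in [-1, 1]")
  lr <- cfg$loading_range
  if (length(lr) != 2 || lr[1] >= lr[2] || lr[1] <= 0 || lr[2] >= 1)
    stop("synth_config: loading_range must satisfy 0 < min < max < 1")
  if (cfg$loading_shape <= 0) stop("synth_config: loading_shape must be > 0")
  if (cfg$noise_sd <= 0) stop("synth_config: noise_sd must be > 0")
  if (cfg$baseline_hazard <= 0) stop("synth_config: baseline_hazard must be > 0")
  if (cfg$censoring_time <= 0) stop("synth_config: censoring_time must be > 0")
  if (cfg$n_modules > 0 &&
      (cfg$prognostic_module < 1 || cfg$prognostic_module > cfg$n_modules))
    stop("synth_config: prognostic_module out of range")
  invisible(cfg)
}

#' Draw the planted ground truth for a configuration
#'
#' Assigns genes to modules, draws loadings uniformly over `loading_range`,
#' designates the top-loading `hub_frac` of each module as planted hubs, and
#' records planted per-step log2 fold changes and the prognostic gene set.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `genes` (per-gene table), `modules` (per-module table)
#'   and the `config`.
#' @export
make_ground_truth <- function(config, seed = config$seed) {
  validate_synth_config(config)
  with_seed(seed, {
    n_mod_genes <- config$n_modules * config$genes_per_module
    n_genes <- n_mod_genes + config$n_background
    gene <- sprintf("G%05d", seq_len(n_genes))
    module <- c(rep(sprintf("M%d", seq_len(config$n_modules)),
                    each = config$genes_per_module),
                rep("background", config$n_background))
    alpha_by_mod <- stats::setNames(config$module_grade_cor,
                                    sprintf("M%d", seq_len(config$n_modules)))
    loading <- rep(NA_real_, n_genes)
    if (n_mod_genes > 0) {
      u <- stats::runif(n_mod_genes)
      loading[seq_len(n_mod_genes)] <- config$loading_range[1] +
        diff(config$loading_range) * u^config$loading_shape
    }
    alpha <- ifelse(module == "background", 0, alpha_by_mod[module])
    de_direction <- ifelse(module == "background", 0L, as.integer(sign(alpha)))
    step_lfc <- de_direction * config$grade_shift *
      ifelse(is.na(loading), 0, loading)
    is_hub <- rep(FALSE, n_genes)
    for (m in names(alpha_by_mod)) {
      idx <- which(module == m)
      if (!length(idx)) next
      n_hub <- ceiling(config$hub_frac * length(idx))
      is_hub[idx[order(-loading[idx])][seq_len(n_hub)]] <- TRUE
    }
    baseline <- stats::runif(n_genes, config$baseline_range[1],
                             config$baseline_range[2])
    prog_label <- sprintf("M%d", config$prognostic_module)
    prognostic <- module == prog_label & config$prognostic_log_hazard != 0
    hazard_direction <- integer(n_genes)
    # Marginal hazard association of a gene: the grade route
    # (beta_s * alpha_m * lambda) plus, for the prognostic module, the direct
    # factor route (gamma * lambda).
    route <- config$grade_log_hazard * alpha * ifelse(is.na(loading), 0, loading) +
      ifelse(module == prog_label, config$prognostic_log_hazard, 0) *
        ifelse(is.na(loading), 0, loading)
    hazard_direction <- as.integer(sign(route))
    genes <- data.frame(gene = gene, module = module, loading = loading,
                        alpha = as.numeric(alpha),
                        de_direction = de_direction, step_lfc = step_lfc,
                        baseline = baseline, is_hub = is_hub,
                        prognostic = prognostic,
                        hazard_direction = hazard_direction,
                        stringsAsFactors = FALSE)
    modules <- data.frame(module = names(alpha_by_mod),
                          alpha = as.numeric(alpha_by_mod),
                          prognostic = names(alpha_by_mod) == prog_label &
                            config$prognostic_log_hazard != 0,
                          stringsAsFactors = FALSE)
    list(genes = genes, modules = modules, config = config)
  })
}

# One cohort draw from a fixed ground truth.
draw_cohort <- function(truth, seed, prefix = "S") {
  cfg <- truth$config
  with_seed(seed, {
    grade <- rep(c("normal", "II", "III", "IV"),
                 times = c(cfg$n_normal, cfg$n_grade2, cfg$n_grade3,
                           cfg$n_grade4))
    n <- length(grade)
    sample_id <- sprintf("%s%04d", prefix, seq_len(n))
    code <- grade_code(grade)
    steps <- grade_steps(grade)
    z_all <- if (stats::sd(code) > 0) as.numeric(scale(code)) else rep(0, n)

    alpha <- truth$modules$alpha
    n_mod <- cfg$n_modules
    factors <- matrix(0, nrow = max(n_mod, 1), ncol = n)
    for (m in seq_len(n_mod)) {
      factors[m, ] <- alpha[m] * z_all +
        sqrt(1 - alpha[m]^2) * stats::rnorm(n)
    }

    g <- truth$genes
    n_genes <- nrow(g)
    expr <- matrix(stats::rnorm(n_genes * n), nrow = n_genes)
    mod_idx <- match(g$module, truth$modules$module)  # NA for background
    for (i in seq_len(n_genes)) {
      if (!is.na(mod_idx[i])) {
        lam <- g$loading[i]
        expr[i, ] <- cfg$noise_sd * (lam * factors[mod_idx[i], ] +
          sqrt(1 - lam^2) * expr[i, ]) + g$step_lfc[i] * steps
      }
    }
    bg <- is.na(mod_idx)
    if (any(bg)) expr[bg, ] <- cfg$noise_sd * expr[bg, , drop = FALSE]
    expr <- expr + g$baseline
    dimnames(expr) <- list(g$gene, sample_id)

    tumor <- grade != "normal"
    os_time <- rep(NA_real_, n)
    os_event <- rep(NA_integer_, n)
    if (any(tumor)) {
      code_t <- code[tumor]
      z_t <- if (stats::sd(code_t) > 0) as.numeric(scale(code_t)) else
        rep(0, sum(tumor))
      lin <- cfg$grade_log_hazard * z_t
      if (n_mod > 0)
        lin <- lin + cfg$prognostic_log_hazard *
          factors[cfg$prognostic_module, tumor]
      rate <- cfg$baseline_hazard * exp(lin)
      t_raw <- stats::rexp(sum(tumor), rate = rate)
      os_event[tumor] <- as.integer(t_raw <= cfg$censoring_time)
      os_time[tumor] <- pmin(t_raw, cfg$censoring_time)
    }
    age <- round(40 + 3 * code + stats::rnorm(n, 0, 8))
    clinical <- data.frame(sample_id = sample_id, grade = grade,
                           os_time = os_time, os_event = os_event, age = age,
                           stringsAsFactors = FALSE)
    list(expr = expr, clinical = clinical)
  })
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the same seed reproduces the cohort bit for bit.
#' @param truth optional pre-drawn [make_ground_truth()] result, to share one
#'   truth across several cohorts; when `NULL` it is drawn from `seed`.
#' @param prefix sample-id prefix.
#' @return list with `expr` (genes x samples log2 matrix), `clinical`
#'   (sample_id, grade, os_time, os_event, age) and `truth`.
#' @export
generate_cohort <- function(config, seed = config$seed, truth = NULL,
                            prefix = "S") {
  validate_synth_config(config)
  if (is.null(truth)) truth <- make_ground_truth(config, seed)
  cohort <- draw_cohort(truth, seed = seed + 1L, prefix = prefix)
  cohort$truth <- truth
  cohort
}

#' Generate two cohorts sharing one ground truth
#'
#' Emulates a discovery/replication pair: the same planted modules, loadings
#' and effect sizes, with independent sampling noise and disjoint sample ids.
#'
#' @inheritParams generate_cohort
#' @return list with `truth`, `cohort_a` and `cohort_b`.
#' @export
generate_paired_cohorts <- function(config, seed = config$seed) {
  validate_synth_config(config)
  truth <- make_ground_truth(config, seed)
  list(truth = truth,
       cohort_a = c(draw_cohort(truth, seed = seed + 1L, prefix = "A"),
                    list(truth = truth)),
       cohort_b = c(draw_cohort(truth, seed = seed + 2L, prefix = "B"),
                    list(truth = truth)))
}

#' Planted hub genes of a ground truth
#' @param truth a [make_ground_truth()] result.
#' @return character vector of gene ids.
#' @export
planted_hubs <- function(truth) truth$genes$gene[truth$genes$is_hub]

#' Genes planted as simultaneously hub, differentially expressed and prognostic
#'
#' The reference set for end-to-end recovery: planted hubs whose planted
#' per-step log2 fold change exceeds the screening threshold and whose
#' expression carries a marginal hazard association (through the grade route
#' or the prognostic module factor).
#'
#' @param truth a [make_ground_truth()] result.
#' @param lfc_min planted per-step log2FC threshold (strict).
#' @return character vector of gene ids.
#' @export
planted_key_genes <- function(truth, lfc_min = 1) {
  g <- truth$genes
  g$gene[g$is_hub & abs(g$step_lfc) > lfc_min & g$hazard_direction != 0]
}

#' Write a cohort to plain-text files
#'
#' Expression as TSV (first column `gene`, header row of sample ids),
#' clinical as CSV, and the ground-truth gene table as a CSV sidecar.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  write_expression(cohort$expr, paths[["expr"]])
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth$genes, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
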