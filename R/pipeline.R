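## End-to-end pipeline --------------------------------------------------------

#' Default pipeline configuration
#'
#' Every screening threshold is a named key carrying the screen's standard
#' value: 30/70 survival split, `P < 0.001` throughout, `|log2FC| > 1`,
#' top-20% hub selection, scale-free fit threshold 0.9, top-1% subnetwork
#' edges with the top-30% nodes, and four trait modules.
#'
#' @param ... overrides for any configuration key.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    synth = synth_config(),
    discovery_expr = NULL, discovery_clinical = NULL,
    replication_expr = NULL, replication_clinical = NULL,
    validation_expr = NULL, validation_clinical = NULL,
    quantile_normalization = TRUE,
    min_mean = 1, min_variance = 1e-8,
    outlier_height = NULL, outlier_linkage = "average",
    candidate_powers = 1:20, r2_min = 0.9, network_mode = "unsigned",
    min_module_size = 20, merge_cut = 0.25, cut_height = NULL,
    cohesion = 0.95,
    n_top_modules = 4,
    top_frac = 0.2,
    p_max = 0.001, lfc_min = 1, chisq_bins = 3,
    low_frac = 0.3,
    survival_test = "logrank", report_test = "cox",
    edge_top_frac = 0.01, node_top_frac = 0.3)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown pipeline configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_config()] defaults. A
#'   `synth` mapping is passed to [synth_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) raw$synth <- do.call(synth_config, raw$synth)
  do.call(pipeline_config, raw)
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$discovery_expr)) {
    read_pair <- function(e, c) list(expr = read_expression(e),
                                     clinical = read_clinical(c))
    list(
      discovery = read_pair(cfg$discovery_expr, cfg$discovery_clinical),
      replication = read_pair(cfg$replication_expr, cfg$replication_clinical),
      validation = read_pair(cfg$validation_expr, cfg$validation_clinical),
      truth = NULL)
  } else {
    truth <- make_ground_truth(cfg$synth, seed = cfg$seed)
    tumor_cfg <- cfg$synth
    tumor_cfg$n_normal <- 0L
    tumor_truth <- truth
    tumor_truth$config <- tumor_cfg
    list(
      discovery = draw_cohort(truth, seed = cfg$seed + 1L, prefix = "GEO"),
      replication = draw_cohort(tumor_truth, seed = cfg$seed + 2L,
                                prefix = "SEQ"),
      validation = draw_cohort(tumor_truth, seed = cfg$seed + 3L,
                               prefix = "ARR"),
      truth = truth)
  }
}

#' Run the full hub-gene screen
#'
#' Drives the whole screen over a discovery cohort (with normal samples;
#' source of the co-expression network, the hub set A and the DEG set B), a
#' replication cohort (grade-monotone DEG set D and the first survival
#' screen) and a validation cohort (the second survival screen), then
#' intersects A, B and D into the key-gene report, annotated with
#' survival-set (C) membership, per-step fold changes, survival statistics,
#' subnetwork connectivity and diagnostic AUC.
#'
#' With no input files configured, cohorts are simulated from one shared
#' planted ground truth. When `out_dir` is set, all result tables, the
#' network scan, the subnetwork edge list, a machine-readable summary and a
#' run log are written there; reruns with the same configuration and seed
#' reproduce them byte for byte.
#'
#' @param config a [pipeline_config()] list, a YAML path, or `NULL` for the
#'   defaults.
#' @return list with the key-gene `report`, the result sets, the network
#'   objects, the `summary` list, and (synthetic runs) the ground `truth`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (is.null(config)) pipeline_config()
  else if (is.character(config)) read_pipeline_config(config)
  else config
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message("[pipeline] ", line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(cfg$out_dir)) {
        dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(
          list(failed_stage = name, error = conditionMessage(e),
               artifacts = list.files(cfg$out_dir)),
          file.path(cfg$out_dir, "manifest.json"), auto_unbox = TRUE)
      }
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  note("seed = ", cfg$seed)
  inputs <- stage("inputs", load_pipeline_inputs(cfg))
  note("cohorts: discovery ", ncol(inputs$discovery$expr),
       " samples, replication ", ncol(inputs$replication$expr),
       ", validation ", ncol(inputs$validation$expr))

  prep <- function(cohort, qn) {
    e <- cohort$expr
    if (qn) e <- quantile_normalize(e)
    cl <- suppressMessages(clean_genes_samples(e, cfg$min_mean, cfg$min_variance))
    e <- cl$expr
    removed <- character(0)
    if (!is.null(cfg$outlier_height)) {
      ro <- suppressMessages(remove_outlier_samples(e, cfg$outlier_height,
                                                    cfg$outlier_linkage))
      e <- ro$expr
      removed <- ro$removed_samples
    }
    al <- suppressMessages(align_cohort(e, cohort$clinical))
    list(expr = al$expr, clinical = al$clinical,
         removed_genes = cl$removed_genes, removed_outliers = removed)
  }
  # quantile normalization applies to the microarray-style cohorts
  # (discovery and validation); the replication cohort plays the part of
  # RNA-seq FPKM data and is left as supplied.
  disc <- stage("io_prep", prep(inputs$discovery, cfg$quantile_normalization))
  repl <- stage("io_prep", prep(inputs$replication, FALSE))
  vali <- stage("io_prep", prep(inputs$validation, cfg$quantile_normalization))
  note("prep: discovery ", nrow(disc$expr), " genes x ", ncol(disc$expr),
       " samples after cleaning")

  ## --- co-expression network on the discovery cohort (result A)
  net <- stage("coexnet", {
    pw <- pick_power(disc$expr, cfg$candidate_powers, cfg$r2_min,
                     cfg$network_mode)
    S <- similarity(disc$expr, cfg$network_mode)
    A <- adjacency(S, pw$power)
    W <- tom(A)
    assignment <- detect_modules(W, cfg$min_module_size, cfg$merge_cut,
                                 cfg$cut_height, cfg$cohesion,
                                 expr = disc$expr)
    me <- module_eigengenes(disc$expr, assignment)
    traits <- data.frame(grade = grade_code(disc$clinical$grade),
                         age = disc$clinical$age)
    mt <- module_trait_correlation(me, traits)
    chosen <- suppressMessages(
      pick_trait_modules(mt, "grade", cfg$n_top_modules))
    mmgs <- membership_and_significance(disc$expr, me,
                                        grade_code(disc$clinical$grade))
    hubs <- select_module_hubs(mmgs, assignment, chosen, cfg$top_frac)
    list(power = pw$power, scan = pw$scan, tom = W, assignment = assignment,
         eigengenes = me, module_trait = mt, chosen_modules = chosen,
         mmgs = mmgs, result_a = hubs)
  })
  note("network: power ", net$power, ", ",
       length(setdiff(unique(net$assignment), "grey")), " modules, ",
       "chosen: ", paste(net$chosen_modules, collapse = ", "),
       "; |A| = ", length(net$result_a))

  ## --- differential expression (results B and D)
  result_b <- stage("degstats", suppressMessages(
    build_result_b(disc$expr, disc$clinical, cfg$p_max, cfg$lfc_min,
                   cfg$p_max, cfg$chisq_bins)))
  result_d <- stage("degstats", suppressMessages(
    build_result_d(repl$expr, repl$clinical, cfg$p_max, cfg$lfc_min)))
  note("DEG: |B| = ", nrow(result_b), ", |D| = ", nrow(result_d))

  ## --- survival screens (result C)
  survc <- stage("survstats", {
    if (all(is.na(repl$clinical$os_time)) || all(is.na(vali$clinical$os_time)))
      stop("survival columns missing from replication/validation cohorts")
    sx <- suppressMessages(screen_survival(repl$expr, repl$clinical,
                                           cfg$low_frac, cfg$p_max,
                                           cfg$survival_test))
    sy <- suppressMessages(screen_survival(vali$expr, vali$clinical,
                                           cfg$low_frac, cfg$p_max,
                                           cfg$survival_test))
    cc <- suppressMessages(cross_dataset_consistent(sx, sy, cfg$p_max,
                                                    cfg$p_max,
                                                    cfg$survival_test))
    list(screen_x = sx, screen_y = sy, result_c = cc)
  })
  note("survival: |C| = ", nrow(survc$result_c))

  ## --- intersection and report
  report <- stage("integrate", {
    key <- Reduce(intersect, list(net$result_a, result_b$gene, result_d$gene))
    subnet_genes <- names(net$assignment)[
      net$assignment %in% net$chosen_modules]
    conn <- NULL
    if (length(key)) {
      sub <- suppressWarnings(extract_subnetwork(
        net$tom[subnet_genes, subnet_genes],
        intersect(key, subnet_genes),
        cfg$edge_top_frac, cfg$node_top_frac))
      conn <- stats::setNames(sub$nodes$connectivity, sub$nodes$gene)
    } else {
      sub <- list(edges = data.frame(), nodes = data.frame())
    }
    rep <- intersect_results(net$result_a, result_b$gene,
                             survc$result_c$gene, result_d$gene,
                             deg_d = result_d, screen = survc$screen_x,
                             connectivity = conn, test = cfg$report_test)
    # diagnostic AUC (tumor vs normal on the discovery cohort)
    grade_disc <- normalize_grade(disc$clinical$grade)
    if (any(grade_disc == "normal") && nrow(rep)) {
      rep$auc <- vapply(rep$gene, function(g)
        roc_auc(disc$expr[g, ], ifelse(grade_disc == "normal",
                                       "normal", "tumor"), "tumor"),
        numeric(1))
    }
    list(report = rep, subnetwork = sub)
  })
  note("key genes: ", nrow(report$report))

  summary <- list(
    seed = cfg$seed,
    power = net$power,
    n_modules = length(setdiff(unique(net$assignment), "grey")),
    chosen_modules = net$chosen_modules,
    counts = list(result_a = length(net$result_a),
                  result_b = nrow(result_b),
                  result_c = nrow(survc$result_c),
                  result_d = nrow(result_d),
                  key_genes = nrow(report$report)),
    key_genes = report$report$gene,
    key_genes_in_c = sum(report$report$in_c),
    thresholds = cfg[c("p_max", "lfc_min", "low_frac", "top_frac", "r2_min",
                       "edge_top_frac", "node_top_frac", "n_top_modules")])

  if (!is.null(cfg$out_dir)) {
    stage("write", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      wcsv <- function(x, f) utils::write.csv(
        x, file.path(cfg$out_dir, f), row.names = FALSE)
      wcsv(data.frame(gene = net$result_a), "result_a.csv")
      wcsv(result_b, "result_b.csv")
      wcsv(survc$result_c, "result_c.csv")
      wcsv(result_d, "result_d.csv")
      wcsv(report$report, "key_gene_report.csv")
      wcsv(data.frame(gene = names(net$assignment),
                      module = unname(net$assignment)),
           "module_assignment.csv")
      wcsv(net$scan, "power_scan.csv")
      wcsv(net$module_trait, "module_trait.csv")
      if (nrow(report$subnetwork$edges))
        utils::write.table(report$subnetwork$edges,
                           file.path(cfg$out_dir, "subnetwork_edges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
    })
  }

  list(report = report$report, subnetwork = report$subnetwork,
       result_a = net$result_a, result_b = result_b,
       result_c = survc$result_c, result_d = result_d,
       screens = survc[c("screen_x", "screen_y")],
       network = net[c("power", "scan", "assignment", "eigengenes",
                       "module_trait", "chosen_modules")],
       truth = inputs$truth, summary = summary, config = cfg)
}
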