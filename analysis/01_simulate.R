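#!/usr/bin/env Rscript
# Simulate the three study cohorts from one shared planted ground truth:
# a discovery cohort with normal brain samples (microarray-style, the
# network/DEG discovery set), a tumor-only replication cohort (RNA-seq
# style) and a tumor-only validation cohort (microarray style), mirroring
# the shapes of the real discovery/replication glioma series. Writes
# plain-text cohorts under results/cohorts/.

suppressMessages(library(hubscreen))

seed <- 1L
cfg <- synth_config()
truth <- make_ground_truth(cfg, seed = seed)
tumor_cfg <- cfg; tumor_cfg$n_normal <- 0L
tumor_truth <- truth; tumor_truth$config <- tumor_cfg

cohorts <- list(
  discovery = hubscreen:::draw_cohort(truth, seed = seed + 1L, prefix = "GEO"),
  replication = hubscreen:::draw_cohort(tumor_truth, seed = seed + 2L,
                                        prefix = "SEQ"),
  validation = hubscreen:::draw_cohort(tumor_truth, seed = seed + 3L,
                                       prefix = "ARR"))

for (nm in names(cohorts)) {
  co <- cohorts[[nm]]
  co$truth <- truth
  paths <- write_cohort(co, file.path("results", "cohorts", nm))
  message(nm, ": ", nrow(co$expr), " genes x ", ncol(co$expr),
          " samples -> ", dirname(paths[[1]]))
}
message("planted: ", sum(truth$genes$is_hub), " hubs, ",
        sum(abs(truth$genes$step_lfc) > 1), " genes with |log2FC|/step > 1, ",
        sum(truth$genes$prognostic), " prognostic-module genes")
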