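#!/usr/bin/env Rscript
# Read the simulated cohorts back from disk, quantile-normalize the
# microarray-style ones (discovery, validation), drop near-zero genes and
# samples, and save the cleaned matrices for the downstream stages.

suppressMessages(library(hubscreen))

dir.create("results/prepared", showWarnings = FALSE, recursive = TRUE)
for (nm in c("discovery", "replication", "validation")) {
  expr <- read_expression(file.path("results/cohorts", nm, "expression.tsv"))
  clin <- read_clinical(file.path("results/cohorts", nm, "clinical.csv"))
  if (nm != "replication") expr <- quantile_normalize(expr)
  cl <- clean_genes_samples(expr, min_mean = 1, min_variance = 1e-8)
  al <- align_cohort(cl$expr, clin)
  write_expression(al$expr, file.path("results/prepared",
                                      paste0(nm, "_expression.tsv")))
  write.csv(al$clinical, file.path("results/prepared",
                                   paste0(nm, "_clinical.csv")),
            row.names = FALSE)
  message(nm, ": kept ", nrow(al$expr), " genes x ", ncol(al$expr),
          " samples (removed ", length(cl$removed_genes), " genes, ",
          length(cl$removed_samples), " samples)")
}
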