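#!/usr/bin/env Rscript
# Expression-stratified survival screen on the two tumor cohorts: per gene,
# a 30/70 low/high split, log-rank and Cox likelihood-ratio tests, the
# mortality-rate ratio and the death/alive chi-square; genes significant
# (log-rank P < 0.001), chi-square-confirmed and direction-consistent in
# both cohorts form result C.

suppressMessages(library(hubscreen))

screens <- list()
for (nm in c("replication", "validation")) {
  expr <- read_expression(file.path("results/prepared",
                                    paste0(nm, "_expression.tsv")))
  clin <- read_clinical(file.path("results/prepared",
                                  paste0(nm, "_clinical.csv")))
  sc <- screen_survival(expr, clin, low_frac = 0.3)
  screens[[nm]] <- sc
  message(nm, ": ", sum(sc$significant), " of ", nrow(sc),
          " genes at log-rank P < 0.001")
  write.csv(sc, file.path("results", paste0("survival_", nm, ".csv")),
            row.names = FALSE)
}

cc <- cross_dataset_consistent(screens$replication, screens$validation)
message("result C: ", nrow(cc), " genes consistent in both cohorts (",
        attr(cc, "n_inconsistent"), " direction-inconsistent dropped)")
write.csv(cc, "results/result_c.csv", row.names = FALSE)
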