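#!/usr/bin/env Rscript
# Differential expression: trend-consistent DEGs with the tertile chi-square
# grade gate on the discovery cohort (result B), and the grade-monotone
# III-vs-II / IV-vs-III intersection on the replication cohort (result D).
# Thresholds: P < 0.001, |log2FC| > 1 throughout.

suppressMessages(library(hubscreen))

expr_d <- read_expression("results/prepared/discovery_expression.tsv")
clin_d <- read_clinical("results/prepared/discovery_clinical.csv")
b <- build_result_b(expr_d, clin_d)
message("result B: ", nrow(b), " genes (",
        sum(b$direction == "up"), " up, ",
        sum(b$direction == "down"), " down); raw intersection ",
        attr(b, "n_raw_intersection"), ", trend-consistent ",
        attr(b, "n_trend_consistent"))
write.csv(b, "results/result_b.csv", row.names = FALSE)

expr_r <- read_expression("results/prepared/replication_expression.tsv")
clin_r <- read_clinical("results/prepared/replication_clinical.csv")
d <- build_result_d(expr_r, clin_r)
message("result D: ", nrow(d), " genes (",
        sum(d$direction == "up"), " up, ",
        sum(d$direction == "down"), " down)")
write.csv(d, "results/result_d.csv", row.names = FALSE)
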