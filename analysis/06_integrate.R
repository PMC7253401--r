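#!/usr/bin/env Rscript
# Intersect results A, B and D into the key-gene set, report survival-set
# (C) membership, and annotate each key gene with its subnetwork
# connectivity (top-1% TOM edges, top-30% nodes), per-step fold changes,
# survival statistics, diagnostic AUC, and recovery against the planted
# ground truth.

suppressMessages(library(hubscreen))

a <- read.csv("results/result_a.csv")$gene
b <- read.csv("results/result_b.csv")
cset <- read.csv("results/result_c.csv")
d <- read.csv("results/result_d.csv")
screen <- read.csv("results/survival_replication.csv")
W <- readRDS("results/scratch_tom.rds")
chosen <- readLines("results/chosen_modules.txt")
assignment <- read.csv("results/module_assignment.csv")

key <- Reduce(intersect, list(a, b$gene, d$gene))
subnet_genes <- assignment$gene[assignment$module %in% chosen]
sub <- extract_subnetwork(W[subnet_genes, subnet_genes],
                          intersect(key, subnet_genes),
                          edge_top_frac = 0.01, node_top_frac = 0.3)
conn <- setNames(sub$nodes$connectivity, sub$nodes$gene)
write.table(sub$edges, "results/subnetwork_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

report <- intersect_results(a, b, cset, d, deg_d = d, screen = screen,
                            connectivity = conn)

# diagnostic AUC of each key gene, tumor vs normal on the discovery cohort
expr_d <- read_expression("results/prepared/discovery_expression.tsv")
clin_d <- read_clinical("results/prepared/discovery_clinical.csv")
lab <- ifelse(clin_d$grade == "normal", "normal", "tumor")
report$auc <- vapply(report$gene,
                     function(g) roc_auc(expr_d[g, ], lab, "tumor"),
                     numeric(1))
write.csv(report, "results/key_gene_report.csv", row.names = FALSE)

message("key genes (A n B n D): ", nrow(report),
        "; in survival set C: ", sum(report$in_c))

truth <- read.csv("results/cohorts/discovery/ground_truth.csv")
planted <- truth$gene[truth$is_hub & abs(truth$step_lfc) > 1 &
                        truth$hazard_direction != 0]
message("planted key genes recovered: ",
        sum(planted %in% report$gene), "/", length(planted),
        "; non-planted in key set: ",
        sum(!report$gene %in% planted))
print(head(report[, c("gene", "connectivity", "lfc_3v2", "lfc_4v3",
                      "survival_p", "rr", "in_c", "auc")], 10))
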