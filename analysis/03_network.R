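#!/usr/bin/env Rscript
# Weighted co-expression network on the discovery cohort: soft-threshold
# selection by scale-free fit, topological overlap, module detection,
# module-trait correlation, and top-20% hub selection from the four modules
# most correlated with WHO grade (result A).

suppressMessages(library(hubscreen))

expr <- read_expression("results/prepared/discovery_expression.tsv")
clin <- read_clinical("results/prepared/discovery_clinical.csv")

pw <- pick_power(expr)
message("selected soft threshold: ", pw$power, " (signed R^2 = ",
        round(pw$scan$r_squared[pw$scan$power == pw$power], 3), ")")
write.csv(pw$scan, "results/power_scan.csv", row.names = FALSE)

W <- tom(adjacency(similarity(expr), pw$power))
assignment <- detect_modules(W, expr = expr)
message("modules: ", paste(names(table(assignment)), table(assignment),
                           sep = "=", collapse = ", "))
write.csv(data.frame(gene = names(assignment), module = unname(assignment)),
          "results/module_assignment.csv", row.names = FALSE)

me <- module_eigengenes(expr, assignment)
grade <- grade_code(clin$grade)
mt <- module_trait_correlation(me, data.frame(grade = grade, age = clin$age))
write.csv(mt, "results/module_trait.csv", row.names = FALSE)
chosen <- pick_trait_modules(mt, "grade", n_top = 4)
message("grade modules: ", paste(chosen, collapse = ", "))

mmgs <- membership_and_significance(expr, me, grade)
hubs <- select_module_hubs(mmgs, assignment, chosen, top_frac = 0.2)
message("result A: ", length(hubs), " hub genes")
write.csv(data.frame(gene = hubs), "results/result_a.csv", row.names = FALSE)

saveRDS(W, "results/scratch_tom.rds")  # reused by 06_integrate.R
writeLines(chosen, "results/chosen_modules.txt")
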