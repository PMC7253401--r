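# hubscreen

Multi-stage screening of tumor **hub genes** — genes that are at once
central in a weighted gene co-expression network, differentially expressed
along the malignancy axis, and prognostic for overall survival. The package
targets glioma-style study designs: a discovery expression cohort with
normal controls and WHO-graded tumors, plus two tumor cohorts with survival
follow-up.

## The method

Four result sets are computed and intersected:

* **A — network hubs.** Unsigned similarity `S_ij = |cor(x_i, x_j)|` is
  soft-thresholded (`A = S^β`, β the smallest power whose connectivity
  distribution fits a scale-free law with signed R² ≥ 0.9) and converted to
  topological overlap `TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`.
  Modules are average-linkage clusters of `1 − TOM`; for the four modules
  whose eigengenes correlate most with WHO grade, the top 20% of genes by
  |module membership| is intersected with the top 20% by |grade
  significance|.
* **B — grade-consistent DEGs.** Empirical-Bayes moderated t-tests (tumor
  vs normal, WHO III/IV vs I/II) at `P < 0.001`, `|log2FC| > 1`, same trend
  in both, confirmed by a chi-square of three equal-width expression
  intervals against the grade split (`P < 0.001`).
* **C — reproducible survival genes.** Per gene, a 30/70 low/high
  expression split; log-rank and Cox likelihood-ratio tests, the
  mortality-rate ratio `RR = (deaths_high/n_high)/(deaths_low/n_low)`, and
  a death/alive chi-square — required to be significant and
  direction-consistent in both survival cohorts.
* **D — grade-monotone replication DEGs.** Same-trend DEGs of III vs II
  and IV vs III on the replication cohort.

The key-gene report is `A ∩ B ∩ D`, with C-membership, subnetwork
connectivity (top-1% TOM edges, top-30% nodes), per-step fold changes,
survival statistics and diagnostic AUC per gene. A latent-factor synthetic
cohort generator with planted hubs, fold changes and hazards provides
ground truth for every stage; see the methods vignette
(`vignettes/hub-gene-screening.Rmd`) for the model and all numerical
choices.

## A worked example

The `analysis/` scripts run the screen as six narrative stages on a
simulated study (1200 genes; 200-sample discovery cohort with normals, two
180-sample tumor cohorts with survival):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prepare.R
Rscript analysis/03_network.R
Rscript analysis/04_differential.R
Rscript analysis/05_survival.R
Rscript analysis/06_integrate.R
```

which prints, stage by stage:

```
selected soft threshold: 4 (signed R^2 = 0.909)
modules: grey=619, M1=100, M2=100, M3=100, M4=100, M5=95, M6=86
grade modules: M3, M1, M2, M4
result A: 63 hub genes
result B: 385 genes (199 up, 186 down)
result D: 380 genes (188 up, 192 down)
replication: 396 of 1200 genes at log-rank P < 0.001
result C: 302 genes consistent in both cohorts
key genes (A n B n D): 63; in survival set C: 63
planted key genes recovered: 55/80; non-planted in key set: 8
```

Reading: the power scan picked β = 4; all six planted modules were
recovered (the four grade-linked ones exactly); 63 hub genes survived the
MM/GS intersection; the DEG and survival screens each recovered the planted
gene sets; and the final intersection holds 63 key genes, every one also in
the survival set C — the same containment pattern the screen is designed to
surface. All tables land under `results/` (`key_gene_report.csv` is the
per-gene report). The same pipeline runs as one call:

```r
library(hubscreen)
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "results/run"))
res$summary$counts
```

Real data enter through `pipeline_config(discovery_expr = ...,
discovery_clinical = ..., ...)` with gene-level TSV expression matrices and
CSV clinical tables (`sample_id, grade, os_time, os_event, age`).

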