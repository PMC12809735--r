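#!/usr/bin/env Rscript
# Step 2 — read the simulated survey back from CSV (exercising the same
# ingestion path a field dataset would take), validate it, and compute every
# derived stand, site, diversity and climate-composite covariate.

suppressPackageStartupMessages(library(hdmixed))

trees <- read_trees("results/trees.csv")
plots <- read_plots("results/plots.csv")
ds <- forest_dataset(trees, plots)

report <- validate_dataset(ds, min_species_n = 100)
print(report)
write_validation_json(report, "results/validation.json")

metrics <- plot_metrics_table(ds)
write_table_full(metrics, "results/plot_metrics.csv")
bal <- tree_bal_table(ds)
write_table_full(bal, "results/tree_bal.csv")

message(sprintf(
  "plot metrics: QMD %.1f-%.1f cm (mean %.1f), SIM %.2f-%.2f (mean %.2f), BAL max %.1f m2/ha",
  min(metrics$QMD), max(metrics$QMD), mean(metrics$QMD),
  min(metrics$SIM), max(metrics$SIM), mean(metrics$SIM), max(bal$BAL)))
message("wrote results/validation.json, results/plot_metrics.csv, results/tree_bal.csv")
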