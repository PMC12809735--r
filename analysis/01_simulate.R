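#!/usr/bin/env Rscript
# Step 1 — build the synthetic mixed forest used by the whole workflow.
#
# The generator emulates the structure of a 99-plot temperate mixed-forest
# survey: five species with truncated-normal diameter laws, plot covariates
# (SOC, MAP, MAT, elevation, slope) drawn from their reported marginals, and
# heights produced by the covariate-extended power model with plot- and
# species-level random effects. Stand covariates (QMD, SIM, per-tree BAL) are
# derived from the realized tree lists, so they are coherent with the trees.

suppressPackageStartupMessages(library(hdmixed))
dir.create("results", showWarnings = FALSE)

seed <- 20260925
syn <- simulate_heights(sim_config(seed = seed))

ds <- syn$dataset
write_table_full(ds$trees, "results/trees.csv")
write_table_full(ds$plots, "results/plots.csv")
write_table_full(syn$frame, "results/model_frame.csv")

truth <- syn$truth$config
jsonlite::write_json(
  list(seed = seed,
       n_plots = truth$n_plots,
       n_trees = nrow(ds$trees),
       fixed = as.list(truth$fixed),
       plot_sd = as.list(setNames(sqrt(diag(truth$re$plot_cov)),
                                  truth$re$plot)),
       species_sd = sqrt(truth$re$species_var),
       sigma = truth$sigma,
       n_clipped = syn$truth$n_clipped),
  "results/truth.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf("simulated %d trees in %d plots (%d species); %d heights clipped",
                nrow(ds$trees), nrow(ds$plots),
                length(unique(ds$trees$species)), syn$truth$n_clipped))
message("wrote results/trees.csv, results/plots.csv, results/model_frame.csv, results/truth.json")
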