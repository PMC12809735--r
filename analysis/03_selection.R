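#!/usr/bin/env Rscript
# Step 3 — two-stage covariate selection.
#
# Stage 1: per-species base-model fits, then Pearson correlations between the
# species coefficients and candidate covariates aggregated per species.
# Stage 2: iterative VIF screening (threshold 5) of the plot-level candidate
# set, then the nested AIC ladder adding QMD, BAL, SIM, MAP and SOC to the
# base model.

suppressPackageStartupMessages(library(hdmixed))

trees <- read_trees("results/trees.csv")
plots <- read_plots("results/plots.csv")
ds <- forest_dataset(trees, plots)
frame <- hd_model_frame(ds)

# stage 1: species-level coefficients and their covariate environments
fits <- stage1_species_fits(frame)
print(fits, digits = 3)
agg <- aggregate(frame[, c("SOC", "MAP", "SIM", "BAL", "QMD")],
                 by = list(species = frame$species), FUN = mean)
agg <- agg[match(fits$species, agg$species), ]
cors <- stage1_correlations(fits[, c("beta0", "beta1")], agg[, -1])
write_selection_json(list(species_fits = fits, correlations = cors),
                     "results/stage1.json")

# stage 2: VIF screen on the plot-level candidate table
cand <- plots[, c("SOC", "MAP", "MAT", "elevation_m", "slope_deg")]
cand$M <- de_martonne(plots$MAP, plots$MAT)
cand$AHM <- annual_heat_moisture(plots$MAT, plots$MAP)
st <- stage_transforms(plots$slope_deg, plots$elevation_m)
cand$SIE <- st$sie; cand$CIE <- st$cie
cand$QMD <- plots$QMD; cand$SIM <- plots$SIM
mf_bal <- aggregate(BAL ~ plot_id, frame, mean)
cand$BAL <- mf_bal$BAL[match(plots$plot_id, mf_bal$plot_id)]
vf <- vif_filter(cand, threshold = 5)
message("VIF screen kept: ", paste(vf$kept, collapse = ", "))
message("VIF screen dropped: ", paste(vf$dropped, collapse = ", "))
write_selection_json(list(kept = vf$kept, dropped = vf$dropped,
                          vif = as.list(vf$vif)), "results/vif.json")

ladder <- aic_ladder(frame)
print(ladder, digits = 6, row.names = FALSE)
message("minimum-AIC rung: ", attr(ladder, "best"))
write_table_full(ladder, "results/aic_ladder.csv")
message("wrote results/stage1.json, results/vif.json, results/aic_ladder.csv")
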