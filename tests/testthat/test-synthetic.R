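test_that("generation is deterministic under the seed", {
  a <- make_fixture("tiny", seed = 5)
  b <- make_fixture("tiny", seed = 5)
  expect_identical(a$frame, b$frame)
  c <- make_fixture("tiny", seed = 6)
  expect_false(identical(a$frame$height_m, c$frame$height_m))
  expect_equal(nrow(a$frame), 15)  # 3 plots x 5 trees
})

test_that("plot covariates reproduce the configured marginals", {
  cfg <- sim_config(n_plots = 10000, seed = 3)
  plots <- generate_plots(cfg)
  map <- plots$MAP
  expect_lt(abs(mean(map) - 454.10) / 454.10, 0.01)
  expect_gte(min(map), 363.4)
  expect_lte(max(map), 508.8)
  soc <- plots$SOC
  expect_gte(min(soc), 37.2)
  expect_lte(max(soc), 159.3)
  # sd = 0 collapses a covariate to its mean
  tbl <- default_covariate_table()
  tbl$sd[tbl$name == "MAP"] <- 0
  cfg0 <- sim_config(n_plots = 50, covariates = tbl, seed = 3)
  expect_true(all(generate_plots(cfg0)$MAP == 454.10))
})

test_that("diameters respect the survey truncation across many draws", {
  cfg <- sim_config(n_plots = 99, seed = 4)
  gen <- generate_trees(cfg, generate_plots(cfg))
  expect_gte(min(gen$trees$dbh_cm), 5)
  sp_tbl <- cfg$species
  for (s in sp_tbl$species) {
    dmax <- sp_tbl$d_max[sp_tbl$species == s]
    expect_lte(max(gen$trees$dbh_cm[gen$trees$species == s]), dmax)
  }
  # the Weibull alternative respects the same truncation
  cfgw <- sim_config(n_plots = 20, d_law = "weibull", seed = 4)
  genw <- generate_trees(cfgw, generate_plots(cfgw))
  expect_gte(min(genw$trees$dbh_cm), 5)
  expect_lte(max(genw$trees$dbh_cm), max(sp_tbl$d_max))
})

test_that("stored stand covariates equal recomputation from the tree list", {
  syn <- make_fixture("tiny", seed = 7)
  ds <- syn$dataset
  for (p in ds$plots$plot_id) {
    m <- compute_stand_metrics(ds, p)
    expect_equal(ds$plots$QMD[ds$plots$plot_id == p], m$qmd_cm)
    expect_equal(ds$plots$SIM[ds$plots$plot_id == p], m$sim)
    rows <- syn$frame$plot_id == p
    area <- ds$plots$area_ha[ds$plots$plot_id == p]
    expect_equal(syn$frame$BAL[rows],
                 compute_bal(syn$frame$dbh_cm[rows], area))
  }
})

test_that("single-species mixes give pure-stand diversity zero", {
  sp <- default_species_table()[4, , drop = FALSE]  # larch only
  cfg <- sim_config(n_plots = 8, trees_per_plot = 10,
                    species = sp, richness_probs = 1, seed = 8)
  syn <- simulate_heights(cfg)
  expect_true(all(syn$frame$SIM == 0))
  expect_true(all(syn$frame$SHI == 0))
})

test_that("zero variances reproduce the deterministic model exactly", {
  re0 <- hd_re_spec(plot = c("beta0", "beta1"), species = "QMD",
                    plot_cov = matrix(0, 2, 2), species_var = 0)
  cfg <- sim_config(n_plots = 5, trees_per_plot = 8, re = re0, sigma = 1e-12,
                    seed = 9)
  syn <- simulate_heights(cfg)
  fe <- cfg$fixed
  mu <- predict_height(fe, syn$frame$dbh_cm,
                       syn$frame[, c("SOC", "MAP", "SIM", "BAL", "QMD")])
  expect_equal(syn$frame$height_m, mu, tolerance = 1e-9)
})

test_that("residual noise follows the variance-function truth in D bins", {
  vs <- hd_var_spec("constant_plus_power", c(0.5, 0.8))
  cfg <- sim_config(n_plots = 99, trees_per_plot = 101, sigma = 0.18,
                    var_truth = vs,
                    re = hd_re_spec(plot = c("beta0", "beta1"), species = "QMD",
                                    plot_cov = matrix(0, 2, 2),
                                    species_var = 0),
                    seed = 10)
  syn <- simulate_heights(cfg)
  fe <- cfg$fixed
  mu <- predict_height(fe, syn$frame$dbh_cm,
                       syn$frame[, c("SOC", "MAP", "SIM", "BAL", "QMD")])
  res <- syn$frame$height_m - mu
  bins <- cut(syn$frame$dbh_cm, breaks = c(5, 10, 15, 20, 30, 62),
              include.lowest = TRUE)
  emp <- tapply(res, bins, sd)
  centers <- tapply(syn$frame$dbh_cm, bins, median)
  model <- evaluate_variance_fn(vs, centers, 0.18)
  ratio <- emp / model
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("between-plot spread grows with the plot-level SD truth", {
  spread <- sapply(c(0.1, 0.5, 1.0), function(sd0) {
    re <- hd_re_spec(plot = "beta0", species = NULL,
                     plot_cov = matrix(sd0^2, 1, 1))
    cfg <- sim_config(n_plots = 40, trees_per_plot = 20, re = re,
                      sigma = 0.5,
                      fixed = c(beta0 = 1.784, beta1 = 0.823, SOC = -1e-3,
                                MAP = 2e-4, SIM = 1.044e-1, BAL = 2e-3,
                                QMD = -5e-3),
                      seed = 11)
    syn <- simulate_heights(cfg)
    fe <- cfg$fixed
    mu <- predict_height(fe, syn$frame$dbh_cm,
                         syn$frame[, c("SOC", "MAP", "SIM", "BAL", "QMD")])
    plot_means <- tapply(syn$frame$height_m - mu, syn$frame$plot_id, mean)
    sd(plot_means)
  })
  expect_true(all(diff(spread) > 0))
})

test_that("the study-scale preset lands in the expected size range", {
  syn <- make_fixture("survey_scale", seed = 12)
  expect_gte(nrow(syn$frame), 7000)
  expect_lte(nrow(syn$frame), 8600)
  expect_equal(length(unique(syn$frame$plot_id)), 99)
  expect_equal(sort(unique(syn$frame$species)),
               sort(default_species_table()$species))
  # heights are physical and the diameter threshold holds
  expect_gt(min(syn$frame$height_m), 1.3)
  expect_gte(min(syn$frame$dbh_cm), 5)
})

test_that("config validation rejects degenerate settings", {
  tbl <- default_covariate_table()
  tbl$min[1] <- tbl$max[1] + 1
  expect_error(sim_config(covariates = tbl), "min >= max")
  sp <- default_species_table()[0, ]
  expect_error(sim_config(species = sp), "empty species")
})
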