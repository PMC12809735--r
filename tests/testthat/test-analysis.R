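make_species_data <- function(b1_by_species, n_per = 150, sigma = 1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(b1_by_species), function(s) {
    D <- runif(n_per, 5, 45)
    data.frame(plot_id = "A", species = s, dbh_cm = D,
               height_m = 1.3 + 2 * D^b1_by_species[[s]] +
                 rnorm(n_per, 0, sigma),
               stringsAsFactors = FALSE)
  }))
}

test_that("species exponents: single species equals the pooled fit", {
  d <- make_species_data(list(Lg = 0.6), seed = 2)
  ex <- species_exponents(d)
  expect_equal(ex$cross_species, ex$by_species$beta1)
  expect_equal(ex$theory, 2 / 3)
})

test_that("the species with the largest exponent is identified", {
  d <- make_species_data(list(Qm = 0.91, Bp = 0.55, Lg = 0.55), seed = 3)
  ex <- species_exponents(d)
  expect_equal(ex$by_species$species[which.max(ex$by_species$beta1)], "Qm")
  expect_true(ex$by_species$excludes_theory[ex$by_species$species == "Qm"])
})

test_that("Wald intervals cover a true exponent of 2/3 at the nominal rate", {
  cover <- replicate(60, {
    d <- make_species_data(list(Lg = 2 / 3), n_per = 200, sigma = 1.5,
                           seed = sample.int(1e6, 1))
    ft <- fit_hd_nls(d)
    ci <- ft$estimates[["beta1"]] + c(-1.96, 1.96) * ft$se[["beta1"]]
    ci[1] <= 2 / 3 && 2 / 3 <= ci[2]
  })
  expect_gte(mean(cover), 0.85)  # binomial noise around 0.95 at 60 draws
})

test_that("exponent report is invariant to row order; duplication shrinks SEs", {
  d <- make_species_data(list(Lg = 0.6, Bp = 0.7), sigma = 1, seed = 4)
  ex1 <- species_exponents(d)
  ex2 <- species_exponents(d[sample(nrow(d)), ])
  expect_equal(ex1$by_species$beta1,
               ex2$by_species$beta1[match(ex1$by_species$species,
                                          ex2$by_species$species)],
               tolerance = 1e-7)
  exdup <- species_exponents(rbind(d, d))
  expect_equal(exdup$by_species$beta1[1], ex1$by_species$beta1[1],
               tolerance = 1e-6)
  expect_equal(exdup$by_species$se_beta1[1] * sqrt(2),
               ex1$by_species$se_beta1[1], tolerance = 0.02)
})

gradient_fixture <- function(seed = 5) {
  set.seed(seed)
  n_plots <- 20; n_tree <- 15
  d <- data.frame(
    plot_id = rep(sprintf("P%02d", 1:n_plots), each = n_tree),
    species = sample(c("Lg", "Bp"), n_plots * n_tree, replace = TRUE),
    dbh_cm = runif(n_plots * n_tree, 5, 45),
    BAL = runif(n_plots * n_tree, 0, 50),
    MAP = rep(runif(n_plots, 380, 500), each = n_tree))
  d$height_m <- 1.3 + 2 * d$dbh_cm^(0.45 + 0.002 * d$BAL + 2e-4 * d$MAP) +
    rnorm(nrow(d), 0, 1)
  d
}

test_that("gradient curves respond to the target covariate as the fit dictates", {
  d <- gradient_fixture()
  ft <- fit_hd_nls(d, hd_model_spec(c("BAL", "MAP")))
  gr <- gradient_simulation(ft, d, target = "BAL", d_grid = c(10, 20, 30))
  # positive BAL coefficient: higher node -> taller at fixed D
  lg <- gr[gr$species == "Lg" & gr$dbh_cm == 20, ]
  lg <- lg[order(lg$node_value), ]
  expect_true(all(diff(lg$height_m) > 0))
  # hand check of the curve offsets at D = 20
  fe <- ft$estimates
  means <- colMeans(d[d$species == "Lg", c("BAL", "MAP")])
  e_at <- function(balval) fe[["beta1"]] + fe[["BAL"]] * balval +
    fe[["MAP"]] * means[["MAP"]]
  offset_expected <- fe[["beta0"]] *
    (20^e_at(lg$node_value[3]) - 20^e_at(lg$node_value[1]))
  expect_equal(lg$height_m[3] - lg$height_m[1], offset_expected,
               tolerance = 1e-10)
  # curves are monotone in D for positive exponents
  one <- gr[gr$species == "Lg" & gr$node == "p50", ]
  expect_true(all(diff(one$height_m[order(one$dbh_cm)]) > 0))
  expect_error(gradient_simulation(ft, d, target = "SOC"), "not a fitted")
})

test_that("a zero-coefficient target collapses the node curves", {
  d <- gradient_fixture(seed = 6)
  ft <- fit_hd_nls(d, hd_model_spec(c("BAL", "MAP")))
  ft$estimates[["BAL"]] <- 0
  gr <- gradient_simulation(ft, d, target = "BAL", d_grid = c(15, 25))
  sp <- gr[gr$species == "Bp" & gr$dbh_cm == 15, ]
  expect_lt(diff(range(sp$height_m)), 1e-12)
})

test_that("finite-difference slopes match the closed-form derivative", {
  d <- gradient_fixture(seed = 7)
  ft <- fit_hd_nls(d, hd_model_spec(c("BAL", "MAP")))
  sl <- slope_summary(ft, d)
  fe <- ft$estimates
  for (s in unique(d$species)) {
    ds <- d[d$species == s, ]
    d_med <- median(ds$dbh_cm)
    means <- colMeans(ds[, c("BAL", "MAP")])
    e <- fe[["beta1"]] + fe[["BAL"]] * means[["BAL"]] +
      fe[["MAP"]] * means[["MAP"]]
    analytic <- fe[["beta0"]] * d_med^e * log(d_med) * fe[["MAP"]]
    got <- sl$slope[sl$species == s & sl$covariate == "MAP"]
    expect_equal(got, analytic, tolerance = 1e-6)
    # slope sign equals coefficient sign for D > 1 cm
    expect_equal(sign(got), sign(fe[["MAP"]]))
  }
})
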