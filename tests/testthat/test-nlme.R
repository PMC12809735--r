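test_that("variance functions reduce correctly at degenerate parameters", {
  D <- c(5, 15, 40)
  expect_equal(evaluate_variance_fn(hd_var_spec("exponential", 0), D, 2),
               rep(2, 3))
  expect_equal(evaluate_variance_fn(hd_var_spec("power", 0), D, 2), rep(2, 3))
  expect_equal(
    evaluate_variance_fn(hd_var_spec("constant_plus_power", c(1, 0)), D, 2),
    rep(4, 3))  # |1 + D^0| = 2
  expect_equal(evaluate_variance_fn(hd_var_spec("none"), D, 1.5), rep(1.5, 3))
  expect_equal(evaluate_variance_fn(hd_var_spec("exponential", 0.05), 20, 2),
               2 * exp(1))
})

test_that("marginal likelihood with zero variances equals the NLS likelihood", {
  d <- small_mixed_data(n_plots = 4, n_trees = 8, re_sd = 0, sigma = 1, seed = 2)
  ft <- fit_hd_nls(d)
  re <- hd_re_spec(plot = "beta0", species = NULL,
                   plot_cov = matrix(0, 1, 1))
  ll <- hd_marginal_loglik(ft$estimates, re, hd_var_spec("none"),
                           sigma = ft$sigma, data = d)
  expect_equal(ll, ft$loglik, tolerance = 1e-12)
})

test_that("marginal likelihood matches dense quadrature on small instances", {
  spec <- hd_model_spec()
  # (a) random effect on beta0: linearization is exact
  d <- small_mixed_data(n_plots = 2, n_trees = 3, re_par = "beta0",
                        re_sd = 0.6, sigma = 0.7, seed = 5)
  fe <- c(beta0 = 2.5, beta1 = 0.55)
  re <- hd_re_spec(plot = "beta0", species = NULL,
                   plot_cov = matrix(0.36, 1, 1))
  ll <- hd_marginal_loglik(fe, re, hd_var_spec("none"), 0.7, d, spec)
  or <- quadrature_loglik(fe, re, hd_var_spec("none"), 0.7, d, spec)
  expect_equal(ll, or, tolerance = 1e-3)

  # (b) small random effect on the exponent: mild nonlinearity
  d2 <- small_mixed_data(n_plots = 2, n_trees = 5, re_par = "beta1",
                         re_sd = 0.03, sigma = 0.5, seed = 6)
  re2 <- hd_re_spec(plot = "beta1", species = NULL,
                    plot_cov = matrix(0.03^2, 1, 1))
  ll2 <- hd_marginal_loglik(fe, re2, hd_var_spec("none"), 0.5, d2, spec)
  or2 <- quadrature_loglik(fe, re2, hd_var_spec("none"), 0.5, d2, spec)
  expect_equal(ll2, or2, tolerance = 1e-3)

  # (c) two correlated plot effects, heteroscedastic errors
  d3 <- small_mixed_data(n_plots = 2, n_trees = 6, re_par = "beta0",
                         re_sd = 0.4, sigma = 0.4, seed = 7)
  V <- matrix(c(0.16, 0.003, 0.003, 0.0009), 2, 2)
  re3 <- hd_re_spec(plot = c("beta0", "beta1"), species = NULL, plot_cov = V)
  vs3 <- hd_var_spec("power", 0.3)
  ll3 <- hd_marginal_loglik(fe, re3, vs3, 0.3, d3, spec)
  or3 <- quadrature_loglik(fe, re3, vs3, 0.3, d3, spec, npts = 161)
  expect_equal(ll3, or3, tolerance = 1e-3)
})

test_that("likelihood scales by the Gaussian closed form in the linear case", {
  # doubling sigma, the RE SD, and all response deviations shifts LL by
  # exactly -n log 2 (the full covariance scales by 4); RE on beta0 is linear
  d <- small_mixed_data(n_plots = 3, n_trees = 6, re_par = "beta0",
                        re_sd = 0.5, sigma = 0.6, seed = 8)
  fe <- c(beta0 = 2.5, beta1 = 0.55)
  mu <- predict_height(fe, d$dbh_cm)
  re1 <- hd_re_spec(plot = "beta0", species = NULL,
                    plot_cov = matrix(0.25, 1, 1))
  re2 <- hd_re_spec(plot = "beta0", species = NULL,
                    plot_cov = matrix(1.00, 1, 1))
  ll1 <- hd_marginal_loglik(fe, re1, hd_var_spec("none"), 0.6, d)
  d2 <- d
  d2$height_m <- mu + 2 * (d$height_m - mu)
  ll2 <- hd_marginal_loglik(fe, re2, hd_var_spec("none"), 1.2, d2)
  expect_equal(ll2, ll1 - nrow(d) * log(2), tolerance = 1e-8)
})

test_that("marginal likelihood is invariant to plot relabeling and row order", {
  d <- small_mixed_data(n_plots = 5, n_trees = 8, re_sd = 0.4, seed = 9)
  fe <- c(beta0 = 2.4, beta1 = 0.56)
  re <- hd_re_spec(plot = "beta0", species = NULL,
                   plot_cov = matrix(0.2, 1, 1))
  ll <- hd_marginal_loglik(fe, re, hd_var_spec("none"), 0.8, d)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  d2$plot_id <- paste0("relabeled_", d2$plot_id)
  ll2 <- hd_marginal_loglik(fe, re, hd_var_spec("none"), 0.8, d2)
  expect_equal(ll2, ll, tolerance = 1e-10)
})

test_that("fit on zero-random-effect data matches NLS within 2 SEs", {
  d <- small_mixed_data(n_plots = 10, n_trees = 15, re_sd = 0, sigma = 1,
                        seed = 10)
  nls_fit <- fit_hd_nls(d)
  ml <- fit_hd_nlme(d, hd_model_spec(),
                    hd_re_spec(plot = "beta0", species = NULL))
  expect_lt(abs(ml$estimates[["beta0"]] - nls_fit$estimates[["beta0"]]),
            2 * nls_fit$se[["beta0"]])
  expect_lt(abs(ml$estimates[["beta1"]] - nls_fit$estimates[["beta1"]]),
            2 * nls_fit$se[["beta1"]])
  # the plot variance collapses towards the boundary
  expect_lt(sqrt(ml$plot_cov[1, 1]), 0.1)
})

test_that("tiny-instance fit attains at least the truth likelihood and the
           quadrature-maximized likelihood", {
  d <- small_mixed_data(n_plots = 3, n_trees = 4, re_par = "beta0",
                        re_sd = 0.5, sigma = 0.5, seed = 11)
  spec <- hd_model_spec()
  re_truth <- hd_re_spec(plot = "beta0", species = NULL,
                         plot_cov = matrix(0.25, 1, 1))
  ll_truth <- hd_marginal_loglik(c(beta0 = 2.5, beta1 = 0.55), re_truth,
                                 hd_var_spec("none"), 0.5, d, spec)
  ft <- fit_hd_nlme(d, spec, hd_re_spec(plot = "beta0", species = NULL),
                    tol = 1e-6, max_iter = 40)
  expect_gte(ft$loglik, ll_truth - 1e-6)

  # independent oracle: maximize the exact (quadrature) likelihood directly
  obj <- function(par) {
    -quadrature_loglik(
      c(beta0 = par[1], beta1 = par[2]),
      hd_re_spec(plot = "beta0", species = NULL,
                 plot_cov = matrix(exp(2 * par[3]), 1, 1)),
      hd_var_spec("none"), exp(par[4]), d, spec, npts = 121)
  }
  opt <- optim(c(2.5, 0.55, log(0.5), log(0.5)), obj,
               control = list(maxit = 500, reltol = 1e-10))
  # RE on beta0 is linear, so the linearized and exact likelihoods coincide
  expect_equal(ft$loglik, -opt$value, tolerance = 1e-2)
})

test_that("parameter census drives the information criteria", {
  d <- small_mixed_data(n_plots = 6, n_trees = 10, re_sd = 0.4, sigma = 0.6,
                        seed = 12)
  ft <- fit_hd_nlme(d, hd_model_spec(),
                    hd_re_spec(plot = "beta0", species = NULL),
                    hd_var_spec("power"))
  # 2 fixed + 1 plot variance + 1 variance-function + sigma = 5
  expect_equal(ft$k, 5)
  expect_equal(unname(sum(ft$k_census)), ft$k)
  expect_equal(ft$aic, -2 * ft$loglik + 2 * ft$k)
  expect_equal(ft$bic, -2 * ft$loglik + log(ft$n) * ft$k)
})

test_that("standardized residuals behave under correct and wrong variance models", {
  # well-specified: residual SD near 1
  d1 <- small_mixed_data(n_plots = 20, n_trees = 25, re_sd = 0.5, sigma = 0.9,
                         seed = 14)
  ft1 <- fit_hd_nlme(d1, hd_model_spec(),
                     hd_re_spec(plot = "beta0", species = NULL))
  expect_gt(sd(standardized_residuals(ft1)), 0.85)
  expect_lt(sd(standardized_residuals(ft1)), 1.15)
  smry <- standardized_residuals(ft1, by = d1$species)
  expect_equal(smry$n, nrow(d1))
  # definition: (observed - conditional prediction) / model SD at the tree's D;
  # residuals vanish where the conditional prediction equals the observation
  expect_equal(standardized_residuals(ft1),
               (d1$height_m - ft1$fitted_cond) / ft1$sigma)
  idx <- which.min(abs(d1$height_m - ft1$fitted_cond))
  expect_lt(abs(standardized_residuals(ft1)[idx]),
            abs(d1$height_m[idx] - ft1$fitted_cond[idx]) / ft1$sigma + 1e-12)

  # misspecified: homoscedastic fit to power-variance data leaves a
  # diameter trend in the absolute residuals
  d2 <- small_mixed_data(n_plots = 20, n_trees = 25, re_sd = 0.3, sigma = 0.02,
                         var_spec = hd_var_spec("power", 1.2), seed = 15)
  ft2 <- fit_hd_nlme(d2, hd_model_spec(),
                     hd_re_spec(plot = "beta0", species = NULL))
  ct <- suppressWarnings(cor.test(abs(standardized_residuals(ft2)), d2$dbh_cm,
                                  method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("likelihood-ratio table is exact for identical models and flags AIC", {
  d <- small_mixed_data(n_plots = 8, n_trees = 10, re_sd = 0.4, sigma = 0.7,
                        seed = 16)
  base <- fit_hd_nlme(d, hd_model_spec(),
                      hd_re_spec(plot = "beta0", species = NULL))
  tab0 <- lrt_variance_functions(base, list(base))
  expect_equal(tab0$L_ratio[2], 0, tolerance = 1e-6)
  expect_equal(tab0$p_value[2], 1)

  ext <- fit_hd_nlme(d, hd_model_spec(),
                     hd_re_spec(plot = "beta0", species = NULL),
                     hd_var_spec("power"))
  tab <- lrt_variance_functions(base, list(ext))
  expect_equal(tab$df[2], 1)
  expect_equal(tab$L_ratio[2], 2 * (ext$loglik - base$loglik))
  expect_true(attr(tab, "best") %in% tab$model)
  # non-nested / different data rejected
  d2 <- d[1:40, ]
  base2 <- fit_hd_nlme(d2, hd_model_spec(),
                       hd_re_spec(plot = "beta0", species = NULL))
  expect_error(lrt_variance_functions(base2, list(ext)), "identical data")
})

test_that("engine agrees with the nlme package on a two-level model", {
  skip_if_not_installed("nlme")
  set.seed(17)
  syn <- simulate_heights(sim_config(n_plots = 25, trees_per_plot = 15,
                                     seed = 17))
  fr <- syn$frame
  fr$sp <- factor(fr$species)
  spec <- hd_model_spec(c("SOC", "QMD"))
  mine <- fit_hd_nlme(fr, spec,
                      hd_re_spec(plot = c("beta0", "beta1"), species = "QMD"))
  ref <- nlme::nlme(
    height_m ~ 1.3 + b0 * dbh_cm^(b1 + b2 * SOC + b6 * QMD),
    data = fr, fixed = b0 + b1 + b2 + b6 ~ 1,
    random = list(plot_id = b0 + b1 ~ 1, sp = b6 ~ 1),
    groups = ~ plot_id / sp,
    start = c(b0 = 1.8, b1 = 0.8, b2 = -1e-3, b6 = -5e-3),
    method = "ML",
    control = nlme::nlmeControl(maxIter = 200, returnObject = TRUE))
  expect_equal(unname(mine$estimates), unname(nlme::fixef(ref)),
               tolerance = 5e-3)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 0.05)
  expect_equal(mine$sigma, ref$sigma, tolerance = 5e-3)
})

test_that("fixed effects are recovered within 3 SEs across seeds", {
  truth <- default_truth()
  spec <- hd_model_spec(c("SOC", "MAP", "SIM", "BAL", "QMD"))
  hits <- 0; total <- 0
  for (s in 1:3) {
    syn <- simulate_heights(sim_config(n_plots = 40, trees_per_plot = 25,
                                       seed = 300 + s))
    ft <- fit_hd_nlme(syn$frame, spec,
                      hd_re_spec(plot = c("beta0", "beta1"), species = "QMD"))
    expect_true(ft$converged)
    ok <- abs(ft$estimates - truth$fixed[names(ft$estimates)]) <= 3 * ft$se
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.8)
})
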