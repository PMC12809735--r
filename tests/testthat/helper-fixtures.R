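# Shared fixtures and independent oracles for the test suite.

# small two-plot dataset with hand-checkable values
toy_dataset <- function() {
  trees <- data.frame(
    plot_id = c("A", "A", "A", "B", "B"),
    species = c("Lg", "Lg", "Bp", "Lg", "Lg"),
    dbh_cm = c(10, 20, 15, 8, 8),
    height_m = c(9, 15, 12, 7, 8),
    stringsAsFactors = FALSE
  )
  plots <- data.frame(
    plot_id = c("A", "B"), area_ha = c(0.1, 0.06),
    elevation_m = c(exp(1), 500), slope_deg = c(0, 30),
    soc_g_kg = c(90, 120), MAT = c(-2.94, -3.5), MAP = c(454.1, 430),
    stringsAsFactors = FALSE
  )
  forest_dataset(trees, plots)
}

# noiseless / noisy power-law data for fitter tests
powerlaw_data <- function(n = 200, beta0 = 2, beta1 = 0.5, sigma = 0,
                          d_range = c(5, 50), seed = 1) {
  set.seed(seed)
  D <- runif(n, d_range[1], d_range[2])
  H <- 1.3 + beta0 * D^beta1 + if (sigma > 0) rnorm(n, 0, sigma) else 0
  data.frame(dbh_cm = D, height_m = H)
}

# O(n^2) double-loop BAL oracle (independent of the sorted implementation)
bal_oracle <- function(dbh, area_ha) {
  sapply(seq_along(dbh), function(i) {
    sum(pi * (dbh[dbh > dbh[i]] / 200)^2) / area_ha
  })
}

# dense-grid marginal likelihood oracle for <= 2 random effects per plot.
# Integrates the exact (nonlinear) conditional density over a wide grid.
quadrature_loglik <- function(fe, re, var_spec, sigma, data, spec,
                              npts = 201, width = 8) {
  covn <- spec$covariates
  sds <- sqrt(diag(as.matrix(re$plot_cov)))
  q <- length(re$plot)
  stopifnot(q %in% 1:2, is.null(re$species))
  total <- 0
  for (p in unique(data$plot_id)) {
    d <- data[data$plot_id == p, , drop = FALSE]
    g <- evaluate_variance_fn(var_spec, d$dbh_cm, 1)
    cond_ll <- function(b) {
      fe2 <- fe
      fe2[re$plot] <- fe2[re$plot] + b
      mu <- predict_height(fe2, d$dbh_cm,
                           if (length(covn)) d[, covn, drop = FALSE] else NULL)
      sum(dnorm(d$height_m, mu, sigma * g, log = TRUE))
    }
    if (q == 1) {
      bgrid <- seq(-width * sds[1], width * sds[1], length.out = npts)
      lg <- vapply(bgrid, function(b)
        cond_ll(b) + dnorm(b, 0, sds[1], log = TRUE), numeric(1))
      m <- max(lg)
      total <- total + m + log(sum(exp(lg - m)) * diff(bgrid[1:2]))
    } else {
      b1 <- seq(-width * sds[1], width * sds[1], length.out = npts)
      b2 <- seq(-width * sds[2], width * sds[2], length.out = npts)
      V <- as.matrix(re$plot_cov)
      Vi <- solve(V)
      ldV <- determinant(V, logarithm = TRUE)$modulus[1]
      lg <- matrix(NA_real_, npts, npts)
      for (i in seq_len(npts)) for (j in seq_len(npts)) {
        b <- c(b1[i], b2[j])
        lg[i, j] <- cond_ll(b) -
          0.5 * (2 * log(2 * pi) + ldV + drop(t(b) %*% Vi %*% b))
      }
      m <- max(lg)
      total <- total + m +
        log(sum(exp(lg - m)) * diff(b1[1:2]) * diff(b2[1:2]))
    }
  }
  total
}

# small hierarchical dataset generator for engine tests (one plot-level
# effect by default); returns the frame plus the truth used
small_mixed_data <- function(n_plots = 8, n_trees = 10, seed = 1,
                             re_par = "beta0", re_sd = 0.5, sigma = 0.8,
                             beta0 = 2.5, beta1 = 0.55,
                             var_spec = hd_var_spec("none")) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_plots)) {
    D <- runif(n_trees, 6, 40)
    fe <- c(beta0 = beta0, beta1 = beta1)
    b <- rnorm(1, 0, re_sd)
    fe[re_par] <- fe[re_par] + b
    mu <- 1.3 + fe[["beta0"]] * D^fe[["beta1"]]
    g <- evaluate_variance_fn(var_spec, D, 1)
    rows[[i]] <- data.frame(
      plot_id = sprintf("P%02d", i), species = "Lg", dbh_cm = D,
      height_m = mu + rnorm(n_trees, 0, sigma * g), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
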