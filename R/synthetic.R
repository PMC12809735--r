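# deterministic substreams: each generation stage reseeds from the global
# seed so e.g. adding trees does not perturb the plot covariates
.substream <- function(seed, k) {
  s <- (as.numeric(seed) %% 1000003) * 2017 + k * 7919
  as.integer(s %% 2147483629) + 1L
}

# exact truncated-normal draws by inverse CDF
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (lo >= hi) stop("truncated normal: min >= max", call. = FALSE)
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lo), hi)
}

# Weibull truncated to [lo, hi]; shape/scale by moment matching when absent
.rtrunc_weibull <- function(n, mean, sd, lo, hi, shape = NULL, scale = NULL) {
  if (is.null(shape)) shape <- (sd / mean)^(-1.086)  # Justus approximation
  if (is.null(scale)) scale <- mean / gamma(1 + 1 / shape)
  plo <- stats::pweibull(lo, shape, scale)
  phi <- stats::pweibull(hi, shape, scale)
  x <- stats::qweibull(stats::runif(n, plo, phi), shape, scale)
  pmin(pmax(x, lo), hi)
}

#' Default per-species diameter distributions
#'
#' Mixing weights and truncated-normal diameter laws for the five modelled
#' species of a Daxing'an-mountains mixed forest (birch Bp, Mongolian oak Qm,
#' aspen Pd, Dahurian larch Lg, Mongolian pine Ps), on the survey scale
#' (counts; diameters in cm, truncated at the 5 cm survey threshold).
#'
#' @return data.frame with `species`, `count`, `d_mean`, `d_sd`, `d_min`,
#'   `d_max`.
#' @export
default_species_table <- function() {
  data.frame(
    species = c("Bp", "Qm", "Pd", "Lg", "Ps"),
    count = c(2222, 166, 179, 4778, 440),
    d_mean = c(12.8, 11.9, 14.8, 15.2, 22.9),
    d_sd = c(4.9, 3.6, 4.9, 6.9, 8.7),
    d_min = rep(5, 5),
    d_max = c(40.0, 21.4, 30.9, 61.3, 59.0),
    stringsAsFactors = FALSE
  )
}

#' Default plot-covariate marginals
#'
#' Truncated-normal marginals (mean, SD, range) for the plot-level covariates
#' used by the models: soil organic carbon (g/kg), mean annual precipitation
#' (mm), mean annual temperature (C), elevation (m) and slope (degrees).
#' Covariates are drawn independently across plots.
#'
#' @return data.frame with `name`, `mean`, `sd`, `min`, `max`.
#' @export
default_covariate_table <- function() {
  data.frame(
    name = c("SOC", "MAP", "MAT", "elevation_m", "slope_deg"),
    mean = c(90.16, 454.10, -2.94, 791.10, 11),
    sd = c(34.47, 27.55, 1.03, 167.88, 9),
    min = c(37.20, 363.40, -4.57, 423.80, 0),
    max = c(159.30, 508.80, -0.17, 1135, 47),
    stringsAsFactors = FALSE
  )
}

#' Default simulation truth (fixed effects and variance components)
#'
#' Fixed effects of the full covariate model, plot-level SDs on `beta0` and
#' `beta1`, a species-within-plot SD on the `QMD` coefficient, and residual
#' scale, matching the magnitudes reported for mixed larch-birch forests.
#'
#' @return List with `fixed`, `re` (an [hd_re_spec()] with numeric values)
#'   and `sigma`.
#' @export
default_truth <- function() {
  list(
    fixed = c(beta0 = 1.784, beta1 = 0.823, SOC = -1e-3, MAP = 2e-4,
              SIM = 1.044e-1, BAL = 2e-3, QMD = -5e-3),
    re = hd_re_spec(plot = c("beta0", "beta1"), species = "QMD",
                    plot_cov = diag(c(0.736, 0.110)^2),
                    species_var = (1.6e-3)^2),
    sigma = 1.73
  )
}

#' Simulation configuration for synthetic mixed forests
#'
#' Defines the study conditions the generator emulates: number of plots, plot
#' areas and stem densities, per-plot species richness and composition,
#' per-species diameter laws, independent truncated-normal plot covariates,
#' and the data-generating truth (fixed effects, random-effect covariances,
#' variance function, residual scale).
#'
#' @param n_plots Number of plots (default 99).
#' @param trees_per_plot Fixed tree count per plot, or NULL (default) to
#'   derive counts from plot area times stem density.
#' @param seed Integer seed driving all substreams.
#' @param species Per-species table, see [default_species_table()].
#' @param covariates Plot-covariate table, see [default_covariate_table()].
#' @param area_ha,area_probs Plot-area values (ha) and sampling weights.
#' @param density Stem-density law, `c(mean, sd, min, max)` in stems/ha.
#' @param richness_probs Probabilities of 1..k species present in a plot.
#' @param dirichlet_alpha Concentration of within-plot composition.
#' @param fixed Named fixed-effects truth vector.
#' @param re [hd_re_spec()] with numeric `plot_cov` / `species_var` truth.
#' @param var_truth [hd_var_spec()] residual variance-function truth.
#' @param sigma Residual scale truth.
#' @param d_law `"truncated_normal"` (default) or `"weibull"`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_plots = 99, trees_per_plot = NULL, seed = 1,
                       species = default_species_table(),
                       covariates = default_covariate_table(),
                       area_ha = c(0.06, 0.1, 0.25),
                       area_probs = c(0.94, 0.05, 0.01),
                       density = c(mean = 1197, sd = 486, min = 290, max = 2667),
                       richness_probs = c(0.35, 0.30, 0.20, 0.10, 0.05),
                       dirichlet_alpha = 0.5,
                       fixed = default_truth()$fixed,
                       re = default_truth()$re,
                       var_truth = hd_var_spec("none"),
                       sigma = default_truth()$sigma,
                       d_law = c("truncated_normal", "weibull")) {
  d_law <- match.arg(d_law)
  if (nrow(species) == 0) stop("sim_config: empty species mix", call. = FALSE)
  if (any(covariates$min >= covariates$max)) {
    stop("sim_config: covariate min >= max", call. = FALSE)
  }
  if (any(species$d_min >= species$d_max)) {
    stop("sim_config: species d_min >= d_max", call. = FALSE)
  }
  species$weight <- species$count / sum(species$count)
  richness_probs <- richness_probs[seq_len(min(length(richness_probs),
                                               nrow(species)))]
  richness_probs <- richness_probs / sum(richness_probs)
  structure(list(
    n_plots = n_plots, trees_per_plot = trees_per_plot, seed = as.integer(seed),
    species = species, covariates = covariates,
    area_ha = area_ha, area_probs = area_probs / sum(area_probs),
    density = density, richness_probs = richness_probs,
    dirichlet_alpha = dirichlet_alpha,
    fixed = fixed, re = re, var_truth = var_truth, sigma = sigma,
    d_law = d_law
  ), class = "sim_config")
}

#' Generate the plot-covariate table
#'
#' Draws plot areas, stem densities and every configured covariate from
#' truncated normals; deterministic under the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return data.frame with `plot_id`, `area_ha`, `n_trees` and one column per
#'   covariate.
#' @export
generate_plots <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream(cfg$seed, 1L))
  n <- cfg$n_plots
  plots <- data.frame(plot_id = sprintf("P%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
  # deterministic area composition (largest-remainder rounding of the
  # weights), shuffled across plots: keeps the realized total area, and hence
  # the expected tree count, stable across seeds
  cnt <- floor(cfg$area_probs * n)
  rem <- cfg$area_probs * n - cnt
  short <- n - sum(cnt)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    cnt[add] <- cnt[add] + 1L
  }
  plots$area_ha <- sample(rep(cfg$area_ha, cnt))
  dens <- .rtrunc_norm(n, cfg$density[["mean"]], cfg$density[["sd"]],
                       cfg$density[["min"]], cfg$density[["max"]])
  plots$n_trees <- if (!is.null(cfg$trees_per_plot)) {
    rep(as.integer(cfg$trees_per_plot), n)
  } else {
    pmax(5L, as.integer(round(plots$area_ha * dens)))
  }
  for (i in seq_len(nrow(cfg$covariates))) {
    cv <- cfg$covariates[i, ]
    plots[[cv$name]] <- .rtrunc_norm(n, cv$mean, cv$sd, cv$min, cv$max)
  }
  plots
}

#' Generate the tree table (without heights)
#'
#' Species composition is drawn per plot: a species richness from
#' `richness_probs`, a species subset weighted by the global mixing weights,
#' and within-plot proportions from a symmetric Dirichlet. Diameters follow
#' the per-species truncated law. The stand covariates coupled to the model
#' (QMD, SIM and per-tree BAL) are then computed from the realized trees, not
#' sampled, so they are coherent with the tree list by construction.
#'
#' @param cfg A [sim_config()].
#' @param plots Output of [generate_plots()].
#' @return List with `trees` (plot_id, species, dbh_cm, BAL) and `plots`
#'   (input plus realized `QMD`, `SIM`, `SHI`).
#' @export
generate_trees <- function(cfg, plots) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream(cfg$seed, 2L))
  sp <- cfg$species
  out <- vector("list", nrow(plots))
  plots$QMD <- NA_real_; plots$SIM <- NA_real_; plots$SHI <- NA_real_
  for (i in seq_len(nrow(plots))) {
    n_i <- plots$n_trees[i]
    S <- sample.int(length(cfg$richness_probs), 1, prob = cfg$richness_probs)
    subset_idx <- sample.int(nrow(sp), S, prob = sp$weight)
    props <- stats::rgamma(S, shape = cfg$dirichlet_alpha, rate = 1)
    if (sum(props) <= 0) props <- rep(1, S)
    props <- props / sum(props)
    sp_draw <- subset_idx[sample.int(S, n_i, replace = TRUE, prob = props)]
    d <- numeric(n_i)
    for (k in unique(sp_draw)) {
      rows <- which(sp_draw == k)
      d[rows] <- if (cfg$d_law == "truncated_normal") {
        .rtrunc_norm(length(rows), sp$d_mean[k], sp$d_sd[k],
                     sp$d_min[k], sp$d_max[k])
      } else {
        .rtrunc_weibull(length(rows), sp$d_mean[k], sp$d_sd[k],
                        sp$d_min[k], sp$d_max[k])
      }
    }
    bal <- compute_bal(d, plots$area_ha[i])
    counts <- table(sp$species[sp_draw])
    plots$QMD[i] <- compute_qmd(d)
    plots$SIM[i] <- simpson_index(counts)
    plots$SHI[i] <- shannon_index(counts)
    out[[i]] <- data.frame(plot_id = plots$plot_id[i],
                           species = sp$species[sp_draw],
                           dbh_cm = d, BAL = bal, stringsAsFactors = FALSE)
  }
  list(trees = do.call(rbind, out), plots = plots)
}

#' Simulate heights under the hierarchical error model
#'
#' Draws plot-level effects from `N(0, plot_cov)`, species-within-plot effects
#' from `N(0, species_var)` and residuals from `N(0, (sigma * g(D))^2)` per
#' the variance-function truth, then forms
#' `H = 1.3 + (beta0 + u_1) * D^(beta1 + u_2 + ... + (beta_QMD + v) * QMD) + e`.
#' Heights at or below breast height are redrawn up to 10 times, then clipped
#' to 1.31 m with a count recorded.
#'
#' @param cfg A [sim_config()].
#' @param gen Output of [generate_trees()] (or NULL to generate internally).
#' @return Object of class `hd_synth`: `frame` (the modelling frame with
#'   heights), `dataset` (a [forest_dataset()]), `truth` (config, realized
#'   random effects, clip count).
#' @export
simulate_heights <- function(cfg, gen = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(gen)) gen <- generate_trees(cfg, generate_plots(cfg))
  trees <- gen$trees; plots <- gen$plots
  covn <- setdiff(names(cfg$fixed), c("beta0", "beta1"))
  spec <- hd_model_spec(covn)

  frame <- trees
  plot_cols <- setdiff(names(plots), c("plot_id"))
  midx <- match(frame$plot_id, plots$plot_id)
  for (col in plot_cols) {
    if (!col %in% names(frame)) frame[[col]] <- plots[[col]][midx]
  }
  frame$height_m <- 0  # placeholder for the design structure

  re <- cfg$re
  st <- .nlme_struct(frame, spec, re)

  # fixed-effect exponent must stay in (0, 2) over the simulated covariates
  ev0 <- .cond_eval(st, cfg$fixed,
                    matrix(0, st$q1, length(st$plots)),
                    lapply(st$plots, function(pl) numeric(pl$s)))
  if (min(ev0$expo) <= 0 || max(ev0$expo) >= 2) {
    stop(sprintf(
      "simulate_heights: fixed-effect exponent outside (0, 2) (range %.3f..%.3f)",
      min(ev0$expo), max(ev0$expo)), call. = FALSE)
  }

  set.seed(.substream(cfg$seed, 3L))
  u <- matrix(0, st$q1, length(st$plots))
  if (st$q1 > 0) {
    if (is.null(re$plot_cov)) stop("re$plot_cov truth required", call. = FALSE)
    eg <- eigen(re$plot_cov, symmetric = TRUE)  # exact also for zero matrices
    L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), st$q1)
    u <- L %*% matrix(stats::rnorm(st$q1 * length(st$plots)),
                      st$q1, length(st$plots))
  }
  v <- lapply(st$plots, function(pl) {
    if (pl$s == 0) return(numeric(0))
    stats::rnorm(pl$s, 0, sqrt(re$species_var))
  })

  ev <- .cond_eval(st, cfg$fixed, u, v)
  if (min(ev$expo) <= 0 || max(ev$expo) >= 2) {
    warning("simulate_heights: realized exponent outside (0, 2) in some plots",
            call. = FALSE)
  }

  set.seed(.substream(cfg$seed, 4L))
  sdv <- cfg$sigma * .varfn_g(cfg$var_truth$kind, cfg$var_truth$gamma, st$D)
  h <- ev$f + stats::rnorm(st$n, 0, sdv)
  bad <- which(h <= 1.3)
  tries <- 0L
  while (length(bad) && tries < 10L) {
    h[bad] <- ev$f[bad] + stats::rnorm(length(bad), 0, sdv[bad])
    bad <- which(h <= 1.3)
    tries <- tries + 1L
  }
  n_clipped <- length(bad)
  if (n_clipped) {
    h[bad] <- 1.31
    message(sprintf("simulate_heights: %d height(s) clipped to 1.31 m",
                    n_clipped))
  }
  frame$height_m <- h

  ds_trees <- frame[, c("plot_id", "species", "dbh_cm", "height_m")]
  ds <- forest_dataset(ds_trees, plots,
                       species_registry = cfg$species$species)
  structure(list(
    frame = frame,
    dataset = ds,
    truth = list(config = cfg,
                 plot_effects = if (st$q1 > 0) {
                   m <- t(u); dimnames(m) <- list(names(st$plots), re$plot); m
                 } else NULL,
                 species_effects = v,
                 noiseless = ev$f,
                 n_clipped = n_clipped)
  ), class = "hd_synth")
}

#' @export
print.hd_synth <- function(x, ...) {
  cat(sprintf("hd_synth: %d trees in %d plots (seed %d)\n",
              nrow(x$frame), x$truth$config$n_plots, x$truth$config$seed))
  invisible(x)
}

#' Named synthetic-forest presets
#'
#' `tiny`: 3 plots x 5 trees for oracle tests. `survey_scale`: 99 plots,
#' roughly 7,800 trees, five species with the study-scale diameter and
#' covariate marginals and the default hierarchical truth. `heteroscedastic`:
#' `survey_scale` with a constant-plus-power residual SD
#' (`sigma * |0.5 + D^0.8|`, sigma scaled to keep the mid-diameter residual
#' SD near the homoscedastic preset).
#'
#' @param name One of `"tiny"`, `"survey_scale"`, `"heteroscedastic"`.
#' @param seed Integer seed.
#' @return An `hd_synth` object.
#' @export
make_fixture <- function(name = c("tiny", "survey_scale", "heteroscedastic"),
                         seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = sim_config(n_plots = 3, trees_per_plot = 5, seed = seed),
    survey_scale = sim_config(seed = seed),
    heteroscedastic = sim_config(seed = seed,
                                 var_truth = hd_var_spec("constant_plus_power",
                                                         c(0.5, 0.8)),
                                 sigma = 0.18)
  )
  simulate_heights(cfg)
}
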