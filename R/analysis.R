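#' Per-species allometric scaling exponents
#'
#' Fits the base power model per species and pooled across species, and
#' compares each exponent against the metabolic-scaling prediction
#' `H ~ D^(2/3)` via a Wald confidence interval.
#'
#' @param data Modelling frame with `species`, `dbh_cm`, `height_m`.
#' @param min_species_n Minimum trees per species (default 100).
#' @param theory Theoretical exponent (default 2/3).
#' @param level Confidence level (default 0.95).
#' @return List of class `hd_exponents`: `by_species` (data.frame with
#'   `beta1`, `se`, `ci_lo`, `ci_hi`, `excludes_theory`), `cross_species`
#'   (pooled exponent), `theory`.
#' @export
species_exponents <- function(data, min_species_n = 100, theory = 2 / 3,
                              level = 0.95) {
  fits <- stage1_species_fits(data, min_species_n = min_species_n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  fits$ci_lo <- fits$beta1 - z * fits$se_beta1
  fits$ci_hi <- fits$beta1 + z * fits$se_beta1
  fits$excludes_theory <- fits$ci_lo > theory | fits$ci_hi < theory
  counts <- table(data$species)
  keep <- data$species %in% names(counts)[counts >= min_species_n]
  pooled <- fit_hd_nls(data[keep, , drop = FALSE], hd_model_spec())
  structure(list(by_species = fits,
                 cross_species = pooled$estimates[["beta1"]],
                 cross_species_se = pooled$se[["beta1"]],
                 theory = theory),
            class = "hd_exponents")
}

#' @export
print.hd_exponents <- function(x, ...) {
  cat(sprintf("cross-species scaling exponent: %.3f (theory %.3f)\n",
              x$cross_species, x$theory))
  print(x$by_species, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Covariate-gradient height curves
#'
#' Population-level (random effects at zero) height predictions over a
#' diameter grid with the target covariate set to its 5th, 50th and 95th
#' empirical percentiles and all other covariates at their means. Percentiles
#' and means are computed per species from each species' own covariate
#' distribution, so curves are species-specific even at the population level.
#'
#' @param fit Fitted `hd_nls` or `hd_nlme` with covariates in the exponent.
#' @param data Modelling frame (source of the empirical covariate
#'   distribution; must contain `species` and the model covariates).
#' @param target Covariate to vary.
#' @param d_grid Diameter grid, cm (default 20 points over the species' D
#'   range).
#' @param probs Percentile nodes (default `c(0.05, 0.5, 0.95)`).
#' @return data.frame of class `hd_gradient` with `species`, `node`,
#'   `node_value`, `dbh_cm`, `height_m`.
#' @export
gradient_simulation <- function(fit, data, target, d_grid = NULL,
                                probs = c(0.05, 0.5, 0.95)) {
  covn <- fit$spec$covariates
  if (!target %in% covn) {
    stop(sprintf("gradient_simulation: '%s' is not a fitted covariate", target),
         call. = FALSE)
  }
  fe <- fit$estimates
  rows <- list()
  for (s in unique(data$species)) {
    d <- data[data$species == s, , drop = FALSE]
    grid <- if (is.null(d_grid)) {
      seq(min(d$dbh_cm), max(d$dbh_cm), length.out = 20)
    } else d_grid
    nodes <- stats::quantile(d[[target]], probs = probs, type = 7, names = FALSE)
    base_covs <- vapply(covn, function(cv) mean(d[[cv]]), numeric(1))
    for (k in seq_along(nodes)) {
      covs <- base_covs
      covs[target] <- nodes[k]
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, node = paste0("p", probs[k] * 100),
        node_value = nodes[k], dbh_cm = grid,
        height_m = predict_height(fe, grid, as.list(covs)),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("hd_gradient", "data.frame"))
}

#' Marginal covariate slopes by species
#'
#' Finite-difference sensitivity of the predicted height to each covariate,
#' evaluated at the species' covariate means and median diameter, with step
#' 1% of the covariate SD (falling back to 1% of the mean magnitude for
#' near-constant covariates).
#'
#' @param fit Fitted `hd_nls` or `hd_nlme`.
#' @param data Modelling frame with `species` and the model covariates.
#' @param step_frac Step as a fraction of the covariate SD (default 0.01).
#' @return data.frame with `species`, `covariate`, `slope` (m per covariate
#'   unit).
#' @export
slope_summary <- function(fit, data, step_frac = 0.01) {
  covn <- fit$spec$covariates
  if (!length(covn)) stop("slope_summary: model has no covariates", call. = FALSE)
  fe <- fit$estimates
  rows <- list()
  for (s in unique(data$species)) {
    d <- data[data$species == s, , drop = FALSE]
    d_med <- stats::median(d$dbh_cm)
    means <- vapply(covn, function(cv) mean(d[[cv]]), numeric(1))
    for (cv in covn) {
      h <- step_frac * stats::sd(d[[cv]])
      if (!is.finite(h) || h == 0) h <- step_frac * max(abs(means[cv]), 1)
      up <- means; up[cv] <- up[cv] + h
      dn <- means; dn[cv] <- dn[cv] - h
      slope <- (predict_height(fe, d_med, as.list(up)) -
                  predict_height(fe, d_med, as.list(dn))) / (2 * h)
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, covariate = cv, slope = slope, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
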