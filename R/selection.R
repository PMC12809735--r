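#' Stage-1 per-species base-model fits
#'
#' Fits the base power model `H = 1.3 + beta0 * D^beta1` separately to each
#' species with at least `min_species_n` trees (the `nlsList` idiom).
#' Non-convergent species are reported in the result, not fatal.
#'
#' @param data Modelling frame with `species`, `dbh_cm`, `height_m`.
#' @param min_species_n Minimum trees per group (default 100).
#' @param group_col Grouping column, `"species"` by default; pass
#'   `"plot_id"` for plot-level refits.
#' @return data.frame with one row per fitted group: `species` (the group
#'   label), `n`, `beta0`, `beta1`, `se_beta0`, `se_beta1`, `converged`.
#' @export
stage1_species_fits <- function(data, min_species_n = 100,
                                group_col = "species") {
  counts <- table(data[[group_col]])
  keep <- names(counts)[counts >= min_species_n]
  rows <- lapply(keep, function(s) {
    d <- data[data[[group_col]] == s, , drop = FALSE]
    ft <- tryCatch(fit_hd_nls(d, hd_model_spec()), error = function(e) NULL)
    if (is.null(ft)) {
      return(data.frame(species = s, n = nrow(d), beta0 = NA_real_,
                        beta1 = NA_real_, se_beta0 = NA_real_,
                        se_beta1 = NA_real_, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    data.frame(species = s, n = nrow(d),
               beta0 = ft$estimates[["beta0"]], beta1 = ft$estimates[["beta1"]],
               se_beta0 = ft$se[["beta0"]], se_beta1 = ft$se[["beta1"]],
               converged = ft$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stage-1 correlations of model coefficients with candidate covariates
#'
#' Pearson correlation and two-sided p-value for every (coefficient,
#' covariate) pair across units (species-level coefficients by default, or
#' plot-level refits). Constant covariates yield an undefined correlation,
#' reported as NA with a note.
#'
#' @param coefs data.frame of per-unit coefficients; every numeric column is
#'   treated as a coefficient (e.g. `beta0`, `beta1`).
#' @param candidates data.frame of per-unit covariate values, rows aligned
#'   with `coefs`.
#' @return data.frame with `coefficient`, `covariate`, `r`, `p_value`, `note`.
#' @export
stage1_correlations <- function(coefs, candidates) {
  stopifnot(nrow(coefs) == nrow(candidates))
  if (nrow(coefs) < 3) {
    stop("stage1_correlations: need >= 3 units", call. = FALSE)
  }
  coef_cols <- names(coefs)[vapply(coefs, is.numeric, logical(1))]
  cov_cols <- names(candidates)[vapply(candidates, is.numeric, logical(1))]
  rows <- list()
  for (cf in coef_cols) for (cv in cov_cols) {
    x <- coefs[[cf]]; y <- candidates[[cv]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        coefficient = cf, covariate = cv, r = NA_real_, p_value = NA_real_,
        note = "undefined (constant or insufficient data)",
        stringsAsFactors = FALSE)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      coefficient = cf, covariate = cv, r = unname(ct$estimate),
      p_value = ct$p.value, note = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Variance-inflation-factor filter
#'
#' Iteratively drops the covariate with the highest VIF (`1/(1 - R2_j)` from
#' regressing covariate j on the remaining candidates) until all VIFs are at
#' or below the threshold. Exact collinearity (infinite VIF) is dropped
#' immediately. Ties break lexicographically; the procedure is deterministic.
#'
#' @param candidates data.frame of numeric candidate covariates (n > p).
#' @param threshold VIF threshold (default 5, the screening rule).
#' @return List with `kept` (character), `dropped` (character, in drop order)
#'   and `vif` (named vector over the kept set).
#' @export
vif_filter <- function(candidates, threshold = 5) {
  stopifnot(is.data.frame(candidates))
  X <- as.data.frame(lapply(candidates, as.numeric))
  if (ncol(X) < 2) stop("vif_filter: need >= 2 candidates", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("vif_filter: need n > p", call. = FALSE)
  compute_vif <- function(cols) {
    vapply(cols, function(j) {
      fit <- stats::lm(stats::reformulate(cols[cols != j], response = j),
                       data = X)
      # exact collinearity (infinite VIF) is an expected input here
      r2j <- suppressWarnings(summary(fit)$r.squared)
      if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
    }, numeric(1))
  }
  cols <- sort(names(X))
  dropped <- character(0)
  while (length(cols) >= 2) {
    v <- compute_vif(cols)
    if (max(v) <= threshold) break
    worst <- names(v)[v == max(v)][1]  # lexicographic tie-break (sorted cols)
    if (is.infinite(max(v))) {
      message(sprintf("vif_filter: '%s' exactly collinear, dropped", worst))
    }
    dropped <- c(dropped, worst)
    cols <- setdiff(cols, worst)
  }
  vif <- if (length(cols) >= 2) compute_vif(cols) else
    stats::setNames(rep(1, length(cols)), cols)
  list(kept = cols, dropped = dropped, vif = vif)
}

#' AIC ladder over nested covariate additions
#'
#' Fits the nested sequence of exponent-covariate models starting from the
#' base power model and adding covariate groups in the given order (default:
#' QMD for developmental stage, BAL for competition, SIM for species
#' diversity, MAP for climate, SOC for soil), reporting AIC, log-likelihood
#' and R2 per rung. Non-convergent rungs are recorded and the ladder
#' continues.
#'
#' @param data Modelling frame.
#' @param order Character vector of covariates added one per rung.
#' @return data.frame with `model`, `variables`, `AIC`, `LL`, `R2`,
#'   `converged`; attribute `"best"` holds the minimal-AIC model label.
#' @export
aic_ladder <- function(data, order = c("QMD", "BAL", "SIM", "MAP", "SOC")) {
  labels <- c("Basic", paste0("M", seq_along(order)))
  rows <- list()
  for (i in seq_len(length(order) + 1L)) {
    covs <- if (i == 1) character(0) else order[seq_len(i - 1L)]
    ft <- tryCatch(fit_hd_nls(data, hd_model_spec(covs)),
                   error = function(e) NULL)
    rows[[i]] <- data.frame(
      model = labels[i],
      variables = paste(c("D", covs), collapse = " + "),
      AIC = if (is.null(ft)) NA_real_ else ft$aic,
      LL = if (is.null(ft)) NA_real_ else ft$loglik,
      R2 = if (is.null(ft)) NA_real_ else r2(data$height_m, ft$fitted),
      converged = if (is.null(ft)) FALSE else ft$converged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- which(!is.na(out$AIC))
  attr(out, "best") <- out$model[ok[which.min(out$AIC[ok])]]
  out
}

#' Serialize a selection result to JSON
#'
#' @param x A list (e.g. stage-1 tables, VIF result, ladder).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
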