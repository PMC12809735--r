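#' Coefficient of determination
#'
#' `1 - SSE/SST` about the observed mean. Undefined (NA with a warning) when
#' the observations are constant.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return R-squared (can be negative for a bad model).
#' @export
r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("r2: zero total sum of squares; R2 undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / sst
}

#' Root mean square error
#'
#' @inheritParams r2
#' @return RMSE in the units of the response (m for heights).
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1)
  sqrt(mean((observed - predicted)^2))
}

#' Total relative error (signed aggregate bias)
#'
#' `100 * sum(observed - predicted) / sum(predicted)`, in percent; positive
#' when observations exceed predictions on aggregate. No absolute value is
#' taken.
#'
#' @inheritParams r2
#' @return TRE, %.
#' @export
tre <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sp <- sum(predicted)
  if (sp == 0) stop("tre: sum of predictions is zero", call. = FALSE)
  100 * sum(observed - predicted) / sp
}

#' Goodness-of-fit report
#'
#' R2, RMSE and TRE overall and, optionally, per species.
#'
#' @inheritParams r2
#' @param species Optional grouping vector aligned with the data.
#' @return List of class `hd_eval`: `r2`, `rmse`, `tre`, `n`, `by_species`
#'   (data.frame or NULL).
#' @export
eval_report <- function(observed, predicted, species = NULL) {
  out <- list(r2 = r2(observed, predicted),
              rmse = rmse(observed, predicted),
              tre = tre(observed, predicted),
              n = length(observed), by_species = NULL)
  if (!is.null(species)) {
    idx <- split(seq_along(observed), species)
    out$by_species <- do.call(rbind, lapply(names(idx), function(s) {
      i <- idx[[s]]
      data.frame(species = s, n = length(i),
                 r2 = if (length(i) >= 2) r2(observed[i], predicted[i]) else NA,
                 rmse = rmse(observed[i], predicted[i]),
                 tre = tre(observed[i], predicted[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(out, class = "hd_eval")
}

#' @export
print.hd_eval <- function(x, ...) {
  cat(sprintf("n = %d: R2 %.3f, RMSE %.3f m, TRE %.2f%%\n",
              x$n, x$r2, x$rmse, x$tre))
  if (!is.null(x$by_species)) print(x$by_species, row.names = FALSE)
  invisible(x)
}

#' Evaluate a fitted model
#'
#' Convenience wrapper producing an [eval_report()] from a fitted `hd_nls` or
#' `hd_nlme` object. For mixed-effects fits the default uses conditional
#' (random-effects-included) predictions; `level = "population"` uses the
#' fixed effects only.
#'
#' @param fit `hd_nls` or `hd_nlme` fit.
#' @param data Data used for the fit (defaults to the frame stored on the fit).
#' @param level Prediction level for mixed fits.
#' @return An `hd_eval` report.
#' @export
hd_evaluate <- function(fit, data = fit$data,
                        level = c("conditional", "population")) {
  level <- match.arg(level)
  pred <- if (inherits(fit, "hd_nlme")) {
    if (identical(data, fit$data)) predict(fit, level = level)
    else predict(fit, newdata = data, level = "population")
  } else {
    predict(fit, newdata = data)
  }
  eval_report(data$height_m, pred,
              species = if ("species" %in% names(data)) data$species else NULL)
}

#' Partial R-squared decomposition by refitting
#'
#' For each covariate in the full model, the reduced model dropping that
#' covariate is refit and the partial R2 is `R2_full - R2_reduced`. For the
#' diameter term itself the reduced model drops the diameter entirely
#' (`H = 1.3 + beta0`, a constant), so its partial R2 equals the full-model
#' R2. Terms whose reduced fit fails to converge are reported as NA.
#'
#' @param data Modelling frame with `dbh_cm`, `height_m` and covariates.
#' @param spec Full-model [hd_model_spec()].
#' @param fitter Fitting function, `fit_hd_nls` by default (any function with
#'   the same `(data, spec)` signature returning `$fitted` and `$converged`).
#' @param include_dbh Include the diameter term in the decomposition.
#' @return Named numeric vector of partial R2 values, decreasing.
#' @export
partial_r2 <- function(data, spec, fitter = fit_hd_nls, include_dbh = TRUE) {
  stopifnot(inherits(spec, "hd_model_spec"))
  full <- fitter(data, spec)
  if (!isTRUE(full$converged)) {
    stop("partial_r2: full model did not converge", call. = FALSE)
  }
  r2_full <- r2(data$height_m, full$fitted)
  out <- numeric(0)
  for (cv in spec$covariates) {
    red_spec <- hd_model_spec(setdiff(spec$covariates, cv))
    red <- tryCatch(fitter(data, red_spec), error = function(e) NULL)
    out[cv] <- if (!is.null(red) && isTRUE(red$converged)) {
      r2_full - r2(data$height_m, red$fitted)
    } else NA_real_
  }
  if (include_dbh) {
    # dropping D: constant-mean model, R2 = 0 by construction
    out["D"] <- r2_full
  }
  sort(out, decreasing = TRUE, na.last = TRUE)
}
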