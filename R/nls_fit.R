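#' Height-diameter model specification
#'
#' The base model is the power law `H = 1.3 + beta0 * D^beta1`. Covariates
#' extend the scaling exponent additively:
#' `H = 1.3 + beta0 * D^(beta1 + sum_j beta_j * x_j)`, with one coefficient
#' per named covariate column (the study's choice: SOC, MAP, SIM, BAL, QMD).
#'
#' @param covariates Character vector of covariate column names entering the
#'   exponent (empty for the base model).
#' @return Object of class `hd_model_spec`.
#' @export
hd_model_spec <- function(covariates = character(0)) {
  stopifnot(is.character(covariates))
  if (anyDuplicated(covariates)) {
    stop("hd_model_spec: duplicated covariate names", call. = FALSE)
  }
  structure(list(covariates = covariates,
                 params = c("beta0", "beta1", covariates)),
            class = "hd_model_spec")
}

# Evaluate the model and its derivatives at per-tree parameter values.
# beta: named vector (beta0, beta1, covariates); X: n x m covariate matrix;
# add0 / adde: per-row additions to beta0 / to the exponent (random effects).
.hd_eval <- function(beta, D, X, add0 = 0, adde = 0) {
  m <- if (is.null(X)) 0L else ncol(X)
  expo <- beta[["beta1"]] + adde
  if (m > 0) expo <- expo + drop(X %*% beta[colnames(X)])
  if (any(!is.finite(expo)) || max(abs(expo)) > 20) {
    stop("hd model: exponent overflow; check covariate scaling", call. = FALSE)
  }
  A <- beta[["beta0"]] + add0
  De <- D^expo
  f <- 1.3 + A * De
  list(f = f, De = De, dexpo = A * De * log(D), expo = expo, A = A)
}

# Jacobian of predictions w.r.t. the fixed effects, columns in spec$params order.
.hd_jacobian <- function(ev, X) {
  J <- cbind(beta0 = ev$De, beta1 = ev$dexpo)
  if (!is.null(X) && ncol(X) > 0) {
    J <- cbind(J, ev$dexpo * X)
  }
  J
}

.hd_design <- function(data, spec) {
  need <- c("dbh_cm", "height_m", spec$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  cc <- stats::complete.cases(data[, need, drop = FALSE])
  if (!all(cc)) {
    stop(sprintf("%d row(s) have missing values in modelling columns", sum(!cc)),
         call. = FALSE)
  }
  if (any(data$dbh_cm <= 0)) stop("dbh_cm must be positive", call. = FALSE)
  X <- if (length(spec$covariates)) {
    as.matrix(data[, spec$covariates, drop = FALSE])
  } else NULL
  list(D = data$dbh_cm, H = data$height_m, X = X)
}

#' Predict tree height from fixed effects
#'
#' `H = 1.3 + beta0 * D^(beta1 + sum beta_j x_j)`; reduces to the base power
#' model when no covariate coefficients are present.
#'
#' @param fe Named numeric vector with `beta0`, `beta1` and optionally one
#'   coefficient per covariate, or a fitted `hd_nls` / `hd_nlme` object.
#' @param dbh_cm Diameter(s), cm, positive.
#' @param covs Named list/vector or data.frame supplying each covariate named
#'   in `fe` (recycled to the length of `dbh_cm` if scalar).
#' @return Predicted height(s), m.
#' @export
predict_height <- function(fe, dbh_cm, covs = NULL) {
  if (inherits(fe, "hd_nls") || inherits(fe, "hd_nlme")) fe <- fe$estimates
  fe <- unlist(fe)
  if (any(dbh_cm <= 0)) stop("predict_height: dbh_cm must be positive",
                             call. = FALSE)
  covnames <- setdiff(names(fe), c("beta0", "beta1"))
  X <- NULL
  if (length(covnames)) {
    if (is.null(covs)) {
      stop(sprintf("predict_height: missing covariate '%s'", covnames[1]),
           call. = FALSE)
    }
    covs <- as.data.frame(as.list(covs))
    miss <- setdiff(covnames, names(covs))
    if (length(miss)) {
      stop(sprintf("predict_height: missing covariate '%s'", miss[1]),
           call. = FALSE)
    }
    X <- sapply(covnames, function(nm) rep_len(covs[[nm]], length(dbh_cm)))
    X <- matrix(X, nrow = length(dbh_cm),
                dimnames = list(NULL, covnames))
  }
  .hd_eval(fe, dbh_cm, X)$f
}

#' Starting values from log-linearization
#'
#' Ordinary least squares of `log(H - 1.3)` on `log(D)` gives exact starting
#' values for noiseless power-law data; covariate coefficients start at 0.
#' Rows with `H <= 1.3` are excluded (with a message) since the log is
#' undefined there.
#'
#' @param dbh_cm Diameters, cm.
#' @param height_m Heights, m.
#' @param covariates Character vector of covariate names (start at 0).
#' @return Named numeric vector of starting values.
#' @export
auto_start <- function(dbh_cm, height_m, covariates = character(0)) {
  keep <- !is.na(height_m) & height_m > 1.3 & !is.na(dbh_cm) & dbh_cm > 0
  if (sum(keep) < 3) {
    stop("auto_start: fewer than 3 usable observations (H > 1.3 m)",
         call. = FALSE)
  }
  if (any(!keep)) {
    message(sprintf("auto_start: %d row(s) with H <= 1.3 m excluded",
                    sum(!keep)))
  }
  ols <- stats::lm.fit(cbind(1, log(dbh_cm[keep])), log(height_m[keep] - 1.3))
  start <- c(beta0 = exp(ols$coefficients[[1]]), beta1 = ols$coefficients[[2]])
  c(start, stats::setNames(rep(0, length(covariates)), covariates))
}

# Back-transformation matrix from internally z-scaled covariates to the raw
# scale: beta_raw = T %*% beta_scaled (beta0 untouched; beta1 absorbs the
# centring; covariate coefficients divide by their SDs).
.unscale_matrix <- function(params, scale_info) {
  p <- length(params)
  T <- diag(p)
  dimnames(T) <- list(params, params)
  for (nm in names(scale_info$mu)) {
    T[nm, nm] <- 1 / scale_info$sd[[nm]]
    T["beta1", nm] <- -scale_info$mu[[nm]] / scale_info$sd[[nm]]
  }
  T
}

#' Fit the height-diameter model by nonlinear least squares
#'
#' Damped Gauss-Newton (Levenberg-Marquardt) minimization of the residual sum
#' of squares with an analytic Jacobian. Covariates are z-scaled internally
#' for conditioning and the estimates, covariance and standard errors are
#' back-transformed exactly to the raw scale. The Gaussian log-likelihood uses
#' the ML variance `sigma^2 = SSE/n` so AIC is comparable with the
#' mixed-effects engine's ML fits; standard errors use `SSE/(n - p)`.
#'
#' @param data data.frame with columns `dbh_cm`, `height_m` and every
#'   covariate named in `spec`.
#' @param spec An [hd_model_spec()].
#' @param start Optional named starting vector; default [auto_start()].
#' @param tol Convergence tolerance on the relative SSE change (default 1e-10);
#'   a gradient max-norm below 1e-8 (on the scaled problem) also stops.
#' @param max_iter Maximum accepted LM iterations (default 200).
#' @param scale Internally z-scale covariates (default TRUE).
#' @return Object of class `hd_nls` with elements `estimates`, `se`,
#'   `p_values`, `vcov`, `sigma` (ML residual SD), `loglik`, `aic`, `bic`,
#'   `k`, `residuals`, `fitted`, `converged`, `n_iter`, `trace`, `n`, `spec`.
#' @export
fit_hd_nls <- function(data, spec = hd_model_spec(), start = NULL,
                       tol = 1e-10, max_iter = 200, scale = TRUE) {
  stopifnot(inherits(spec, "hd_model_spec"))
  des <- .hd_design(data, spec)
  D <- des$D; H <- des$H; X <- des$X
  n <- length(D); p <- length(spec$params)
  if (n < p + 1) stop("fit_hd_nls: need n >= p + 1 observations", call. = FALSE)

  scale_info <- list(mu = list(), sd = list())
  Xs <- X
  if (scale && !is.null(X)) {
    for (j in seq_len(ncol(X))) {
      mu <- mean(X[, j]); s <- stats::sd(X[, j])
      if (!is.finite(s) || s == 0) s <- 1
      scale_info$mu[[colnames(X)[j]]] <- mu
      scale_info$sd[[colnames(X)[j]]] <- s
      Xs[, j] <- (X[, j] - mu) / s
    }
  }

  beta <- if (is.null(start)) {
    auto_start(D, H, spec$covariates)
  } else {
    st <- unlist(start)[spec$params]
    if (any(is.na(st))) stop("fit_hd_nls: start must name every parameter",
                             call. = FALSE)
    # convert user start (raw scale) to the scaled parameterization
    if (length(scale_info$mu)) {
      for (nm in names(scale_info$mu)) {
        st[["beta1"]] <- st[["beta1"]] + st[[nm]] * scale_info$mu[[nm]]
        st[[nm]] <- st[[nm]] * scale_info$sd[[nm]]
      }
    }
    st
  }
  names(beta) <- spec$params

  sse <- function(b) {
    ev <- tryCatch(.hd_eval(b, D, Xs), error = function(e) NULL)
    if (is.null(ev)) return(list(sse = Inf, ev = NULL))
    r <- H - ev$f
    list(sse = sum(r^2), ev = ev, r = r)
  }

  cur <- sse(beta)
  if (!is.finite(cur$sse)) stop("fit_hd_nls: invalid starting values",
                                call. = FALSE)
  lambda <- 1e-3
  trace <- cur$sse
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    J <- .hd_jacobian(cur$ev, Xs)
    g <- crossprod(J, cur$r)
    if (max(abs(g)) < 1e-8 * max(1, cur$sse)) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    dg <- diag(JtJ)
    if (any(dg <= 0)) {
      stop("fit_hd_nls: singular Jacobian; consider rescaling covariates",
           call. = FALSE)
    }
    accepted <- FALSE
    for (tries in 1:30) {
      A <- JtJ + lambda * diag(dg, nrow = length(dg))
      step <- tryCatch(drop(solve(A, g)), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- sse(beta + stats::setNames(step, spec$params))
        if (is.finite(cand$sse) && cand$sse <= cur$sse) {
          rel <- (cur$sse - cand$sse) / max(cur$sse, .Machine$double.eps)
          beta <- beta + stats::setNames(step, spec$params)
          cur <- cand
          lambda <- max(lambda / 4, 1e-12)
          accepted <- TRUE
          iter <- iter + 1L
          trace <- c(trace, cur$sse)
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 8
    }
    if (!accepted || converged) break
  }

  J <- .hd_jacobian(cur$ev, Xs)
  JtJ <- crossprod(J)
  sigma2_ml <- cur$sse / n
  cov_s <- tryCatch(cur$sse / (n - p) * solve(JtJ), error = function(e) {
    warning("fit_hd_nls: near-singular Jacobian at the optimum; SEs unreliable")
    cur$sse / (n - p) * MASS_ginv(JtJ)
  })
  T <- .unscale_matrix(spec$params, scale_info)
  est <- drop(T %*% beta)
  names(est) <- spec$params
  vc <- T %*% cov_s %*% t(T)
  dimnames(vc) <- list(spec$params, spec$params)
  se <- sqrt(pmax(diag(vc), 0))
  z <- est / se
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  k <- p + 1  # fixed effects + residual variance

  expo <- cur$ev$expo
  if (min(expo) <= 0 || max(expo) >= 2) {
    warning(sprintf(
      "fit_hd_nls: effective exponent outside (0, 2) over the data (range %.3f..%.3f)",
      min(expo), max(expo)), call. = FALSE)
  }

  structure(list(
    estimates = est, se = se,
    p_values = 2 * stats::pnorm(-abs(z)),
    vcov = vc,
    sigma = sqrt(sigma2_ml),
    loglik = loglik, aic = -2 * loglik + 2 * k,
    bic = -2 * loglik + log(n) * k, k = k,
    residuals = cur$r, fitted = cur$ev$f,
    converged = converged, n_iter = iter, trace = trace,
    n = n, spec = spec, scale_info = scale_info,
    data = data[, c("dbh_cm", "height_m", spec$covariates), drop = FALSE]
  ), class = "hd_nls")
}

# minimal Moore-Penrose fallback so the package needs no MASS import
MASS_ginv <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.hd_nls <- function(x, ...) {
  cat(sprintf("hd_nls fit: n = %d, %s\n", x$n,
              if (length(x$spec$covariates))
                paste("exponent covariates:",
                      paste(x$spec$covariates, collapse = ", "))
              else "base power model"))
  tab <- data.frame(estimate = x$estimates, se = x$se, p = x$p_values)
  print(signif(tab, 4))
  cat(sprintf("sigma (ML) %.4f  logLik %.2f  AIC %.1f  converged: %s (%d iter)\n",
              x$sigma, x$loglik, x$aic, x$converged, x$n_iter))
  invisible(x)
}

#' @export
coef.hd_nls <- function(object, ...) object$estimates

#' @export
logLik.hd_nls <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
predict.hd_nls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  covn <- object$spec$covariates
  predict_height(object$estimates, newdata$dbh_cm,
                 if (length(covn)) newdata[, covn, drop = FALSE] else NULL)
}

#' Build the modelling frame from a forest dataset
#'
#' Joins the modelling subset of trees with their plot covariates and the
#' derived stand metrics: per-tree `BAL` and plot-level `QMD` and `SIM`
#' (recomputed from the tree list), plus `SOC` (from `soc_g_kg`) and any
#' climate columns present on the plot table.
#'
#' @param ds A [forest_dataset()].
#' @param min_dbh_cm Diameter threshold for the modelling subset (default 5).
#' @param min_species_n Minimum per-species count (default 100).
#' @return data.frame with columns `plot_id`, `species`, `dbh_cm`, `height_m`,
#'   `BAL`, `QMD`, `SIM` and the plot covariates.
#' @export
hd_model_frame <- function(ds, min_dbh_cm = 5, min_species_n = 100) {
  trees <- modelling_subset(ds, min_dbh_cm = min_dbh_cm,
                            min_species_n = min_species_n)
  out <- trees
  out$BAL <- NA_real_
  plot_cols <- setdiff(names(ds$plots), "plot_id")
  for (col in plot_cols) out[[col]] <- NA_real_
  out$QMD <- NA_real_; out$SIM <- NA_real_; out$SHI <- NA_real_
  for (p in unique(trees$plot_id)) {
    idx <- which(out$plot_id == p)
    prow <- ds$plots[ds$plots$plot_id == p, , drop = FALSE]
    for (col in plot_cols) out[[col]][idx] <- prow[[col]]
    m <- compute_stand_metrics(ds, p, min_dbh_cm = min_dbh_cm)
    # BAL against ALL stems >= min_dbh in the plot, matched by row identity;
    # QMD/SIM/SHI recomputed from the tree list override any stored columns
    out$BAL[idx] <- m$bal_by_tree[rownames(out)[idx]]
    out$QMD[idx] <- m$qmd_cm
    out$SIM[idx] <- m$sim
    out$SHI[idx] <- m$shi
  }
  if ("soc_g_kg" %in% names(out) && !"SOC" %in% names(out)) {
    out$SOC <- out$soc_g_kg
  }
  rownames(out) <- NULL
  out
}
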