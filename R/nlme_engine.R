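#' Random-effects specification for the two-level H-D model
#'
#' Plot-level effects attach to named parameters of the fixed-effects model
#' (default `beta0` and `beta1`, i.e. random scaling coefficient and random
#' exponent intercept per plot); a species-within-plot effect attaches to a
#' single parameter (default the `QMD` coefficient). Numeric values
#' (`plot_cov`, `species_var`) are carried for likelihood evaluation at known
#' variances and as simulation truth; `fit_hd_nlme()` estimates them.
#'
#' @param plot Character vector of parameter names receiving plot-level
#'   effects (`"beta0"`, `"beta1"`, or a covariate name). May be NULL.
#' @param species Single parameter name receiving a species-within-plot
#'   effect, or NULL.
#' @param plot_cov_structure `"unstructured"` (default) or `"diagonal"`
#'   covariance of the plot-level effects.
#' @param plot_cov Optional numeric covariance matrix of the plot effects
#'   (used by [hd_marginal_loglik()] and the simulator).
#' @param species_var Optional numeric variance of the species effect.
#' @return Object of class `hd_re_spec`.
#' @export
hd_re_spec <- function(plot = c("beta0", "beta1"), species = "QMD",
                       plot_cov_structure = c("unstructured", "diagonal"),
                       plot_cov = NULL, species_var = NULL) {
  plot_cov_structure <- match.arg(plot_cov_structure)
  if (!is.null(species) && length(species) != 1) {
    stop("hd_re_spec: species effect must name exactly one parameter",
         call. = FALSE)
  }
  if (is.null(plot) && is.null(species)) {
    stop("hd_re_spec: at least one random effect required (use fit_hd_nls otherwise)",
         call. = FALSE)
  }
  if (!is.null(plot_cov)) {
    plot_cov <- as.matrix(plot_cov)
    if (nrow(plot_cov) != length(plot) ||
        any(abs(plot_cov - t(plot_cov)) > 1e-10) ||
        any(eigen(plot_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
      stop("hd_re_spec: plot_cov must be a symmetric PSD matrix matching 'plot'",
           call. = FALSE)
    }
  }
  if (!is.null(species_var) && species_var < 0) {
    stop("hd_re_spec: species_var must be non-negative", call. = FALSE)
  }
  structure(list(plot = plot, species = species,
                 plot_cov_structure = plot_cov_structure,
                 plot_cov = plot_cov, species_var = species_var),
            class = "hd_re_spec")
}

#' Within-plot variance-function specification
#'
#' Models the residual SD as a function of diameter: `none` (constant sigma),
#' `exponential` (`sigma * exp(gamma * D)`), `constant_plus_power`
#' (`sigma * |gamma1 + D^gamma2|`), or `power` (`sigma * D^gamma`).
#'
#' @param kind One of `"none"`, `"exponential"`, `"constant_plus_power"`,
#'   `"power"`.
#' @param gamma Numeric parameter(s): length 1 for exponential/power, length 2
#'   (`gamma1`, `gamma2`) for constant_plus_power; starting values when used
#'   in a fit.
#' @return Object of class `hd_var_spec`.
#' @export
hd_var_spec <- function(kind = c("none", "exponential", "constant_plus_power",
                                 "power"), gamma = NULL) {
  kind <- match.arg(kind)
  npar <- switch(kind, none = 0L, exponential = 1L, power = 1L,
                 constant_plus_power = 2L)
  if (is.null(gamma)) {
    gamma <- switch(kind, none = numeric(0), exponential = 0.01,
                    power = 0.1, constant_plus_power = c(0.5, 0.5))
  }
  if (length(gamma) != npar) {
    stop(sprintf("hd_var_spec: kind '%s' takes %d parameter(s)", kind, npar),
         call. = FALSE)
  }
  structure(list(kind = kind, gamma = gamma, npar = npar),
            class = "hd_var_spec")
}

# relative SD multiplier g(D); the model SD is sigma * g(D)
.varfn_g <- function(kind, gamma, D) {
  g <- switch(kind,
    none = rep(1, length(D)),
    exponential = exp(gamma[1] * D),
    power = D^gamma[1],
    constant_plus_power = abs(gamma[1] + D^gamma[2])
  )
  pmin(pmax(g, 1e-8), 1e8)
}

#' Evaluate a variance function as a residual SD
#'
#' @param var_spec An [hd_var_spec()] with numeric `gamma`.
#' @param dbh_cm Diameter(s), cm, positive.
#' @param sigma Residual scale parameter.
#' @return Model SD(s), m.
#' @export
evaluate_variance_fn <- function(var_spec, dbh_cm, sigma) {
  stopifnot(inherits(var_spec, "hd_var_spec"))
  if (any(dbh_cm <= 0)) stop("evaluate_variance_fn: D must be positive",
                             call. = FALSE)
  sigma * .varfn_g(var_spec$kind, var_spec$gamma, dbh_cm)
}

# ---- internal engine structures -------------------------------------------

# carrier of a random effect: multiplies the derivative of the prediction.
# beta0 acts on the base (derivative D^e); anything else acts in the exponent
# (derivative A * D^e * log(D) * x), x = 1 for beta1, covariate column else.
.carrier <- function(par, data, spec) {
  if (par == "beta0") return(NULL)  # special-cased
  if (par == "beta1") return(rep(1, nrow(data)))
  if (!par %in% spec$covariates) {
    stop(sprintf("random effect on unknown parameter '%s'", par), call. = FALSE)
  }
  data[[par]]
}

.nlme_struct <- function(data, spec, re) {
  need <- c("plot_id", "dbh_cm", "height_m", spec$covariates)
  if (!is.null(re$species)) need <- c(need, "species")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  des <- .hd_design(data, spec)
  q1 <- length(re$plot)
  has_sp <- !is.null(re$species)
  plot_ids <- unique(data$plot_id)
  car_plot <- lapply(re$plot, .carrier, data = data, spec = spec)
  names(car_plot) <- re$plot
  car_sp <- if (has_sp) {
    if (re$species == "beta0") {
      stop("species-level effect on beta0 not supported; use an exponent parameter",
           call. = FALSE)
    }
    .carrier(re$species, data, spec)
  } else NULL
  plots <- lapply(plot_ids, function(p) {
    idx <- which(data$plot_id == p)
    spf <- if (has_sp) factor(data$species[idx]) else NULL
    list(idx = idx, n = length(idx),
         sp = spf, s = if (has_sp) nlevels(spf) else 0L,
         D = des$D[idx], y = des$H[idx],
         X = if (is.null(des$X)) NULL else des$X[idx, , drop = FALSE],
         car_plot = lapply(car_plot, function(x)
           if (is.null(x)) NULL else x[idx]),
         car_sp = if (has_sp) car_sp[idx] else NULL)
  })
  names(plots) <- plot_ids
  list(D = des$D, y = des$H, X = des$X, n = length(des$D),
       plots = plots, q1 = q1, has_sp = has_sp,
       car_plot = car_plot, car_sp = car_sp, re = re, spec = spec)
}

# conditional evaluation: returns per-row f, De, dexpo given modes
.cond_eval <- function(st, beta, u, v) {
  add0 <- numeric(st$n); adde <- numeric(st$n)
  for (pi in seq_along(st$plots)) {
    pl <- st$plots[[pi]]
    if (st$q1 > 0) {
      for (k in seq_len(st$q1)) {
        par <- st$re$plot[k]
        if (par == "beta0") add0[pl$idx] <- add0[pl$idx] + u[k, pi]
        else adde[pl$idx] <- adde[pl$idx] + u[k, pi] * st$car_plot[[par]][pl$idx]
      }
    }
    if (st$has_sp && pl$s > 0) {
      adde[pl$idx] <- adde[pl$idx] +
        v[[pi]][as.integer(pl$sp)] * st$car_sp[pl$idx]
    }
  }
  .hd_eval(beta, st$D, st$X, add0 = add0, adde = adde)
}

# evaluation restricted to the rows of plot pi (cheap inner-loop path)
.local_eval <- function(st, pi, beta, u, v) {
  pl <- st$plots[[pi]]
  add0 <- 0; adde <- 0
  if (st$q1 > 0) {
    for (k in seq_len(st$q1)) {
      par <- st$re$plot[k]
      if (par == "beta0") add0 <- add0 + u[k, pi]
      else adde <- adde + u[k, pi] * pl$car_plot[[par]]
    }
  }
  if (st$has_sp && pl$s > 0) {
    adde <- adde + v[[pi]][as.integer(pl$sp)] * pl$car_sp
  }
  .hd_eval(beta, pl$D, pl$X, add0 = add0, adde = adde)
}

# Z_i for plot pi; ev_de / ev_dexpo are the derivative vectors for the rows
# of the plot (from .local_eval, or a global eval subset by idx)
.zmat_rows <- function(st, pi, ev_de, ev_dexpo) {
  pl <- st$plots[[pi]]
  cols <- list()
  for (par in st$re$plot) {
    cols[[par]] <- if (par == "beta0") ev_de
                   else ev_dexpo * pl$car_plot[[par]]
  }
  Z <- if (length(cols)) do.call(cbind, cols) else matrix(0, pl$n, 0)
  if (st$has_sp && pl$s > 0) {
    Sp <- matrix(0, pl$n, pl$s)
    Sp[cbind(seq_len(pl$n), as.integer(pl$sp))] <- ev_dexpo * pl$car_sp
    Z <- cbind(Z, Sp)
  }
  Z
}

# Z_i from a full-data conditional evaluation
.zmat <- function(st, pi, ev) {
  pl <- st$plots[[pi]]
  .zmat_rows(st, pi, ev$De[pl$idx], ev$dexpo[pl$idx])
}

.pen_chol <- function(st, pi, Dinv1_chol, d2inv) {
  pl <- st$plots[[pi]]
  qi <- st$q1 + pl$s
  L <- matrix(0, qi, qi)
  if (st$q1 > 0) L[seq_len(st$q1), seq_len(st$q1)] <- Dinv1_chol
  if (pl$s > 0) {
    diag(L)[st$q1 + seq_len(pl$s)] <- sqrt(d2inv)
  }
  L
}

# plot-local penalized objective: weighted SSE of the plot + mode penalty
.local_obj <- function(st, pi, beta, u, v, Dinv1, d2inv, g) {
  pl <- st$plots[[pi]]
  ev <- .local_eval(st, pi, beta, u, v)
  r <- (st$y[pl$idx] - ev$f) / g[pl$idx]
  pen <- 0
  if (st$q1 > 0) pen <- pen + drop(crossprod(u[, pi], Dinv1 %*% u[, pi]))
  if (pl$s > 0) pen <- pen + d2inv * sum(v[[pi]]^2)
  list(value = sum(r^2) + pen, ev = ev)
}

# one penalized-least-squares pass: updates modes (per-plot Gauss-Newton on
# the plot-local penalized objective) and, when update_beta, the fixed
# effects, all at fixed variance parameters
.pnls <- function(st, beta, u, v, Dinv1, d2inv, gamma, var_kind,
                  update_beta = TRUE, sweeps = 30, tol = 1e-9) {
  g <- .varfn_g(var_kind, gamma, st$D)
  Dinv1_chol <- if (st$q1 > 0) chol(Dinv1) else NULL
  prev_total <- Inf
  total <- NA_real_
  for (sw in seq_len(sweeps)) {
    total <- 0
    # (a) mode updates, plot by plot
    for (pi in seq_along(st$plots)) {
      pl <- st$plots[[pi]]
      qi <- st$q1 + pl$s
      lo <- .local_obj(st, pi, beta, u, v, Dinv1, d2inv, g)
      if (qi == 0) { total <- total + lo$value; next }
      gi <- g[pl$idx]
      L <- .pen_chol(st, pi, Dinv1_chol, d2inv)
      for (gn in 1:5) {
        Z <- .zmat_rows(st, pi, lo$ev$De, lo$ev$dexpo)
        b <- c(if (st$q1 > 0) u[, pi] else numeric(0),
               if (pl$s > 0) v[[pi]] else numeric(0))
        A <- rbind(Z / gi, L)
        rhs <- c((st$y[pl$idx] - lo$ev$f) / gi, -drop(L %*% b))
        delta <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
        if (is.null(delta) || any(!is.finite(delta))) break
        step <- 1; improved <- FALSE
        for (h in 1:10) {
          bn <- b + step * delta
          if (st$q1 > 0) u[, pi] <- bn[seq_len(st$q1)]
          if (pl$s > 0) v[[pi]] <- bn[st$q1 + seq_len(pl$s)]
          cand <- tryCatch(.local_obj(st, pi, beta, u, v, Dinv1, d2inv, g),
                           error = function(e) list(value = Inf))
          if (is.finite(cand$value) && cand$value <= lo$value + 1e-12) {
            lo <- cand; improved <- TRUE
            break
          }
          step <- step / 2
        }
        if (!improved) {  # restore the pre-step modes
          if (st$q1 > 0) u[, pi] <- b[seq_len(st$q1)]
          if (pl$s > 0) v[[pi]] <- b[st$q1 + seq_len(pl$s)]
          lo <- .local_obj(st, pi, beta, u, v, Dinv1, d2inv, g)
          break
        }
        if (max(abs(delta)) < 1e-10) break
      }
      total <- total + lo$value
    }
    # (b) fixed-effects update (penalty term does not involve beta)
    if (update_beta) {
      ev <- .cond_eval(st, beta, u, v)
      cur_sse <- sum(((st$y - ev$f) / g)^2)
      for (gn in 1:5) {
        J <- .hd_jacobian(ev, st$X) / g
        r <- (st$y - ev$f) / g
        delta <- tryCatch(qr.solve(J, r), error = function(e) NULL)
        if (is.null(delta) || any(!is.finite(delta))) break
        step <- 1; improved <- FALSE
        for (h in 1:10) {
          bn <- beta + step * stats::setNames(delta, names(beta))
          evn <- tryCatch(.cond_eval(st, bn, u, v), error = function(e) NULL)
          if (!is.null(evn)) {
            sn <- sum(((st$y - evn$f) / g)^2)
            if (sn <= cur_sse + 1e-12) {
              total <- total - cur_sse + sn
              beta <- bn; ev <- evn; cur_sse <- sn; improved <- TRUE
              break
            }
          }
          step <- step / 2
        }
        if (!improved || max(abs(delta)) < 1e-11) break
      }
    }
    if (abs(prev_total - total) < tol * max(1, abs(prev_total))) break
    prev_total <- total
  }
  list(beta = beta, u = u, v = v, pobj = total,
       ev = .cond_eval(st, beta, u, v))
}

# ---- variance-parameter (theta) packing -----------------------------------

.theta_template <- function(re, var_spec) {
  q1 <- length(re$plot)
  n_plotcov <- if (q1 == 0) 0L else if (re$plot_cov_structure == "unstructured")
    q1 * (q1 + 1L) / 2L else q1
  list(q1 = q1, n_plotcov = as.integer(n_plotcov),
       has_sp = !is.null(re$species), n_gamma = var_spec$npar,
       kind = var_spec$kind,
       len = as.integer(n_plotcov + !is.null(re$species) + var_spec$npar))
}

.theta_init <- function(tmpl, var_spec, rel_plot_sd = 0.3, rel_sp_sd = 0.1) {
  th <- numeric(0)
  if (tmpl$q1 > 0) {
    if (tmpl$n_plotcov == tmpl$q1) {
      th <- rep(log(rel_plot_sd), tmpl$q1)
    } else {
      th <- c(rep(log(rel_plot_sd), tmpl$q1),
              rep(0, tmpl$n_plotcov - tmpl$q1))
    }
  }
  if (tmpl$has_sp) th <- c(th, log(rel_sp_sd))
  c(th, var_spec$gamma)
}

# unpack theta into relative covariance pieces (relative = divided by sigma^2)
.theta_unpack <- function(theta, tmpl) {
  pos <- 0L
  D1 <- NULL; Dinv1 <- NULL; logdetD1 <- 0; L1 <- NULL
  if (tmpl$q1 > 0) {
    if (tmpl$n_plotcov == tmpl$q1) {  # diagonal
      sd1 <- exp(pmin(pmax(theta[seq_len(tmpl$q1)], -12), 12))
      L1 <- diag(sd1, tmpl$q1)
    } else {  # log-Cholesky, diag first then row-wise off-diagonals
      ld <- theta[seq_len(tmpl$q1)]
      off <- theta[tmpl$q1 + seq_len(tmpl$n_plotcov - tmpl$q1)]
      L1 <- diag(exp(pmin(pmax(ld, -12), 12)), tmpl$q1)
      k <- 0L
      for (i in seq_len(tmpl$q1)) for (j in seq_len(i - 1L)) {
        k <- k + 1L
        L1[i, j] <- off[k]
      }
    }
    pos <- tmpl$n_plotcov
    D1 <- L1 %*% t(L1)
    Dinv1 <- chol2inv(t(L1))
    logdetD1 <- 2 * sum(log(diag(L1)))
  }
  d2 <- NA_real_; d2inv <- Inf
  if (tmpl$has_sp) {
    pos <- pos + 1L
    sd2 <- exp(pmin(pmax(theta[pos], -12), 12))
    d2 <- sd2^2
    d2inv <- 1 / d2
  }
  gamma <- if (tmpl$n_gamma > 0) theta[pos + seq_len(tmpl$n_gamma)] else numeric(0)
  list(D1 = D1, Dinv1 = Dinv1, logdetD1 = logdetD1, L1 = L1,
       d2 = d2, d2inv = d2inv, gamma = gamma)
}

# ---- profiled marginal log-likelihood of the linearized model -------------

# lin: list per plot with X, Z, w, D (built at the current linearization);
# returns negative LL; with details = TRUE also beta_hat, sigma2, M = X'V^-1 X
.lme_negll <- function(theta, tmpl, lin, n, p, details = FALSE) {
  vp <- .theta_unpack(theta, tmpl)
  M <- matrix(0, p, p); xw <- numeric(p); wVw <- 0; sld <- 0
  for (pl in lin) {
    g <- .varfn_g(tmpl$kind, vp$gamma, pl$D)
    Xw <- pl$X / g; ww <- pl$w / g
    qi <- ncol(pl$Z)
    if (qi > 0) {
      Zw <- pl$Z / g
      Dinv <- matrix(0, qi, qi)
      ld <- 0
      if (tmpl$q1 > 0) {
        Dinv[seq_len(tmpl$q1), seq_len(tmpl$q1)] <- vp$Dinv1
        ld <- ld + vp$logdetD1
      }
      s_i <- qi - tmpl$q1
      if (s_i > 0) {
        diag(Dinv)[tmpl$q1 + seq_len(s_i)] <- vp$d2inv
        ld <- ld + s_i * log(vp$d2)
      }
      A <- crossprod(Zw) + Dinv
      cA <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(cA)) return(if (details) NULL else 1e10)
      sld <- sld + 2 * sum(log(g)) + ld + 2 * sum(log(diag(cA)))
      FX <- forwardsolve(t(cA), crossprod(Zw, Xw))
      Fw <- forwardsolve(t(cA), crossprod(Zw, ww))
      M <- M + crossprod(Xw) - crossprod(FX)
      xw <- xw + crossprod(Xw, ww) - crossprod(FX, Fw)
      wVw <- wVw + sum(ww^2) - sum(Fw^2)
    } else {
      sld <- sld + 2 * sum(log(g))
      M <- M + crossprod(Xw)
      xw <- xw + crossprod(Xw, ww)
      wVw <- wVw + sum(ww^2)
    }
  }
  bh <- tryCatch(solve(M, xw), error = function(e) NULL)
  if (is.null(bh)) return(if (details) NULL else 1e10)
  rss <- drop(wVw - 2 * crossprod(bh, xw) + crossprod(bh, M %*% bh))
  rss <- max(rss, n * 1e-24)  # guard against cancellation at perfect fits
  sigma2 <- rss / n
  negll <- 0.5 * (n * log(2 * pi * sigma2) + n + sld)
  if (!details) return(negll)
  list(negll = negll, beta = drop(bh), sigma2 = sigma2, M = M, vp = vp)
}

# Closure over the linearization. For the homoscedastic case the per-plot
# crossproducts do not depend on theta, so they are precomputed once and each
# likelihood evaluation reduces to q x q algebra.
.make_negll <- function(tmpl, lin, n, p) {
  if (tmpl$kind != "none") {
    return(function(theta, details = FALSE)
      .lme_negll(theta, tmpl, lin, n, p, details))
  }
  pre <- lapply(lin, function(pl) {
    qi <- ncol(pl$Z)
    list(qi = qi, s = qi - tmpl$q1,
         ZtZ = if (qi) crossprod(pl$Z) else NULL,
         ZtX = if (qi) crossprod(pl$Z, pl$X) else NULL,
         Ztw = if (qi) crossprod(pl$Z, pl$w) else NULL,
         XtX = crossprod(pl$X),
         Xtw = crossprod(pl$X, pl$w),
         wtw = sum(pl$w^2))
  })
  function(theta, details = FALSE) {
    vp <- .theta_unpack(theta, tmpl)
    M <- matrix(0, p, p); xw <- matrix(0, p, 1); wVw <- 0; sld <- 0
    for (pl in pre) {
      if (pl$qi > 0) {
        Dinv <- matrix(0, pl$qi, pl$qi); ld <- 0
        if (tmpl$q1 > 0) {
          Dinv[seq_len(tmpl$q1), seq_len(tmpl$q1)] <- vp$Dinv1
          ld <- ld + vp$logdetD1
        }
        if (pl$s > 0) {
          diag(Dinv)[tmpl$q1 + seq_len(pl$s)] <- vp$d2inv
          ld <- ld + pl$s * log(vp$d2)
        }
        A <- pl$ZtZ + Dinv
        cA <- tryCatch(chol(A), error = function(e) NULL)
        if (is.null(cA)) return(if (details) NULL else 1e10)
        sld <- sld + ld + 2 * sum(log(diag(cA)))
        FX <- forwardsolve(t(cA), pl$ZtX)
        Fw <- forwardsolve(t(cA), pl$Ztw)
        M <- M + pl$XtX - crossprod(FX)
        xw <- xw + pl$Xtw - crossprod(FX, Fw)
        wVw <- wVw + pl$wtw - sum(Fw^2)
      } else {
        M <- M + pl$XtX; xw <- xw + pl$Xtw; wVw <- wVw + pl$wtw
      }
    }
    bh <- tryCatch(solve(M, xw), error = function(e) NULL)
    if (is.null(bh)) return(if (details) NULL else 1e10)
    rss <- drop(wVw - 2 * crossprod(bh, xw) + crossprod(bh, M %*% bh))
    rss <- max(rss, n * 1e-24)  # guard against cancellation at perfect fits
    sigma2 <- rss / n
    negll <- 0.5 * (n * log(2 * pi * sigma2) + n + sld)
    if (!details) return(negll)
    list(negll = negll, beta = drop(bh), sigma2 = sigma2, M = M, vp = vp)
  }
}

.linearize <- function(st, beta, u, v, ev = NULL) {
  if (is.null(ev)) ev <- .cond_eval(st, beta, u, v)
  Xfull <- .hd_jacobian(ev, st$X)
  lapply(seq_along(st$plots), function(pi) {
    pl <- st$plots[[pi]]
    Z <- .zmat(st, pi, ev)
    b <- c(if (st$q1 > 0) u[, pi] else numeric(0),
           if (pl$s > 0) v[[pi]] else numeric(0))
    w <- st$y[pl$idx] - ev$f[pl$idx] +
      drop(Xfull[pl$idx, , drop = FALSE] %*% beta) +
      (if (length(b)) drop(Z %*% b) else 0)
    list(X = Xfull[pl$idx, , drop = FALSE], Z = Z, w = w, D = st$D[pl$idx])
  })
}

#' Fit the two-level nonlinear mixed-effects height-diameter model
#'
#' Maximum-likelihood estimation by an alternating algorithm in the
#' Lindstrom-Bates tradition: (a) a penalized nonlinear least-squares step
#' updates the fixed effects and the random-effect modes at the current
#' variance parameters; (b) a linear mixed-effects step maximizes the
#' first-order (linearized) marginal likelihood over the variance-covariance
#' and variance-function parameters, profiling the fixed effects and the
#' residual scale. Iteration stops when the marginal log-likelihood changes by
#' less than `tol`.
#'
#' The within-plot error covariance is `sigma^2 * G_i` with `G_i` diagonal
#' from the variance function evaluated at each tree's diameter (within-plot
#' correlation fixed to the identity).
#'
#' @param data data.frame with `plot_id`, `species` (if a species effect is
#'   requested), `dbh_cm`, `height_m`, and the covariates named in `spec`.
#' @param spec An [hd_model_spec()].
#' @param re An [hd_re_spec()].
#' @param var_spec An [hd_var_spec()].
#' @param start Optional list with elements `fixed` (named vector) and/or
#'   `theta` (variance-parameter vector); defaults to an NLS fit and moderate
#'   relative variances.
#' @param tol Outer convergence tolerance on the log-likelihood (default 1e-4).
#' @param max_iter Maximum outer iterations (default 20).
#' @param control List: `lme_maxit` (Nelder-Mead evaluations per LME step),
#'   `pnls_sweeps`.
#' @param verbose Print the LL trace.
#' @return Object of class `hd_nlme`: `fixed` (estimates), `se`, `plot_cov`,
#'   `species_var`, `var_fn` (spec with estimated gamma), `sigma`, `loglik`,
#'   `aic`, `bic`, `k`, `k_census`, `re_modes`, `fitted_cond`,
#'   `std_residuals`, `converged`, `boundary`, `trace`, `n`.
#' @export
fit_hd_nlme <- function(data, spec = hd_model_spec(), re = hd_re_spec(),
                        var_spec = hd_var_spec("none"), start = NULL,
                        tol = 1e-4, max_iter = 20, control = list(),
                        verbose = FALSE) {
  stopifnot(inherits(spec, "hd_model_spec"), inherits(re, "hd_re_spec"),
            inherits(var_spec, "hd_var_spec"))
  ctl <- utils::modifyList(list(lme_maxit = 400, lme_maxit_later = 200,
                                pnls_sweeps = 20, pnls_sweeps_later = 5,
                                pnls_tol = 1e-8), control)
  st <- .nlme_struct(data, spec, re)
  if (length(st$plots) < 2 && st$q1 > 0) {
    stop("fit_hd_nlme: plot-level effects need >= 2 plots", call. = FALSE)
  }
  p <- length(spec$params)
  tmpl <- .theta_template(re, var_spec)

  beta <- if (!is.null(start$fixed)) {
    b <- unlist(start$fixed)[spec$params]
    if (any(is.na(b))) stop("start$fixed must name every parameter", call. = FALSE)
    stats::setNames(b, spec$params)
  } else {
    fit_hd_nls(data, spec)$estimates
  }
  theta <- if (!is.null(start$theta)) {
    if (length(start$theta) != tmpl$len) stop("start$theta has wrong length",
                                              call. = FALSE)
    start$theta
  } else .theta_init(tmpl, var_spec)

  u <- matrix(0, st$q1, length(st$plots))
  v <- lapply(st$plots, function(pl) numeric(pl$s))

  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  res <- NULL
  for (outer in seq_len(max_iter)) {
    vp <- .theta_unpack(theta, tmpl)
    pn <- .pnls(st, beta, u, v, vp$Dinv1, vp$d2inv, vp$gamma, var_spec$kind,
                sweeps = if (outer == 1) ctl$pnls_sweeps else
                  ctl$pnls_sweeps_later,
                tol = ctl$pnls_tol)
    beta <- pn$beta; u <- pn$u; v <- pn$v
    lin <- .linearize(st, beta, u, v, ev = pn$ev)
    maxit <- if (outer == 1) ctl$lme_maxit else ctl$lme_maxit_later
    negll_fn <- .make_negll(tmpl, lin, st$n, p)
    theta <- if (length(theta) == 1L) {
      stats::optimize(negll_fn, interval = theta + c(-8, 8),
                      tol = 1e-8)$minimum
    } else {
      stats::optim(theta, negll_fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))$par
    }
    res <- negll_fn(theta, details = TRUE)
    if (is.null(res)) stop("fit_hd_nlme: likelihood evaluation failed",
                           call. = FALSE)
    beta <- stats::setNames(res$beta, spec$params)
    ll <- -res$negll
    ll_trace <- c(ll_trace, ll)
    if (verbose) message(sprintf("outer %d: logLik %.5f", outer, ll))
    if (abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- ll
  }
  # refresh modes at the final parameters
  vp <- res$vp
  pn <- .pnls(st, beta, u, v, vp$Dinv1, vp$d2inv, vp$gamma, var_spec$kind,
              update_beta = FALSE, sweeps = 10)
  u <- pn$u; v <- pn$v

  sigma2 <- res$sigma2
  sigma <- sqrt(sigma2)
  plot_cov <- if (st$q1 > 0) {
    pc <- sigma2 * vp$D1
    dimnames(pc) <- list(re$plot, re$plot)
    pc
  } else NULL
  species_var <- if (tmpl$has_sp) sigma2 * vp$d2 else NULL
  vfit <- hd_var_spec(var_spec$kind,
                      if (var_spec$npar) vp$gamma else NULL)

  vc <- tryCatch(sigma2 * solve(res$M), error = function(e) {
    sigma2 * MASS_ginv(res$M)
  })
  dimnames(vc) <- list(spec$params, spec$params)
  se <- sqrt(pmax(diag(vc), 0))

  k <- p + tmpl$n_plotcov + as.integer(tmpl$has_sp) + tmpl$n_gamma + 1L
  k_census <- c(fixed = p, plot_cov = tmpl$n_plotcov,
                species_var = as.integer(tmpl$has_sp),
                variance_fn = tmpl$n_gamma, sigma = 1L)
  loglik <- -res$negll
  boundary <- character(0)
  if (st$q1 > 0) {
    rel_sd <- sqrt(diag(vp$D1))
    boundary <- c(boundary, re$plot[rel_sd < 1e-4])
  }
  if (tmpl$has_sp && sqrt(vp$d2) < 1e-4) boundary <- c(boundary, re$species)

  ev <- .cond_eval(st, beta, u, v)
  g <- .varfn_g(var_spec$kind, vp$gamma, st$D)
  re_modes <- list(
    plot = if (st$q1 > 0) {
      m <- t(u); dimnames(m) <- list(names(st$plots), re$plot); m
    } else NULL,
    species = if (tmpl$has_sp) {
      do.call(rbind, lapply(seq_along(st$plots), function(pi) {
        pl <- st$plots[[pi]]
        if (pl$s == 0) return(NULL)
        data.frame(plot_id = names(st$plots)[pi], species = levels(pl$sp),
                   mode = v[[pi]], stringsAsFactors = FALSE)
      }))
    } else NULL
  )

  structure(list(
    estimates = beta, fixed = beta, se = se,
    p_values = 2 * stats::pnorm(-abs(beta / se)),
    vcov = vc,
    plot_cov = plot_cov, species_var = species_var,
    var_fn = vfit, sigma = sigma,
    loglik = loglik, aic = -2 * loglik + 2 * k,
    bic = -2 * loglik + log(st$n) * k,
    k = k, k_census = k_census,
    theta = theta,
    re_modes = re_modes,
    fitted_cond = ev$f,
    std_residuals = (st$y - ev$f) / (sigma * g),
    converged = converged, boundary = boundary,
    n_outer = length(ll_trace), trace = ll_trace,
    n = st$n, spec = spec, re = re,
    data = data[, unique(c("plot_id",
                           if (tmpl$has_sp) "species",
                           "dbh_cm", "height_m", spec$covariates)),
                drop = FALSE]
  ), class = "hd_nlme")
}

#' @export
print.hd_nlme <- function(x, ...) {
  cat(sprintf("hd_nlme fit: n = %d, %d plot(s); logLik %.2f, AIC %.1f%s\n",
              x$n, if (!is.null(x$re_modes$plot)) nrow(x$re_modes$plot) else NA,
              x$loglik, x$aic,
              if (length(x$boundary))
                paste0(" [boundary: ", paste(x$boundary, collapse = ", "), "]")
              else ""))
  tab <- data.frame(estimate = x$estimates, se = x$se, p = x$p_values)
  print(signif(tab, 4))
  if (!is.null(x$plot_cov)) {
    cat("plot-level SDs:",
        paste(sprintf("%s %.4g", rownames(x$plot_cov),
                      sqrt(diag(x$plot_cov))), collapse = ", "), "\n")
  }
  if (!is.null(x$species_var)) {
    cat(sprintf("species-level SD: %.4g\n", sqrt(x$species_var)))
  }
  cat(sprintf("sigma %.4f, variance function: %s%s\n", x$sigma, x$var_fn$kind,
              if (x$var_fn$npar)
                paste0(" (", paste(signif(x$var_fn$gamma, 4), collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' @export
coef.hd_nlme <- function(object, ...) object$estimates

#' @export
logLik.hd_nlme <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
predict.hd_nlme <- function(object, newdata = NULL,
                            level = c("conditional", "population"), ...) {
  level <- match.arg(level)
  if (is.null(newdata)) {
    if (level == "conditional") return(object$fitted_cond)
    newdata <- object$data
  } else if (level == "conditional") {
    stop("conditional predictions for new data require random-effect modes; use level = \"population\"",
         call. = FALSE)
  }
  covn <- object$spec$covariates
  predict_height(object$estimates, newdata$dbh_cm,
                 if (length(covn)) newdata[, covn, drop = FALSE] else NULL)
}

#' First-order marginal log-likelihood at given parameter values
#'
#' Evaluates the Lindstrom-Bates approximate marginal log-likelihood of the
#' two-level model at fixed parameter values: random-effect modes are found by
#' penalized least squares (fixed effects held fixed), the model is linearized
#' about the modes, and the Gaussian marginal density of the working residual
#' with covariance `Z Psi Z' + sigma^2 G` is accumulated over plots. With all
#' random-effect variances zero this reduces exactly to the Gaussian NLS
#' log-likelihood.
#'
#' @param fe Named fixed-effects vector (`beta0`, `beta1`, covariates).
#' @param re An [hd_re_spec()] carrying numeric `plot_cov` and/or
#'   `species_var` values.
#' @param var_spec An [hd_var_spec()] with numeric `gamma`.
#' @param sigma Residual scale.
#' @param data Modelling frame (as for [fit_hd_nlme()]).
#' @param spec An [hd_model_spec()].
#' @return The marginal log-likelihood (scalar).
#' @export
hd_marginal_loglik <- function(fe, re, var_spec, sigma, data,
                               spec = hd_model_spec()) {
  stopifnot(inherits(re, "hd_re_spec"), inherits(var_spec, "hd_var_spec"))
  fe <- unlist(fe)[spec$params]
  if (any(is.na(fe))) stop("fe must name every model parameter", call. = FALSE)

  # drop degenerate (zero-variance) effects
  plot_pars <- re$plot
  plot_cov <- re$plot_cov
  if (!is.null(plot_pars)) {
    if (is.null(plot_cov)) stop("re$plot_cov value required", call. = FALSE)
    keep <- diag(as.matrix(plot_cov)) > 1e-12
    plot_pars <- plot_pars[keep]
    plot_cov <- if (any(keep)) as.matrix(plot_cov)[keep, keep, drop = FALSE]
                else NULL
    if (!any(keep)) plot_pars <- NULL
  }
  sp_par <- re$species
  sp_var <- re$species_var
  if (!is.null(sp_par)) {
    if (is.null(sp_var)) stop("re$species_var value required", call. = FALSE)
    if (sp_var <= 1e-12) { sp_par <- NULL; sp_var <- NULL }
  }

  des <- .hd_design(data, spec)
  if (is.null(plot_pars) && is.null(sp_par)) {
    ev <- .hd_eval(fe, des$D, des$X)
    g <- .varfn_g(var_spec$kind, var_spec$gamma, des$D)
    return(sum(stats::dnorm(des$H, ev$f, sigma * g, log = TRUE)))
  }

  re2 <- hd_re_spec(plot = plot_pars, species = sp_par,
                    plot_cov_structure = re$plot_cov_structure,
                    plot_cov = plot_cov, species_var = sp_var)
  st <- .nlme_struct(data, spec, re2)
  sigma2 <- sigma^2
  D1 <- if (!is.null(plot_cov)) plot_cov / sigma2 else NULL
  Dinv1 <- if (!is.null(D1)) solve(D1) else NULL
  logdetD1 <- if (!is.null(D1)) determinant(D1, logarithm = TRUE)$modulus[1] else 0
  d2 <- if (!is.null(sp_var)) sp_var / sigma2 else NA_real_
  d2inv <- if (!is.null(sp_var)) 1 / d2 else Inf

  u <- matrix(0, st$q1, length(st$plots))
  v <- lapply(st$plots, function(pl) numeric(pl$s))
  pn <- .pnls(st, fe, u, v, Dinv1, d2inv, var_spec$gamma, var_spec$kind,
              update_beta = FALSE, sweeps = 50, tol = 1e-12)
  u <- pn$u; v <- pn$v
  ev <- pn$ev

  ll <- 0
  for (pidx in seq_along(st$plots)) {
    pl <- st$plots[[pidx]]
    Z <- .zmat(st, pidx, ev)
    b <- c(if (st$q1 > 0) u[, pidx] else numeric(0),
           if (pl$s > 0) v[[pidx]] else numeric(0))
    r <- st$y[pl$idx] - ev$f[pl$idx] + (if (length(b)) drop(Z %*% b) else 0)
    g <- .varfn_g(var_spec$kind, var_spec$gamma, st$D[pl$idx])
    Zw <- Z / g; rw <- r / g
    qi <- ncol(Z)
    Dinv <- matrix(0, qi, qi); ld <- 0
    if (st$q1 > 0) {
      Dinv[seq_len(st$q1), seq_len(st$q1)] <- Dinv1
      ld <- ld + logdetD1
    }
    if (pl$s > 0) {
      diag(Dinv)[st$q1 + seq_len(pl$s)] <- d2inv
      ld <- ld + pl$s * log(d2)
    }
    A <- crossprod(Zw) + Dinv
    cA <- chol(A)
    logdetV <- 2 * sum(log(g)) + ld + 2 * sum(log(diag(cA)))
    Fr <- forwardsolve(t(cA), crossprod(Zw, rw))
    qf <- sum(rw^2) - sum(Fr^2)
    ll <- ll - 0.5 * (pl$n * log(2 * pi * sigma2) + logdetV + qf / sigma2)
  }
  ll
}

#' Likelihood-ratio comparison of variance functions
#'
#' Compares a homoscedastic base fit against fits extending it with a variance
#' function (same data, same fixed and random structure), reporting AIC, BIC,
#' log-likelihood, the likelihood ratio `2 * (LL_ext - LL_base)` and its
#' chi-square p-value with degrees of freedom equal to the added parameters.
#'
#' @param base_fit `hd_nlme` fit with variance function `"none"`.
#' @param extended_fits List of `hd_nlme` fits with non-trivial variance
#'   functions, nested above `base_fit`.
#' @return data.frame with one row for the base model and one per extension;
#'   attribute `"best"` holds the minimal-AIC row label.
#' @export
lrt_variance_functions <- function(base_fit, extended_fits) {
  stopifnot(inherits(base_fit, "hd_nlme"))
  if (inherits(extended_fits, "hd_nlme")) extended_fits <- list(extended_fits)
  rows <- list(data.frame(model = "none", AIC = base_fit$aic,
                          BIC = base_fit$bic, LL = base_fit$loglik,
                          L_ratio = NA_real_, df = NA_integer_,
                          p_value = NA_real_, stringsAsFactors = FALSE))
  for (ft in extended_fits) {
    stopifnot(inherits(ft, "hd_nlme"))
    if (ft$n != base_fit$n ||
        !identical(ft$spec$params, base_fit$spec$params)) {
      stop("lrt_variance_functions: fits are not on identical data/model",
           call. = FALSE)
    }
    df <- ft$k - base_fit$k
    if (df < 0) stop("lrt_variance_functions: models are not nested",
                     call. = FALSE)
    lr <- 2 * (ft$loglik - base_fit$loglik)
    p <- if (df == 0) {
      if (abs(lr) < 1e-6) 1 else NA_real_
    } else stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      model = ft$var_fn$kind, AIC = ft$aic, BIC = ft$bic, LL = ft$loglik,
      L_ratio = lr, df = df, p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$model[which.min(out$AIC)]
  out
}

#' Standardized residuals of a mixed-effects fit
#'
#' `(observed - conditional prediction) / model SD at the tree's diameter`.
#' With `by`, returns per-group summaries (n, mean, SD) instead.
#'
#' @param fit An `hd_nlme` fit.
#' @param by Optional grouping vector (e.g. species) aligned with the data.
#' @return Numeric vector, or a summary data.frame when `by` is given.
#' @export
standardized_residuals <- function(fit, by = NULL) {
  stopifnot(inherits(fit, "hd_nlme"))
  r <- fit$std_residuals
  if (is.null(by)) return(r)
  groups <- split(r, by)
  data.frame(group = names(groups),
             n = vapply(groups, length, integer(1)),
             mean = vapply(groups, mean, numeric(1)),
             sd = vapply(groups, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
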