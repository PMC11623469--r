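#' Random-effects panel Tobit regression
#'
#' Maximum likelihood for the two-limit censored panel model
#' `y*_it = x_it' beta + u_i + e_it`, `u_i ~ N(0, sigma_u^2)`,
#' `e_it ~ N(0, sigma_e^2)`, with `y` observed as `y*` censored at
#' `bounds[1]` and `bounds[2]`. Interior observations contribute normal
#' density terms, boundary observations normal CDF terms, and the unit-level
#' random effect is integrated out by adaptive Gauss-Hermite quadrature:
#' each unit's posterior mode and curvature are located by Newton steps and
#' the nodes are shifted and scaled accordingly, so a modest node count
#' suffices even when the posterior of `u_i` is far from the prior.
#' Estimation is deterministic: a least-squares warm start followed by BFGS
#' on `(beta, log sigma_u, log sigma_e)`; standard errors come from the
#' observed information at the optimum.
#'
#' @param y Numeric response in `[bounds[1], bounds[2]]`.
#' @param X Numeric model matrix (including an intercept column).
#' @param unit Unit id for each row (factor/character/integer).
#' @param bounds Censoring limits, default `c(0, 1)`.
#' @param quad_points Number of Gauss-Hermite nodes (default 12, minimum 8
#'   unless `sigma_u_fixed = 0`).
#' @param sigma_u_fixed Optionally fix the random-effect standard deviation
#'   (0 gives a pooled Tobit; with no boundary observations that is ordinary
#'   normal-likelihood regression, equal to least squares).
#' @return A `re_tobit` fit: coefficients, standard errors, `sigma_u`,
#'   `sigma_e` (each with SE), log-likelihood, `n_obs`, `n_units`,
#'   convergence flag, variance-covariance matrix of the optimized
#'   parameters.
#' @export
re_tobit <- function(y, X, unit, bounds = c(0, 1), quad_points = 12,
                     sigma_u_fixed = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X) || length(unit) != nrow(X)) {
    stop("y, X, unit must have matching rows", call. = FALSE)
  }
  if (any(y < bounds[1] - 1e-12) || any(y > bounds[2] + 1e-12)) {
    stop("response outside the censoring bounds", call. = FALSE)
  }
  est_sigma_u <- is.null(sigma_u_fixed)
  if (est_sigma_u && quad_points < 8) {
    stop("quad_points must be at least 8", call. = FALSE)
  }
  unit <- as.integer(factor(unit))
  nll <- function(theta) {
    re_tobit_nll(theta, y, X, unit, bounds, quad_points, sigma_u_fixed)
  }

  # warm start from least squares
  ls <- lm.fit(X, y)
  beta0 <- ls$coefficients
  beta0[is.na(beta0)] <- 0
  res <- ls$residuals
  res_by_unit <- drop(rowsum(res, unit)) / tabulate(unit)
  s_u0 <- max(sd(res_by_unit), 1e-3)
  s_e0 <- max(sqrt(max(var(res) - s_u0^2, 1e-8)), 1e-3)
  theta0 <- if (est_sigma_u) c(beta0, log(s_u0), log(s_e0))
            else c(beta0, log(s_e0))

  opt <- optim(theta0, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))

  k <- ncol(X)
  vcov <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, length(theta0), length(theta0))
  })
  se_all <- unname(suppressWarnings(sqrt(diag(vcov))))
  beta <- setNames(opt$par[seq_len(k)], colnames(X))
  sigma_u <- if (est_sigma_u) unname(exp(opt$par[k + 1])) else sigma_u_fixed
  sigma_e <- unname(exp(opt$par[length(opt$par)]))

  structure(list(
    coefficients = beta,
    se = setNames(se_all[seq_len(k)], colnames(X)),
    sigma_u = sigma_u,
    sigma_u_se = if (est_sigma_u) sigma_u * se_all[k + 1] else NA_real_,
    sigma_e = sigma_e,
    sigma_e_se = sigma_e * se_all[length(opt$par)],
    logLik = -opt$value,
    n_obs = length(y), n_units = max(unit),
    quad_points = quad_points, bounds = bounds,
    converged = opt$convergence == 0,
    vcov = vcov,
    par = opt$par,
    data = list(y = y, X = X, unit = unit, sigma_u_fixed = sigma_u_fixed)
  ), class = "re_tobit")
}

# Negative log marginal likelihood with adaptive Gauss-Hermite integration
# of the unit random effect. theta = (beta, [log sigma_u], log sigma_e).
re_tobit_nll <- function(theta, y, X, unit, bounds, quad_points,
                         sigma_u_fixed) {
  n_units <- max(unit)
  est_sigma_u <- is.null(sigma_u_fixed)
  at_lo <- y <= bounds[1] + 1e-12
  at_hi <- y >= bounds[2] - 1e-12
  interior <- !(at_lo | at_hi)
  gh <- pracma::gaussHermite(quad_points)

  beta <- theta[seq_len(ncol(X))]
  sigma_u <- if (est_sigma_u) exp(theta[ncol(X) + 1]) else sigma_u_fixed
  sigma_e <- exp(theta[length(theta)])
  eta <- drop(X %*% beta)

  # per-observation log-integrand and its first/second u-derivatives;
  # censored terms use the inverse Mills ratio lambda
  obs_terms <- function(u_long, what) {
    out <- numeric(length(y))
    if (any(interior)) {
      r <- y[interior] - eta[interior] - u_long[interior]
      out[interior] <- switch(what,
        l = dnorm(r, sd = sigma_e, log = TRUE),
        g = r / sigma_e^2,
        h = rep(-1 / sigma_e^2, length(r)))
    }
    if (any(at_lo)) {
      a <- (bounds[1] - eta[at_lo] - u_long[at_lo]) / sigma_e
      lam <- exp(dnorm(a, log = TRUE) - pnorm(a, log.p = TRUE))
      out[at_lo] <- switch(what,
        l = pnorm(a, log.p = TRUE),
        g = -lam / sigma_e,
        h = -lam * (a + lam) / sigma_e^2)
    }
    if (any(at_hi)) {
      b <- (eta[at_hi] + u_long[at_hi] - bounds[2]) / sigma_e
      lam <- exp(dnorm(b, log = TRUE) - pnorm(b, log.p = TRUE))
      out[at_hi] <- switch(what,
        l = pnorm(b, log.p = TRUE),
        g = lam / sigma_e,
        h = -lam * (b + lam) / sigma_e^2)
    }
    out
  }

  if (sigma_u < 1e-10) {
    return(-sum(obs_terms(numeric(length(y)), "l")))
  }

  # Newton search for each unit's posterior mode of u_i
  mode <- rep(0, n_units)
  for (it in 1:25) {
    u_long <- mode[unit]
    g <- drop(rowsum(obs_terms(u_long, "g"), unit)) - mode / sigma_u^2
    h <- drop(rowsum(obs_terms(u_long, "h"), unit)) - 1 / sigma_u^2
    step <- pmin(pmax(g / h, -5 * sigma_u), 5 * sigma_u)
    mode <- mode - step
    if (max(abs(g)) < 1e-9) break
  }
  u_long <- mode[unit]
  h <- drop(rowsum(obs_terms(u_long, "h"), unit)) - 1 / sigma_u^2
  s_hat <- 1 / sqrt(pmax(-h, 1e-12))

  # adaptive nodes u_ik = mode_i + sqrt(2) s_i x_k; log-sum-exp over nodes
  logL_nodes <- matrix(0, n_units, quad_points)
  for (k in seq_len(quad_points)) {
    u_k <- mode + sqrt(2) * s_hat * gh$x[k]
    lobs <- drop(rowsum(obs_terms(u_k[unit], "l"), unit))
    logL_nodes[, k] <- log(gh$w[k]) + gh$x[k]^2 + lobs +
      dnorm(u_k, sd = sigma_u, log = TRUE)
  }
  m <- apply(logL_nodes, 1, max)
  -sum(m + log(rowSums(exp(logL_nodes - m))) + log(sqrt(2) * s_hat))
}

#' Re-evaluate a fitted log-likelihood with a different node count
#'
#' Quadrature-stability check: on a converged fit the log-likelihood should
#' be essentially unchanged when the number of Gauss-Hermite nodes grows.
#'
#' @param fit A `re_tobit` fit.
#' @param quad_points Node count to re-evaluate with.
#' @return The log-likelihood at the fitted parameters.
#' @export
re_tobit_loglik <- function(fit, quad_points = fit$quad_points) {
  d <- fit$data
  -re_tobit_nll(fit$par, d$y, d$X, d$unit, fit$bounds, quad_points,
                d$sigma_u_fixed)
}

#' @export
print.re_tobit <- function(x, ...) {
  cat("Random-effects panel Tobit (", x$n_units, " units, ", x$n_obs,
      " obs, ", x$quad_points, " quadrature nodes)\n", sep = "")
  print(round(cbind(Estimate = x$coefficients, `Std. Error` = x$se), 4))
  cat(sprintf("sigma_u = %.4f, sigma_e = %.4f, logLik = %.3f%s\n",
              x$sigma_u, x$sigma_e, x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Panel Tobit fits for the national sample and each region
#'
#' Joins the CCD panel with the covariate panel and fits [re_tobit()] on the
#' pooled sample and, when a region map is supplied, on each region.
#'
#' @param ccd_tbl Tibble `unit`, `year`, `D`.
#' @param covariates Tibble `unit`, `year` plus the covariate columns.
#' @param vars Covariate column names entering the regression (in order).
#' @param region_map Optional tibble `unit`, `region` for per-region fits.
#' @inheritParams re_tobit
#' @return Named list of `re_tobit` fits (`National` first).
#' @export
fit_re_tobit <- function(ccd_tbl, covariates,
                         vars = c("lnPGDP", "lnUR", "lnOPEN", "lnEL", "lnGHE"),
                         region_map = NULL, bounds = c(0, 1),
                         quad_points = 12) {
  df <- dplyr::inner_join(ccd_tbl[c("unit", "year", "D")],
                          covariates, by = c("unit", "year"))
  missing <- setdiff(vars, names(df))
  if (length(missing) > 0) {
    stop("covariate panel lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  one_fit <- function(d) {
    X <- cbind(`(Intercept)` = 1, as.matrix(d[vars]))
    re_tobit(d$D, X, d$unit, bounds = bounds, quad_points = quad_points)
  }
  fits <- list(National = one_fit(df))
  if (!is.null(region_map)) {
    region_map <- validate_region_map(region_map, unique(df$unit))
    df_r <- dplyr::left_join(df, region_map, by = "unit")
    for (r in unique(region_map$region)) {
      fits[[r]] <- one_fit(df_r[df_r$region == r, ])
    }
  }
  fits
}

#' Coefficient table for a set of Tobit fits
#'
#' @param fits Named list of `re_tobit` fits (from [fit_re_tobit()]).
#' @return Tidy tibble `scope`, `term`, `estimate`, `se`, `z`, `p_value`,
#'   `stars` (significance at 0.1/0.05/0.01).
#' @export
tobit_table <- function(fits) {
  rows <- lapply(names(fits), function(sc) {
    f <- fits[[sc]]
    z <- f$coefficients / f$se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(scope = sc, term = names(f$coefficients),
                   estimate = unname(f$coefficients), se = unname(f$se),
                   z = unname(z), p_value = unname(p),
                   stars = ifelse(p < 0.01, "***",
                           ifelse(p < 0.05, "**",
                           ifelse(p < 0.1, "*", ""))))
  })
  dplyr::bind_rows(rows)
}
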