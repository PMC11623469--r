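#' Configuration for the synthetic panel generator
#'
#' Bundles every knob of the data generator emulating a 31-unit, 13-year
#' provincial panel: region sizes, latent development trends for the two
#' subsystems, region-level offsets, spatial spillover strength, noise
#' levels, the missing-cell rate exercising imputation, and the true panel
#' Tobit parameters used for the covariate stage.
#'
#' The defaults encode the study conditions the package is designed around:
#' 31 units over 2010-2022 split 11/8/12 into Eastern/Central/Western
#' regions; latent subsystem levels rising so the environment index grows on
#' the order of 86% and the health index 56% over the window; positive
#' spatial spillover `rho = 0.6`; Tobit coefficients
#' `(0.08, 0.15, -0.015, 0.02, -0.01)` with `sigma_u = 0.03`,
#' `sigma_e = 0.02`.
#'
#' @param n_units Number of units (31).
#' @param years Year vector (2010:2022).
#' @param region_sizes Named integer vector of region sizes summing to
#'   `n_units`.
#' @param specs Indicator specification (default [default_indicator_specs()]).
#' @param trend_start,trend_end Named numeric: latent level of each subsystem
#'   in the first / last year.
#' @param region_offsets List (one named numeric per subsystem) of additive
#'   region effects on the latent level.
#' @param rho Spatial spillover strength in `[0, 1)` of the
#'   simultaneous-autoregressive noise.
#' @param noise_sd Standard deviation of the latent-level noise.
#' @param measurement_sd Relative sd of indicator measurement noise.
#' @param missing_frac Fraction of panel cells deleted to exercise
#'   imputation.
#' @param knn Number of nearest neighbours in the generated contiguity graph.
#' @param tobit_beta True covariate coefficients
#'   (lnPGDP, lnUR, lnOPEN, lnEL, lnGHE).
#' @param tobit_alpha True intercept; `NULL` centers the linear index at
#'   `tobit_center`.
#' @param tobit_center Target mean of the generated CCD (0.55).
#' @param sigma_u,sigma_e True random-effect and idiosyncratic sds.
#' @param seed Integer seed; every generator call is fully determined by it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_units = 31,
    years = 2010:2022,
    region_sizes = c(Eastern = 11, Central = 8, Western = 12),
    specs = default_indicator_specs(),
    trend_start = c(EEC = 0.26, RPH = 0.30),
    trend_end = c(EEC = 0.485, RPH = 0.465),
    region_offsets = list(
      EEC = c(Eastern = 0.000, Central = -0.015, Western = 0.005),
      RPH = c(Eastern = 0.020, Central = -0.012, Western = -0.003)),
    rho = 0.6,
    noise_sd = 0.05,
    measurement_sd = 0.05,
    missing_frac = 0.02,
    knn = 4,
    tobit_beta = c(lnPGDP = 0.08, lnUR = 0.15, lnOPEN = -0.015,
                   lnEL = 0.02, lnGHE = -0.01),
    tobit_alpha = NULL,
    tobit_center = 0.55,
    sigma_u = 0.03,
    sigma_e = 0.02,
    seed = 2010) {
  if (sum(region_sizes) != n_units) {
    stop("region sizes must sum to n_units", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (noise_sd <= 0 || sigma_u <= 0 || sigma_e <= 0) {
    stop("all standard deviations must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# symmetric k-nearest-neighbour contiguity on point coordinates
knn_contiguity <- function(coords, k = 4) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, order(d[i, ])[seq_len(k)]] <- 1
  }
  A <- pmax(A, t(A))  # symmetrize: contiguity is mutual
  dimnames(A) <- dimnames(d)
  A
}

#' Generate a synthetic indicator panel with spatial structure
#'
#' Latent subsystem development levels rise linearly over the years with
#' region offsets, a persistent unit effect, and yearly shocks, both built by
#' a simultaneous-autoregressive (SAR) transform `(I - rho W)^-1 e` on a
#' generated contiguity graph, so neighbouring units co-move (positive
#' spatial autocorrelation of the resulting CCD). Each indicator is a
#' monotone noisy affine transform of its subsystem's latent level, rising
#' for positive-attribute indicators and falling for negative ones. A
#' configurable fraction of cells is deleted (each series keeps at least two
#' observations) to exercise imputation.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `panel` (an `indicator_panel` with missing cells),
#'   `region_map`, `weights` (row-standardized `spatial_weights`), `coords`,
#'   and `latent` (tibble `unit`, `year`, one column per subsystem).
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_units
  years <- cfg$years
  Tn <- length(years)
  units <- sprintf("P%02d", seq_len(n))

  coords <- cbind(x = runif(n), y = runif(n))
  rownames(coords) <- units
  # regions are contiguous blocks along the x axis, mimicking east-west bands
  ord <- order(coords[, "x"])
  region <- character(n)
  pos <- 1
  for (r in names(cfg$region_sizes)) {
    take <- ord[seq(pos, pos + cfg$region_sizes[[r]] - 1)]
    region[take] <- r
    pos <- pos + cfg$region_sizes[[r]]
  }
  region_map <- tibble::tibble(unit = units, region = region)

  A <- knn_contiguity(coords, k = cfg$knn)
  dimnames(A) <- list(units, units)
  W <- spatial_weights(A, row_standardize = TRUE)
  sar <- solve(diag(n) - cfg$rho * unclass(W))

  subsystems <- unique(cfg$specs$subsystem)
  latent <- tibble::tibble(unit = rep(units, Tn),
                           year = rep(years, each = n))
  # spillover operates on the overall regional development level: one shared
  # spatial field moves both subsystems (neighbouring units co-develop),
  # with smaller subsystem-specific components on top
  shared_persistent <- drop(sar %*% rnorm(n, sd = cfg$noise_sd))
  shared_yearly <- as.vector(sar %*% matrix(rnorm(n * Tn,
                                                  sd = cfg$noise_sd / 2),
                                            n, Tn))
  for (s in subsystems) {
    base <- cfg$trend_start[[s]] +
      (cfg$trend_end[[s]] - cfg$trend_start[[s]]) *
      rep((seq_len(Tn) - 1) / (Tn - 1), each = n)
    offs <- cfg$region_offsets[[s]][region]
    specific_persistent <- drop(sar %*% rnorm(n, sd = cfg$noise_sd / 2))
    specific_yearly <- rnorm(n * Tn, sd = cfg$noise_sd / 4)
    latent[[s]] <- base + rep(offs, Tn) +
      rep(shared_persistent + specific_persistent, Tn) +
      shared_yearly + specific_yearly
  }

  rows <- list()
  for (j in seq_len(nrow(cfg$specs))) {
    sp <- cfg$specs[j, ]
    L <- latent[[sp$subsystem]]
    scale_j <- runif(1, 0.5, 2)
    base_j <- runif(1, 0, 1)
    signed <- if (sp$attribute == "positive") L else (1.2 - L)
    value <- base_j + scale_j * signed +
      rnorm(length(L), sd = cfg$measurement_sd * scale_j)
    rows[[j]] <- tibble::tibble(unit = latent$unit, year = latent$year,
                                indicator = sp$indicator, value = value)
  }
  long <- dplyr::bind_rows(rows)

  if (cfg$missing_frac > 0) {
    drop_mask <- runif(nrow(long)) < cfg$missing_frac
    # never reduce a (unit, indicator) series below two observations
    long <- long |>
      dplyr::mutate(.drop = drop_mask) |>
      dplyr::group_by(.data$unit, .data$indicator) |>
      dplyr::mutate(.drop = .data$.drop &
                      cumsum(.data$.drop) <= dplyr::n() - 2) |>
      dplyr::ungroup()
    long <- long[!long$.drop, c("unit", "year", "indicator", "value")]
  }

  list(panel = indicator_panel(long, cfg$specs),
       region_map = region_map, weights = W, coords = coords,
       latent = latent)
}

#' Generate a covariate panel tied to the CCD by the true Tobit relation
#'
#' Two modes. With `ccd_truth = NULL` (simulation studies), the five
#' socio-economic covariates are generated first on realistic log scales and
#' the CCD is then drawn from the linear index
#' `D = alpha + X beta + u_i + e_it`, clipped to \[0, 1\]. With a `ccd_truth`
#' panel supplied (pipeline runs), the covariates are solved against the
#' given CCD: four covariates are drawn from their marginal models and
#' lnPGDP is set so the configured relation holds exactly.
#'
#' @param cfg A [synthetic_config()].
#' @param ccd_truth Optional tibble `unit`, `year`, `D` to condition on.
#' @return List with `covariates` (tibble `unit`, `year`, lnPGDP, lnUR,
#'   lnOPEN, lnEL, lnGHE), `ccd` (tibble `unit`, `year`, `D`), and `truth`
#'   (alpha, beta, sigma_u, sigma_e actually used).
#' @export
generate_covariates <- function(cfg, ccd_truth = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_units
  years <- cfg$years
  Tn <- length(years)
  units <- sprintf("P%02d", seq_len(n))
  t_idx <- rep(seq_len(Tn) - 1, each = n)

  unit_fx <- function(s) rep(rnorm(n, sd = s), Tn)
  X <- tibble::tibble(
    unit = rep(units, Tn),
    year = rep(years, each = n),
    lnPGDP = log(3e4) + 0.060 * t_idx + unit_fx(0.25) + rnorm(n * Tn, sd = 0.05),
    lnUR   = log(55)  + 0.012 * t_idx + unit_fx(0.12) + rnorm(n * Tn, sd = 0.02),
    lnOPEN = log(15)  - 0.005 * t_idx + unit_fx(0.60) + rnorm(n * Tn, sd = 0.10),
    lnEL   = log(10)  + 0.030 * t_idx + unit_fx(0.40) + rnorm(n * Tn, sd = 0.05),
    lnGHE  = log(28)  + unit_fx(0.15) + rnorm(n * Tn, sd = 0.05))

  beta <- cfg$tobit_beta
  vars <- names(beta)
  u <- rep(rnorm(n, sd = cfg$sigma_u), Tn)
  e <- rnorm(n * Tn, sd = cfg$sigma_e)

  if (is.null(ccd_truth)) {
    index_no_alpha <- as.matrix(X[vars]) %*% beta
    alpha <- if (is.null(cfg$tobit_alpha)) {
      cfg$tobit_center - mean(index_no_alpha)
    } else cfg$tobit_alpha
    D <- pmin(pmax(drop(alpha + index_no_alpha) + u + e, 0), 1)
    ccd <- tibble::tibble(unit = X$unit, year = X$year, D = D)
  } else {
    key <- paste(X$unit, X$year)
    truth_key <- paste(ccd_truth$unit, ccd_truth$year)
    D <- ccd_truth$D[match(key, truth_key)]
    if (any(is.na(D))) {
      stop("ccd_truth does not cover the generated unit-year grid",
           call. = FALSE)
    }
    others <- as.matrix(X[setdiff(vars, "lnPGDP")]) %*%
      beta[setdiff(vars, "lnPGDP")]
    alpha <- if (is.null(cfg$tobit_alpha)) {
      mean(D) - mean(beta[["lnPGDP"]] * X$lnPGDP + others)
    } else cfg$tobit_alpha
    X$lnPGDP <- drop(D - alpha - others - u - e) / beta[["lnPGDP"]]
    ccd <- tibble::tibble(unit = X$unit, year = X$year, D = D)
  }
  list(covariates = X, ccd = ccd,
       truth = list(alpha = alpha, beta = beta,
                    sigma_u = cfg$sigma_u, sigma_e = cfg$sigma_e))
}
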