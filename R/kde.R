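#' Silverman rule-of-thumb bandwidth
#'
#' `h = 0.9 * min(sd, IQR / 1.34) * n^(-1/5)`.
#'
#' @param values Numeric vector with `n >= 2` and nonzero dispersion.
#' @return Bandwidth h > 0.
#' @export
silverman_bandwidth <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least two values for a bandwidth", call. = FALSE)
  spread <- min(sd(values), IQR(values) / 1.34)
  if (!is.finite(spread) || spread <= 0) {
    # fall back to sd alone when the IQR collapses (heavily tied data)
    spread <- sd(values)
  }
  if (!is.finite(spread) || spread <= 0) {
    stop("zero dispersion: bandwidth undefined", call. = FALSE)
  }
  0.9 * spread * n^(-1 / 5)
}

#' Gaussian kernel density estimate on an explicit grid
#'
#' `f(x) = (1 / (n h)) * sum_i K((x - x_i) / h)` with the standard normal
#' kernel `K(u) = exp(-u^2 / 2) / sqrt(2 pi)`, evaluated by direct summation
#' at each grid point.
#'
#' @param values Sample values.
#' @param grid Evaluation points; default 512 evenly spaced points spanning
#'   `[min - 3h, max + 3h]`.
#' @param h Bandwidth; default [silverman_bandwidth()].
#' @return A `kde_curve`: list with `grid`, `density`, `h`, `n`.
#' @export
#' @examples
#' kde_curve(c(-1, 1), grid = 0, h = 1)$density  # dnorm(1) = 0.24197...
kde_curve <- function(values, grid = NULL, h = NULL) {
  if (is.null(h)) h <- silverman_bandwidth(values)
  if (!is.finite(h) || h <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = 512)
  }
  dens <- vapply(grid, function(x) mean(dnorm((x - values) / h)) / h,
                 numeric(1))
  structure(list(grid = grid, density = dens, h = h, n = length(values)),
            class = "kde_curve")
}

#' @export
print.kde_curve <- function(x, ...) {
  cat(sprintf("<kde_curve> n = %d, h = %.4g, %d grid points on [%.4g, %.4g]\n",
              x$n, x$h, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Summary features of a density curve
#'
#' Modes are strict local maxima of the gridded density whose height exceeds
#' 5% of the global peak (suppressing numerical ripples); `peak_location` is
#' the grid point of the global maximum; `right_tail_mass` is the trapezoidal
#' integral of the density beyond `tail_cutoff`.
#'
#' @param curve A `kde_curve`.
#' @param tail_cutoff Point beyond which the right-tail mass is integrated;
#'   default the 90th percentile of the grid range weighted by density mass.
#' @return A list `n_modes`, `peak_location`, `right_tail_mass`.
#' @export
kde_summary <- function(curve, tail_cutoff = NULL) {
  d <- curve$density
  g <- curve$grid
  peak <- max(d)
  thresh <- 0.05 * peak
  is_mode <- vapply(seq_along(d), function(i) {
    if (d[i] <= thresh) return(FALSE)
    left <- if (i > 1) d[i - 1] else -Inf
    right <- if (i < length(d)) d[i + 1] else -Inf
    d[i] > left && d[i] > right
  }, logical(1))
  if (is.null(tail_cutoff)) {
    # pooled 90th percentile of the estimated distribution on the grid
    cdf <- cumsum((d[-1] + d[-length(d)]) / 2 * diff(g))
    cdf <- c(0, cdf) / max(cdf[length(cdf)], .Machine$double.eps)
    tail_cutoff <- g[which(cdf >= 0.9)[1]]
  }
  beyond <- g >= tail_cutoff
  rt <- if (sum(beyond) >= 2) {
    gb <- g[beyond]; db <- d[beyond]
    sum((db[-1] + db[-length(db)]) / 2 * diff(gb))
  } else 0
  list(n_modes = sum(is_mode), peak_location = g[which.max(d)],
       right_tail_mass = rt)
}

#' Per-year kernel density curves of the CCD
#'
#' One Gaussian KDE of the cross-sectional CCD distribution per year, for the
#' full sample and optionally per region.
#'
#' @param ccd_tbl Output of [ccd_panel()].
#' @param region_map Optional tibble `unit`, `region`; when given, curves are
#'   also computed per region.
#' @param shared_bandwidth If `TRUE`, one bandwidth (from the pooled sample)
#'   is used for every curve, making widths comparable across years; default
#'   `FALSE` (Silverman per curve).
#' @return Tibble `scope`, `year`, `grid`, `density`, `h` in long format.
#' @export
kde_by_year <- function(ccd_tbl, region_map = NULL, shared_bandwidth = FALSE) {
  long <- dplyr::mutate(ccd_tbl, scope = "National")
  if (!is.null(region_map)) {
    region_map <- validate_region_map(region_map, unique(ccd_tbl$unit))
    regional <- ccd_tbl |>
      dplyr::left_join(region_map, by = "unit") |>
      dplyr::rename(scope = "region")
    long <- dplyr::bind_rows(long, regional)
  }
  h0 <- if (shared_bandwidth) silverman_bandwidth(ccd_tbl$D) else NULL
  long |>
    dplyr::group_by(.data$scope, .data$year) |>
    dplyr::group_modify(function(d, key) {
      cv <- kde_curve(d$D, h = h0)
      tibble::tibble(grid = cv$grid, density = cv$density, h = cv$h)
    }) |>
    dplyr::ungroup()
}
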