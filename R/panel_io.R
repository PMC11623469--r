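#' Construct and validate an indicator panel
#'
#' An indicator panel is a long (tidy) table of raw observations: one row per
#' (unit, year, indicator) cell. The attached specification fixes which
#' indicators exist, which subsystem each belongs to, and its attribute sign.
#'
#' @param data A data frame with columns `unit`, `year`, `indicator`, `value`.
#' @param specs Indicator specification tibble; defaults to
#'   [default_indicator_specs()].
#' @return An `indicator_panel`: a tibble with the specification attached as
#'   the `"specs"` attribute.
#' @export
indicator_panel <- function(data, specs = default_indicator_specs()) {
  specs <- validate_indicator_specs(specs)
  required <- c("unit", "year", "indicator", "value")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("panel lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)[required]
  unknown <- setdiff(unique(data$indicator), specs$indicator)
  if (length(unknown) > 0) {
    stop("unknown indicator id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(data[c("unit", "year", "indicator")])
  if (any(dup)) {
    d <- data[dup, ]
    stop("duplicate panel cell(s), e.g. (", d$unit[1], ", ", d$year[1], ", ",
         d$indicator[1], ")", call. = FALSE)
  }
  if (!is.numeric(data$value)) stop("value column must be numeric", call. = FALSE)
  structure(data, specs = specs,
            class = c("indicator_panel", class(tibble::tibble())))
}

#' @export
print.indicator_panel <- function(x, ...) {
  specs <- panel_specs(x)
  cat("<indicator_panel> ", length(unique(x$unit)), " units x ",
      length(unique(x$year)), " years x ", nrow(specs), " indicators (",
      sum(is.na(x$value)), " missing cells)\n", sep = "")
  NextMethod()
}

#' Specification attached to a panel
#' @param panel An `indicator_panel`.
#' @return The specification tibble.
#' @export
panel_specs <- function(panel) attr(panel, "specs")

#' Read a long-format indicator panel from CSV
#'
#' The canonical input is a tidy CSV with columns `unit`, `year`, `indicator`,
#' `value`; missing cells are simply absent rows (or `NA` values).
#'
#' @param path CSV path.
#' @inheritParams indicator_panel
#' @return An `indicator_panel`.
#' @export
read_indicator_panel <- function(path, specs = default_indicator_specs()) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  indicator_panel(data, specs)
}

#' Write an indicator panel to CSV
#' @param panel An `indicator_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicator_panel <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel), path)
  invisible(path)
}

#' Fill missing panel cells by linear interpolation in time
#'
#' Completes every (unit, indicator) series over the full consecutive year
#' range of the panel. Interior gaps are filled by linear interpolation in
#' year; gaps before the first or after the last observed year are filled with
#' the nearest observed value (flat extrapolation). The operation is
#' idempotent: a complete panel is returned unchanged.
#'
#' @param panel An `indicator_panel`, possibly with missing cells.
#' @return A complete `indicator_panel` (every cell present and finite).
#' @export
impute_linear <- function(panel) {
  specs <- panel_specs(panel)
  years <- seq(min(panel$year), max(panel$year))
  units <- sort(unique(panel$unit))
  grid <- tidyr::expand_grid(unit = units, year = years,
                             indicator = specs$indicator)
  full <- dplyr::left_join(grid, tibble::as_tibble(panel),
                           by = c("unit", "year", "indicator"))
  filled <- full |>
    dplyr::group_by(.data$unit, .data$indicator) |>
    dplyr::group_modify(function(df, key) {
      obs <- df[is.finite(df$value), ]
      if (nrow(obs) < 2) {
        stop("cannot impute series with <2 observations: (",
             key$unit, ", ", key$indicator, ")", call. = FALSE)
      }
      # rule = 2: flat extension beyond the observed range
      df$value <- approx(obs$year, obs$value, xout = df$year,
                         method = "linear", rule = 2)$y
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$unit, .data$year, .data$indicator)
  indicator_panel(filled, specs)
}

#' Read a unit-to-region map from CSV
#'
#' @param path CSV with columns `unit`, `region`.
#' @return A tibble `unit`, `region`.
#' @export
read_region_map <- function(path) {
  rm <- readr::read_csv(path, show_col_types = FALSE)
  validate_region_map(rm)
}

validate_region_map <- function(region_map, units = NULL) {
  if (!all(c("unit", "region") %in% names(region_map))) {
    stop("region map needs columns 'unit' and 'region'", call. = FALSE)
  }
  if (anyDuplicated(region_map$unit)) {
    stop("region map assigns some unit more than once", call. = FALSE)
  }
  if (!is.null(units)) {
    missing <- setdiff(units, region_map$unit)
    if (length(missing) > 0) {
      stop("units without a region: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  tibble::as_tibble(region_map)
}

#' Build a spatial weights matrix from an adjacency matrix
#'
#' @param W Square nonnegative symmetric matrix with zero diagonal, with unit
#'   ids as dimnames.
#' @param row_standardize Divide each nonzero row by its sum (default `TRUE`).
#'   Zero rows (isolated units) are preserved as zero.
#' @return A `spatial_weights` matrix with attribute `row_standardized`.
#' @export
spatial_weights <- function(W, row_standardize = TRUE) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (any(W < 0)) stop("W must be nonnegative", call. = FALSE)
  if (any(diag(W) != 0)) stop("W must have a zero diagonal", call. = FALSE)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10))) {
    stop("W must be symmetric before row standardization", call. = FALSE)
  }
  if (is.null(rownames(W))) {
    rownames(W) <- colnames(W) <- paste0("u", seq_len(nrow(W)))
  }
  if (row_standardize) {
    rs <- rowSums(W)
    nz <- rs > 0
    W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  }
  structure(W, row_standardized = row_standardize,
            class = c("spatial_weights", "matrix", "array"))
}

#' Read an adjacency edge list and build contiguity weights
#'
#' The edge list is a CSV with columns `unit_a`, `unit_b` and optionally
#' `weight` (default 1, binary contiguity). Edges are symmetrized.
#'
#' @param path Edge-list CSV path.
#' @param units Character vector fixing the unit order of the matrix; defaults
#'   to the sorted units appearing in the file.
#' @param row_standardize Passed to [spatial_weights()].
#' @return A `spatial_weights` matrix.
#' @export
read_edge_list <- function(path, units = NULL, row_standardize = TRUE) {
  edges <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("unit_a", "unit_b") %in% names(edges))) {
    stop("edge list needs columns 'unit_a' and 'unit_b'", call. = FALSE)
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (is.null(units)) units <- sort(unique(c(edges$unit_a, edges$unit_b)))
  unknown <- setdiff(unique(c(edges$unit_a, edges$unit_b)), units)
  if (length(unknown) > 0) {
    stop("edge list mentions unknown unit(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(units)
  W <- matrix(0, n, n, dimnames = list(units, units))
  for (k in seq_len(nrow(edges))) {
    i <- edges$unit_a[k]; j <- edges$unit_b[k]
    if (i == j) next
    W[i, j] <- max(W[i, j], edges$weight[k])
    W[j, i] <- W[i, j]
  }
  spatial_weights(W, row_standardize = row_standardize)
}
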