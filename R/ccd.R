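#' Ten-level classification labels for the coupling coordination degree
#'
#' Decile intervals over \[0, 1\]: `[0.0, 0.1)` is extreme non-coordination,
#' rising to `[0.9, 1.0]` (closed on the right) for excellent coordination.
#' @return Character vector of the ten labels, lowest interval first.
#' @export
ccd_levels <- function() {
  c("Extreme non-coordination", "Severe non-coordination",
    "Moderate non-coordination", "Mild non-coordination",
    "Near non-coordination", "Near coordination",
    "Primary coordination", "Intermediate coordination",
    "Good coordination", "Excellent coordination")
}

#' Modified two-system coupling degree
#'
#' For subsystem scores `U1`, `U2` in \[0, 1\] (internally relabelled so that
#' `U2 >= U1`), the modified coupling degree is
#' `C = (1 - (U2 - U1)) * sqrt(U1 / U2)`.
#' Unlike the traditional product-based coupling degree, this form spreads C
#' over the whole \[0, 1\] interval: C = 1 exactly when the two subsystems are
#' equal and decreases smoothly as they diverge. By convention C = 0 when both
#' scores are 0.
#'
#' @param U1,U2 Numeric vectors of subsystem scores in \[0, 1\] (recycled).
#' @return Coupling degree vector in \[0, 1\].
#' @export
#' @examples
#' coupling_degree(0.3, 0.6)  # 0.7 * sqrt(0.5)
coupling_degree <- function(U1, U2) {
  check_unit_interval(U1, "U1")
  check_unit_interval(U2, "U2")
  lo <- pmin(U1, U2)
  hi <- pmax(U1, U2)
  out <- ifelse(hi == 0, 0, (1 - (hi - lo)) * sqrt(lo / hi))
  out
}

#' Comprehensive coordination index
#'
#' Weighted mean development level `T = alpha1 * U1 + alpha2 * U2`. With the
#' default equal weights, the two subsystems are taken as equally important.
#'
#' @inheritParams coupling_degree
#' @param alpha Length-2 nonnegative weights summing to 1.
#' @return Coordination index vector in \[0, 1\].
#' @export
coordination_index <- function(U1, U2, alpha = c(0.5, 0.5)) {
  if (length(alpha) != 2 || any(alpha < 0) ||
      abs(sum(alpha) - 1) > 1e-8) {
    stop("alpha must be two nonnegative weights summing to 1", call. = FALSE)
  }
  check_unit_interval(U1, "U1")
  check_unit_interval(U2, "U2")
  alpha[1] * U1 + alpha[2] * U2
}

#' Coupling coordination degree of two subsystem scores
#'
#' Combines the coupling degree C and coordination index T into the coupling
#' coordination degree `D = sqrt(C * T)` (default), a \[0, 1\] measure of
#' synergistic development: high only when the two subsystems are both well
#' developed *and* closely matched.
#'
#' @inheritParams coordination_index
#' @param d_formula `"sqrt"` (default) for `D = sqrt(C * T)`; `"product"` for
#'   the literal product `D = C * T`.
#' @return A tibble with columns `C`, `T`, `D`.
#' @export
#' @examples
#' ccd(0.3, 0.6)
ccd <- function(U1, U2, alpha = c(0.5, 0.5),
                d_formula = c("sqrt", "product")) {
  d_formula <- match.arg(d_formula)
  C <- coupling_degree(U1, U2)
  Tv <- coordination_index(U1, U2, alpha)
  D <- if (d_formula == "sqrt") sqrt(C * Tv) else C * Tv
  tibble::tibble(C = C, T = Tv, D = D)
}

#' Classify a coupling coordination degree into ten levels
#'
#' Assigns the half-open decile interval containing D; the final interval
#' `[0.9, 1.0]` is closed on the right.
#'
#' @param D Numeric vector in \[0, 1\].
#' @return Factor with the levels of [ccd_levels()].
#' @export
#' @examples
#' classify_ccd(c(0.4908, 0.6595, 1))
classify_ccd <- function(D) {
  check_unit_interval(D, "D")
  idx <- pmin(floor(D * 10), 9) + 1
  factor(ccd_levels()[idx], levels = ccd_levels())
}

#' Coupling coordination degree panel from subsystem scores
#'
#' @param scores Wide score tibble (`unit`, `year`, two `U_*` columns), e.g.
#'   from [composite_scores()].
#' @inheritParams ccd
#' @return A tibble `unit`, `year`, the two score columns, `C`, `T`, `D`,
#'   `level`.
#' @export
ccd_panel <- function(scores, alpha = c(0.5, 0.5),
                      d_formula = c("sqrt", "product")) {
  d_formula <- match.arg(d_formula)
  ucols <- grep("^U_", names(scores), value = TRUE)
  if (length(ucols) != 2) {
    stop("scores must have exactly two U_<subsystem> columns", call. = FALSE)
  }
  res <- ccd(scores[[ucols[1]]], scores[[ucols[2]]], alpha = alpha,
             d_formula = d_formula)
  dplyr::bind_cols(scores, res) |>
    dplyr::mutate(level = classify_ccd(.data$D)) |>
    dplyr::arrange(.data$unit, .data$year)
}

#' National and regional yearly means of the CCD
#'
#' @param ccd_tbl Output of [ccd_panel()].
#' @param region_map Tibble `unit`, `region`.
#' @return Tibble `year`, `scope`, `D`, `level`: one row per year for the
#'   pooled sample (`scope = "National"`) and per region, with the mean D
#'   classified into the ten levels.
#' @export
ccd_summary <- function(ccd_tbl, region_map) {
  region_map <- validate_region_map(region_map, units = unique(ccd_tbl$unit))
  with_region <- dplyr::left_join(ccd_tbl, region_map, by = "unit")
  national <- ccd_tbl |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(D = mean(.data$D), .groups = "drop") |>
    dplyr::mutate(scope = "National")
  regional <- with_region |>
    dplyr::group_by(.data$year, scope = .data$region) |>
    dplyr::summarise(D = mean(.data$D), .groups = "drop")
  dplyr::bind_rows(national, regional) |>
    dplyr::mutate(level = classify_ccd(.data$D)) |>
    dplyr::select("year", "scope", "D", "level") |>
    dplyr::arrange(.data$scope != "National", .data$scope, .data$year)
}

check_unit_interval <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
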