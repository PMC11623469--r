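#' Min-max normalize an indicator panel by attribute sign
#'
#' Rescales every indicator to \[0, 1\] using the pooled minimum and maximum
#' across all units and years. Positive-attribute indicators map the pooled
#' maximum to 1 (`(x - min) / (max - min)`), negative-attribute indicators
#' reverse the scale (`(max - x) / (max - min)`), so that 1 is always "better".
#'
#' @param panel A complete `indicator_panel` (run [impute_linear()] first if
#'   cells are missing).
#' @return An `indicator_panel` of normalized values in \[0, 1\].
#' @export
normalize_indicators <- function(panel) {
  specs <- panel_specs(panel)
  if (any(!is.finite(panel$value))) {
    stop("panel has missing cells; impute before normalizing", call. = FALSE)
  }
  df <- tibble::as_tibble(panel) |>
    dplyr::left_join(specs[c("indicator", "attribute")], by = "indicator") |>
    dplyr::group_by(.data$indicator) |>
    dplyr::mutate(.min = min(.data$value), .max = max(.data$value)) |>
    dplyr::ungroup()
  degenerate <- unique(df$indicator[df$.max == df$.min])
  if (length(degenerate) > 0) {
    stop("constant indicator(s) cannot be normalized: ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }
  df$value <- ifelse(df$attribute == "positive",
                     (df$value - df$.min) / (df$.max - df$.min),
                     (df$.max - df$value) / (df$.max - df$.min))
  indicator_panel(df[c("unit", "year", "indicator", "value")], specs)
}

#' Entropy-based indicator weights
#'
#' Computes information-entropy weights over the pooled unit-year sample.
#' For indicator j, the proportions are
#' `p_ijt = x'_ijt / sum_{i,t} x'_ijt`, the entropy is
#' `e_j = -(1 / log(N)) * sum_{i,t} p_ijt * log(p_ijt)` (with `0 * log 0 = 0`),
#' and the weight within each subsystem is `w_j = (1 - e_j) / sum_j (1 - e_j)`.
#' Indicators with little variation across the sample carry high entropy and
#' receive low weight.
#'
#' @param norm A normalized `indicator_panel` (see [normalize_indicators()]).
#' @param subsystem Optional subsystem id to restrict to; default computes
#'   weights for every subsystem in the specification.
#' @param denominator `"nm"` (default) uses `N = n_units * n_years`, matching
#'   the pooled double sum so that `e_j` lies in \[0, 1\]; `"m"` uses the
#'   number of years only.
#' @param zero_shift Nonnegative constant added to every normalized value
#'   before forming proportions (default 0; the `0 * log 0 = 0` convention is
#'   used instead of a shift).
#' @return A tibble `indicator`, `subsystem`, `entropy`, `weight`; weights sum
#'   to 1 within each subsystem.
#' @export
entropy_weights <- function(norm, subsystem = NULL,
                            denominator = c("nm", "m"), zero_shift = 0) {
  denominator <- match.arg(denominator)
  specs <- panel_specs(norm)
  df <- tibble::as_tibble(norm) |>
    dplyr::left_join(specs[c("indicator", "subsystem")], by = "indicator")
  if (!is.null(subsystem)) df <- df[df$subsystem %in% subsystem, ]
  n_units <- length(unique(df$unit))
  n_years <- length(unique(df$year))
  log_n <- if (denominator == "nm") log(n_units * n_years) else log(n_years)
  df$value <- df$value + zero_shift
  ent <- df |>
    dplyr::group_by(.data$subsystem, .data$indicator) |>
    dplyr::summarise(.total = sum(.data$value),
                     entropy = {
                       p <- .data$value / sum(.data$value)
                       -sum(ifelse(p > 0, p * log(p), 0)) / log_n
                     }, .groups = "drop")
  if (any(ent$.total == 0)) {
    stop("indicator(s) with all-zero normalized values: ",
         paste(ent$indicator[ent$.total == 0], collapse = ", "),
         call. = FALSE)
  }
  ent |>
    dplyr::group_by(.data$subsystem) |>
    dplyr::mutate(weight = (1 - .data$entropy) / sum(1 - .data$entropy)) |>
    dplyr::ungroup() |>
    dplyr::select("indicator", "subsystem", "entropy", "weight")
}

#' Composite subsystem scores
#'
#' The development level of each subsystem for a unit-year is the weighted sum
#' `U = sum_j w_j * x'_ijt` of its normalized indicators, a value in \[0, 1\].
#'
#' @param norm A normalized `indicator_panel`.
#' @param weights Weight tibble from [entropy_weights()].
#' @return A wide tibble `unit`, `year`, and one `U_<subsystem>` column per
#'   subsystem.
#' @export
composite_scores <- function(norm, weights) {
  df <- tibble::as_tibble(norm) |>
    dplyr::inner_join(weights[c("indicator", "subsystem", "weight")],
                      by = "indicator")
  df |>
    dplyr::group_by(.data$unit, .data$year, .data$subsystem) |>
    dplyr::summarise(U = sum(.data$weight * .data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "subsystem", values_from = "U",
                       names_prefix = "U_") |>
    dplyr::arrange(.data$unit, .data$year)
}

#' Entropy scoring in one step
#'
#' Convenience wrapper: normalize, weight, and score a raw (complete) panel.
#'
#' @inheritParams normalize_indicators
#' @inheritParams entropy_weights
#' @return A list with elements `normalized` (panel), `weights` (tibble), and
#'   `scores` (wide tibble of subsystem scores).
#' @export
score_subsystems <- function(panel, denominator = c("nm", "m"),
                             zero_shift = 0) {
  denominator <- match.arg(denominator)
  norm <- normalize_indicators(panel)
  w <- entropy_weights(norm, denominator = denominator,
                       zero_shift = zero_shift)
  list(normalized = norm, weights = w, scores = composite_scores(norm, w))
}
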