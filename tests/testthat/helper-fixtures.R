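# Small in-code fixtures shared across test files.

# two-indicator specification (one positive, one negative)
tiny_specs <- function() {
  tibble::tibble(
    indicator = c("good", "bad"),
    subsystem = c("EEC", "EEC"),
    target_layer = "layer",
    attribute = c("positive", "negative"),
    unit_label = "unitless")
}

# fully observed 2-unit x 3-year panel over tiny_specs()
tiny_panel <- function() {
  grid <- tidyr::expand_grid(unit = c("a", "b"), year = 2010:2012,
                             indicator = c("good", "bad"))
  grid$value <- as.numeric(seq_len(nrow(grid)))
  indicator_panel(grid, tiny_specs())
}

# independent pairwise-sum Gini oracle (classical mean absolute difference)
brute_gini <- function(y) {
  n <- length(y)
  s <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) s <- s + abs(y[a] - y[b])
  s / (2 * n^2 * mean(y))
}

# row-standardized weights for a ring of n units
ring_weights <- function(n, units = sprintf("u%d", seq_len(n))) {
  A <- matrix(0, n, n, dimnames = list(units, units))
  for (i in seq_len(n)) {
    A[i, (i %% n) + 1] <- 1
    A[(i %% n) + 1, i] <- 1
  }
  spatial_weights(A)
}

# small complete scored panel for CCD-level tests: deterministic scores
toy_scores <- function(n_units = 6, years = 2010:2014) {
  grid <- expand.grid(unit = sprintf("u%d", seq_len(n_units)), year = years,
                      stringsAsFactors = FALSE)
  grid$U_EEC <- 0.2 + 0.5 * (grid$year - min(years)) / (length(years) - 1) +
    0.02 * as.integer(factor(grid$unit))
  grid$U_RPH <- 0.25 + 0.4 * (grid$year - min(years)) / (length(years) - 1) +
    0.015 * (n_units - as.integer(factor(grid$unit)))
  tibble::as_tibble(grid)
}
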