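#' Four quartile state labels used by the Markov analysis
#' @return Character vector, lowest state first.
#' @export
ccd_states <- function() c("low", "lower-middle", "upper-middle", "high")

#' Discretize CCD values into pooled quartile states
#'
#' Cutpoints are the 25/50/75 percentiles of all pooled unit-year values (one
#' set of cutpoints for the whole panel). States are assigned by half-open
#' intervals `[cut_k, cut_{k+1})`: a value equal to a cutpoint belongs to the
#' upper class; the top interval is closed on the right.
#'
#' @param ccd_tbl Tibble with `unit`, `year`, `D` (e.g. from [ccd_panel()]),
#'   or a tibble with a `value` column named by `value_col`.
#' @param cutpoints Optional length-3 increasing cutpoints to reuse (e.g. to
#'   bin spatial lags on the CCD scale); default: pooled quartiles of the
#'   values themselves.
#' @param value_col Column holding the values to discretize (default `"D"`).
#' @return A `state_panel`: tibble `unit`, `year`, `state` (ordered factor)
#'   with the cutpoints in the `"cutpoints"` attribute.
#' @export
discretize_ccd <- function(ccd_tbl, cutpoints = NULL, value_col = "D") {
  x <- ccd_tbl[[value_col]]
  if (is.null(cutpoints)) {
    if (length(unique(x)) < 4) {
      stop("need at least 4 distinct values to form quartile states",
           call. = FALSE)
    }
    cutpoints <- unname(quantile(x, c(0.25, 0.5, 0.75)))
  }
  if (length(cutpoints) != 3 || is.unsorted(cutpoints)) {
    stop("cutpoints must be three nondecreasing values", call. = FALSE)
  }
  idx <- findInterval(x, cutpoints) + 1L
  out <- tibble::tibble(unit = ccd_tbl$unit, year = ccd_tbl$year,
                        state = factor(ccd_states()[idx],
                                       levels = ccd_states(), ordered = TRUE))
  structure(out, cutpoints = cutpoints,
            class = c("state_panel", class(tibble::tibble())))
}

#' Estimate a Markov transition probability matrix from panel states
#'
#' Counts all one-year transitions (unit, year t) -> (unit, year t + 1) and
#' row-normalizes. A row with zero observed transitions is reported as `NA`
#' probabilities (undefined), never as zeros.
#'
#' @param states A `state_panel` (see [discretize_ccd()]).
#' @param condition Optional `state_panel` of conditioning states (evaluated
#'   at the origin year t); when given, transitions are restricted to origin
#'   years whose conditioning state equals `condition_level`.
#' @param condition_level Level of `condition` to keep.
#' @return A `transition_matrix`: list with integer `counts` (4 x 4),
#'   `probs` (rows summing to 1 or `NA`), `n_transitions`, and the
#'   conditioning level (or `NULL`).
#' @export
transition_matrix <- function(states, condition = NULL,
                              condition_level = NULL) {
  lv <- ccd_states()
  df <- tibble::as_tibble(states) |>
    dplyr::arrange(.data$unit, .data$year) |>
    dplyr::group_by(.data$unit) |>
    dplyr::mutate(to = dplyr::lead(.data$state),
                  next_year = dplyr::lead(.data$year)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to), .data$next_year == .data$year + 1)
  if (!is.null(condition)) {
    cond <- tibble::as_tibble(condition)[c("unit", "year", "state")]
    names(cond)[3] <- "cond_state"
    df <- dplyr::inner_join(df, cond, by = c("unit", "year")) |>
      dplyr::filter(.data$cond_state == condition_level)
  }
  counts <- table(factor(df$state, levels = lv), factor(df$to, levels = lv))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(lv, lv))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(list(counts = counts, probs = probs, n_transitions = sum(counts),
                 condition = condition_level),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  hdr <- if (is.null(x$condition)) "traditional"
         else paste0("lag = ", x$condition)
  cat("Markov transition probability matrix (", hdr, ", ",
      x$n_transitions, " transitions)\n", sep = "")
  print(round(x$probs, digits))
  invisible(x)
}

#' Spatial lag of the CCD
#'
#' `lag(i, t) = sum_j W_ij D(j, t)`: with row-standardized weights, the
#' weighted average CCD of unit i's neighbors in year t. Units with no
#' neighbors (zero weight rows) get `NA` lags and a warning.
#'
#' @param ccd_tbl Tibble with `unit`, `year`, `D`.
#' @param W A `spatial_weights` matrix over the panel's units.
#' @return Tibble `unit`, `year`, `lag`.
#' @export
spatial_lag <- function(ccd_tbl, W) {
  units <- rownames(W)
  missing <- setdiff(unique(ccd_tbl$unit), units)
  if (length(missing) > 0) {
    stop("weights matrix lacks unit(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  isolated <- units[rowSums(W) == 0]
  if (length(isolated) > 0) {
    warning("unit(s) with no neighbors, lag undefined: ",
            paste(isolated, collapse = ", "), call. = FALSE)
  }
  out <- ccd_tbl |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(function(d, key) {
      y <- setNames(d$D, d$unit)[units]
      lag <- as.vector(W %*% y)
      lag[units %in% isolated] <- NA_real_
      tibble::tibble(unit = units, lag = lag)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("unit", "year", "lag")
  out
}

#' Spatially conditioned Markov transition matrices
#'
#' Splits the one-year transitions by the spatial-lag class of the origin
#' year: one 4 x 4 matrix per lag state. By default the lag is discretized
#' with the *same* pooled cutpoints as the CCD states, so "low lag" and "low
#' state" refer to the same scale. The four conditional count matrices
#' partition the traditional counts exactly.
#'
#' @param states A `state_panel` of CCD states.
#' @param lag_tbl Tibble `unit`, `year`, `lag` from [spatial_lag()].
#' @param cutpoints Cutpoints for binning the lag; default: the cutpoints
#'   stored on `states`.
#' @return Named list of four `transition_matrix` objects, one per lag state.
#' @export
spatial_transition_matrices <- function(states, lag_tbl, cutpoints = NULL) {
  if (is.null(cutpoints)) cutpoints <- attr(states, "cutpoints")
  lag_states <- discretize_ccd(lag_tbl[!is.na(lag_tbl$lag), ],
                               cutpoints = cutpoints, value_col = "lag")
  out <- lapply(ccd_states(), function(lv) {
    transition_matrix(states, condition = lag_states, condition_level = lv)
  })
  names(out) <- ccd_states()
  out
}

#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij W_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `S0 = sum(W)`. The p-value comes from randomly permuting the
#' values over the units (`n_perm` draws, fixed by `seed`); the z-value uses
#' the analytic normal approximation.
#'
#' @param values Per-unit numeric vector, in the unit order of `W` (or named
#'   by unit).
#' @param W A `spatial_weights` matrix.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation draw.
#' @param alternative `"greater"` (default; positive autocorrelation),
#'   `"less"`, or `"two.sided"`.
#' @return A list `I`, `expected` (`-1/(n-1)`), `z_value`, `p_value`,
#'   `n_perm`, `alternative`.
#' @export
morans_i <- function(values, W, n_perm = 999, seed = NULL,
                     alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.null(names(values))) values <- values[rownames(W)]
  n <- length(values)
  if (n < 3) stop("need at least 3 units", call. = FALSE)
  if (n != nrow(W)) stop("length(values) must match nrow(W)", call. = FALSE)
  if (var(values) == 0) stop("zero variance: Moran's I undefined", call. = FALSE)

  stat <- function(y) {
    z <- y - mean(y)
    (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
  }
  I <- stat(values)
  EI <- -1 / (n - 1)
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VarI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  z_value <- (I - EI) / sqrt(VarI)

  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(k) stat(sample(values)), numeric(1))
  p_value <- switch(alternative,
    greater = (1 + sum(perm >= I)) / (n_perm + 1),
    less = (1 + sum(perm <= I)) / (n_perm + 1),
    two.sided = (1 + sum(abs(perm - EI) >= abs(I - EI))) / (n_perm + 1))

  list(I = I, expected = EI, z_value = z_value, p_value = p_value,
       n_perm = n_perm, alternative = alternative)
}

#' Yearly global Moran's I of the CCD
#'
#' @param ccd_tbl Tibble `unit`, `year`, `D`.
#' @inheritParams morans_i
#' @return Tibble `year`, `I`, `expected`, `z_value`, `p_value`.
#' @export
morans_i_by_year <- function(ccd_tbl, W, n_perm = 999, seed = NULL) {
  years <- sort(unique(ccd_tbl$year))
  seeds <- if (is.null(seed)) rep(list(NULL), length(years))
           else as.list(seed + seq_along(years))
  rows <- lapply(seq_along(years), function(k) {
    d <- ccd_tbl[ccd_tbl$year == years[k], ]
    m <- morans_i(setNames(d$D, d$unit), W, n_perm = n_perm,
                  seed = seeds[[k]])
    tibble::tibble(year = years[k], I = m$I, expected = m$expected,
                   z_value = m$z_value, p_value = m$p_value)
  })
  dplyr::bind_rows(rows)
}

#' Panel-level Moran test of the CCD
#'
#' Joint test of spatial autocorrelation over all years: the statistic is the
#' mean of the yearly global Moran's I values, and the permutation null
#' relabels units independently within each year. Pooling the years gives far
#' more power than any single cross-section at moderate n.
#'
#' @inheritParams morans_i_by_year
#' @return A list `I_mean` (mean yearly I), `I_by_year`, `p_value`
#'   (one-sided, positive autocorrelation), `n_perm`.
#' @export
morans_i_panel <- function(ccd_tbl, W, n_perm = 999, seed = NULL) {
  units <- rownames(W)
  years <- sort(unique(ccd_tbl$year))
  n <- length(units)
  Wm <- unclass(W)
  S0 <- sum(Wm)
  # year-by-unit value matrix in W's unit order
  V <- vapply(years, function(yr) {
    d <- ccd_tbl[ccd_tbl$year == yr, ]
    setNames(d$D, d$unit)[units]
  }, numeric(n))
  stat_one <- function(v) {
    z <- v - mean(v)
    (n / S0) * sum(Wm * outer(z, z)) / sum(z^2)
  }
  I_by_year <- apply(V, 2, stat_one)
  I_mean <- mean(I_by_year)
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(k) {
    mean(apply(V, 2, function(v) stat_one(v[sample.int(n)])))
  }, numeric(1))
  list(I_mean = I_mean, I_by_year = setNames(I_by_year, years),
       p_value = (1 + sum(perm >= I_mean)) / (n_perm + 1), n_perm = n_perm)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
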