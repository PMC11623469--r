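#' Run the full coupling-coordination analysis pipeline
#'
#' Orchestrates every stage end-to-end: (optionally) simulate a panel,
#' impute, entropy-score the two subsystems, compute the CCD panel and its
#' national/regional summary, the yearly Dagum Gini decomposition, the KDE
#' curves, the traditional and spatial Markov matrices with yearly Moran's I,
#' and the panel Tobit fits. Each enabled stage writes a tidy CSV into
#' `out_dir`; a JSON manifest records the seed, options, and stage list.
#'
#' @param out_dir Output directory (created if absent). `NULL` disables all
#'   file output.
#' @param synthetic A [synthetic_config()] used to simulate inputs; ignored
#'   when `panel` is supplied.
#' @param panel,region_map,weights,covariates Pre-loaded inputs (an
#'   `indicator_panel`, a `unit`/`region` tibble, a `spatial_weights` matrix,
#'   and a covariate tibble). Any that are `NULL` come from the simulation.
#' @param stages Character vector of stages to run, a subset of
#'   `c("score", "ccd", "gini", "kde", "markov", "tobit")` (dependencies are
#'   pulled in automatically).
#' @param d_formula,entropy_denominator,alpha Stage options passed through to
#'   [ccd_panel()] / [entropy_weights()].
#' @param n_perm Permutations for the yearly Moran's I tests.
#' @param quad_points Gauss-Hermite nodes for the Tobit stage.
#' @param seed Seed recorded in the manifest and used for the Moran
#'   permutation draws; defaults to the synthetic config's seed.
#' @return (Invisibly) a named list with every stage's results.
#' @export
run_ccd_pipeline <- function(out_dir = NULL,
                             synthetic = synthetic_config(),
                             panel = NULL, region_map = NULL,
                             weights = NULL, covariates = NULL,
                             stages = c("score", "ccd", "gini", "kde",
                                        "markov", "tobit"),
                             d_formula = c("sqrt", "product"),
                             entropy_denominator = c("nm", "m"),
                             alpha = c(0.5, 0.5),
                             n_perm = 999, quad_points = 12,
                             seed = NULL) {
  d_formula <- match.arg(d_formula)
  entropy_denominator <- match.arg(entropy_denominator)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  simulated <- is.null(panel)
  if (simulated) {
    sim <- stage("simulate", generate_panel(synthetic))
    panel <- sim$panel
    if (is.null(region_map)) region_map <- sim$region_map
    if (is.null(weights)) weights <- sim$weights
    res$simulate <- sim
  }
  if (is.null(seed)) seed <- synthetic$seed

  panel <- stage("impute", impute_linear(panel))

  scored <- stage("score", score_subsystems(panel,
                                            denominator = entropy_denominator))
  res$weights <- scored$weights
  res$scores <- scored$scores
  emit(scored$weights, "weights")
  emit(scored$scores, "scores")

  ccd_tbl <- stage("ccd", ccd_panel(scored$scores, alpha = alpha,
                                    d_formula = d_formula))
  res$ccd <- ccd_tbl
  emit(ccd_tbl, "ccd")
  if (!is.null(region_map)) {
    res$ccd_summary <- stage("ccd", ccd_summary(ccd_tbl, region_map))
    emit(res$ccd_summary, "ccd_summary")
  }

  if ("gini" %in% stages && !is.null(region_map)) {
    res$gini <- stage("gini", dagum_by_year(ccd_tbl, region_map))
    emit(res$gini, "gini")
  }

  if ("kde" %in% stages) {
    res$kde <- stage("kde", kde_by_year(ccd_tbl, region_map))
    emit(res$kde, "kde")
    res$kde_summary <- stage("kde", {
      res$kde |>
        dplyr::group_by(.data$scope, .data$year) |>
        dplyr::group_modify(function(d, key) {
          cs <- kde_summary(list(grid = d$grid, density = d$density))
          tibble::tibble(n_modes = cs$n_modes,
                         peak_location = cs$peak_location,
                         right_tail_mass = cs$right_tail_mass)
        }) |>
        dplyr::ungroup()
    })
    emit(res$kde_summary, "kde_summary")
  }

  if ("markov" %in% stages) {
    res$states <- stage("markov", discretize_ccd(ccd_tbl))
    res$transition <- stage("markov", transition_matrix(res$states))
    if (!is.null(weights)) {
      res$lag <- stage("markov", spatial_lag(ccd_tbl, weights))
      res$spatial_transitions <- stage("markov",
        spatial_transition_matrices(res$states, res$lag))
      res$moran <- stage("markov",
        morans_i_by_year(ccd_tbl, weights, n_perm = n_perm, seed = seed))
      emit(res$moran, "moran")
      emit(transition_long(res$transition, res$spatial_transitions),
           "transitions")
    }
  }

  if ("tobit" %in% stages) {
    if (is.null(covariates)) {
      gen <- stage("tobit", generate_covariates(synthetic, ccd_truth = ccd_tbl))
      covariates <- gen$covariates
      res$covariates <- covariates
      emit(covariates, "covariates")
    }
    res$tobit <- stage("tobit",
      fit_re_tobit(ccd_tbl, covariates, region_map = region_map,
                   quad_points = quad_points))
    res$tobit_table <- tobit_table(res$tobit)
    emit(res$tobit_table, "tobit")
  }

  if (!is.null(out_dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("ccdpanel")),
      seed = seed, stages = stages,
      options = list(d_formula = d_formula,
                     entropy_denominator = entropy_denominator,
                     alpha = alpha, n_perm = n_perm,
                     quad_points = quad_points),
      simulated = simulated,
      n_units = length(unique(ccd_tbl$unit)),
      years = range(ccd_tbl$year),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}

# flatten traditional + spatial transition matrices into one tidy table
transition_long <- function(trad, spatial) {
  mats <- c(list(traditional = trad), spatial)
  rows <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    tibble::tibble(
      matrix = nm,
      from = rep(rownames(m$counts), times = 4),
      to = rep(colnames(m$counts), each = 4),
      count = as.vector(m$counts),
      prob = as.vector(m$probs))
  })
  dplyr::bind_rows(rows)
}
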