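#' Built-in indicator specification for the EEC / RPH evaluation system
#'
#' Returns the default two-subsystem indicator specification: nine indicators
#' for the ecological environmental civilization (EEC) subsystem, organised in
#' pressure / state / response target layers, and fifteen for the resident
#' public health (RPH) subsystem, organised in staff / facilities / healing
#' capacity / efficiency layers. Each indicator carries an attribute sign:
#' `"positive"` indicators are better when larger, `"negative"` when smaller.
#' The sign drives min-max normalization in [normalize_indicators()].
#'
#' @return A tibble with columns `indicator`, `subsystem`, `target_layer`,
#'   `attribute`, `unit_label`.
#' @seealso [read_indicator_specs()] to load a custom specification.
#' @export
#' @examples
#' default_indicator_specs()
default_indicator_specs <- function() {
  tibble::tribble(
    ~indicator, ~subsystem, ~target_layer, ~attribute, ~unit_label,
    "cod_emissions",            "EEC", "EEC pressure", "negative", "tons / 1e8 yuan",
    "so2_emissions",            "EEC", "EEC pressure", "negative", "tons / 1e8 yuan",
    "solid_waste_emissions",    "EEC", "EEC pressure", "negative", "tons / 1e4 yuan",
    "water_resources_pc",       "EEC", "EEC state",    "positive", "cubic meters",
    "park_green_space_pc",      "EEC", "EEC state",    "positive", "square meters",
    "green_coverage_rate",      "EEC", "EEC state",    "positive", "%",
    "waste_treatment_rate",     "EEC", "EEC response", "positive", "%",
    "sewage_treatment_rate",    "EEC", "EEC response", "positive", "%",
    "green_finance",            "EEC", "EEC response", "positive", "score",
    "physicians_per_10k",       "RPH", "Medical staff", "positive", "persons",
    "nurses_per_10k",           "RPH", "Medical staff", "positive", "persons",
    "ph_managers_per_10k",      "RPH", "Medical staff", "positive", "persons",
    "primary_workers_per_10k",  "RPH", "Medical staff", "positive", "persons",
    "health_assets_pc",         "RPH", "Medical facilities", "positive", "yuan",
    "hospital_beds_per_1k",     "RPH", "Medical facilities", "positive", "number",
    "hospitals_per_10k",        "RPH", "Medical facilities", "positive", "number",
    "primary_inst_per_10k",     "RPH", "Medical facilities", "positive", "number",
    "maternal_mortality",       "RPH", "Healing capacity", "negative", "per 1e5",
    "perinatal_mortality",      "RPH", "Healing capacity", "negative", "per 1e3",
    "tertiary_hospitals",       "RPH", "Healing capacity", "positive", "number",
    "patients_per_physician",   "RPH", "Medical efficiency", "positive", "number",
    "bed_days_per_physician",   "RPH", "Medical efficiency", "positive", "days",
    "bed_utilization_rate",     "RPH", "Medical efficiency", "positive", "%",
    "avg_hospitalization_days", "RPH", "Medical efficiency", "positive", "days"
  )
}

#' Read an indicator specification from CSV or YAML
#'
#' A CSV specification must carry the columns `indicator`, `subsystem`,
#' `attribute` (optionally `target_layer`, `unit_label`). A YAML specification
#' is a list of records with the same fields.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @return A validated specification tibble (see [default_indicator_specs()]).
#' @export
read_indicator_specs <- function(path) {
  ext <- tolower(tools::file_ext(path))
  specs <- if (ext %in% c("yml", "yaml")) {
    recs <- yaml::read_yaml(path)
    dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  validate_indicator_specs(specs)
}

validate_indicator_specs <- function(specs) {
  required <- c("indicator", "subsystem", "attribute")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    stop("indicator specification lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(specs$indicator)) {
    stop("duplicate indicator id(s): ",
         paste(unique(specs$indicator[duplicated(specs$indicator)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(specs$attribute), c("positive", "negative"))
  if (length(bad) > 0) {
    stop("attribute must be 'positive' or 'negative'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"target_layer" %in% names(specs)) specs$target_layer <- NA_character_
  if (!"unit_label" %in% names(specs)) specs$unit_label <- NA_character_
  tibble::as_tibble(specs)
}
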