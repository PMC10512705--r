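#' Default model configuration
#'
#' Every input of the base-case analysis: log-logistic scale/shape of the
#' lenvatinib-arm PFS and OS laws, hazard ratios of the combination arm,
#' adverse-event incidences, unit costs (USD, 2022, converted at 6.73
#' RMB/USD), utilities, the 5% annual discount rate, the 21-day cycle, and
#' the structural toggles.  All values can be overridden via
#' [modify_config()] or a YAML/JSON file ([load_config()]).
#'
#' @return nested named list with class `tacelen_config`.
#' @export
default_config <- function() {
  structure(list(
    cycle_days = 21,
    days_per_month = 30.4375,
    days_per_year = 365.25,
    max_cycles = 200L,             # hard cap, ~11.5 years
    death_stop = 0.99,             # stop once this fraction has died
    discount_rate = 0.05,          # per year, costs and outcomes
    wtp = 38201,                   # USD/QALY, 3x 2022 Chinese GDP per capita

    pfs = list(scale = 0.1524227, shape = 2.850079),
    os  = list(scale = 0.08526536, shape = 2.926645),
    hr_pfs = list(point = 0.43, low = 0.34, high = 0.60),
    hr_os  = list(point = 0.45, low = 0.33, high = 0.60),

    natural_mortality_annual = 0.0074,  # Chinese population, 2022
    pfs_death_multiplier = 1,           # scenario switch (x2 / x4)
    recurrence_5yr = 0.19,              # post-hepatectomy recurrence
    hepatectomy_fraction = list(tacelen = 0.153, lenvatinib = 0.018),
    hepatectomy_window_months = 6,
    natural_mortality_in_rfs = TRUE,
    pd_death_mode = "os_conditional",   # or "calibrated"
    half_cycle_correction = FALSE,

    utilities = list(pfs = 0.76, rfs = 0.76, pd = 0.68),

    costs = list(
      lenvatinib_cycle = 1054.88,
      tace_cycle = 1929.00,
      hospitalization_cycle = 384.00,
      test_cycle = 359.96,
      bsc_cycle = 363.00,
      hepatectomy = 9058.24,
      end_of_life = 2176.00,
      ae = list(hyperbilirubinemia = 124.90, alt_ast = 45.60,
                weight_decreased = 75.20, hypertension = 1.48,
                diarrhea = 3.61)),
    ae_incidence = list(
      tacelen    = list(hyperbilirubinemia = 0.094, alt_ast = 0.406,
                        weight_decreased = 0.076, hypertension = 0.206,
                        diarrhea = 0.053),
      lenvatinib = list(hyperbilirubinemia = 0.030, alt_ast = 0.030,
                        weight_decreased = 0.071, hypertension = 0.196,
                        diarrhea = 0.042)),

    tace_sessions = 3,            # one per cycle while in PFS
    lenvatinib_dose = 12,         # mg/day; drug cost scales linearly
    bsc_coverage = 1,             # fraction of PD patients receiving BSC
    test_in_pd = TRUE,            # monitoring continues on BSC
    hosp_in_pd = TRUE             # inpatient supportive care on BSC
  ), class = "tacelen_config")
}

#' Modify a configuration by dotted key paths
#'
#' @param config a `tacelen_config`.
#' @param ... named overrides, names are dotted paths such as
#'   `"costs.bsc_cycle"` or `"hr_pfs.point"`.
#' @return the modified configuration; the input is not changed (pure).
#' @examples
#' cfg <- modify_config(default_config(), "utilities.pfs" = 0.8)
#' @export
modify_config <- function(config, ...) {
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) ||
      (length(ov) == 1L && identical(names(ov), "") && is.list(ov[[1]])))
    ov <- ov[[1]]
  for (key in names(ov)) config <- set_config_key(config, key, ov[[key]])
  config
}

set_config_key <- function(config, key, value) {
  if (is.atomic(value)) value <- unname(value)
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  ref <- config
  for (p in parts) {
    if (is.null(ref[[p]]))
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    ref <- ref[[p]]
  }
  config[[parts]] <- value
  config
}

get_config_key <- function(config, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  ref <- config
  for (p in parts) {
    if (is.null(ref[[p]]))
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    ref <- ref[[p]]
  }
  ref
}

#' Read / write a configuration file
#'
#' YAML or JSON by file extension.  Keys present in the file override the
#' defaults; absent keys keep their default values.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @param config configuration to save.
#' @return `load_config` returns a `tacelen_config`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  cfg <- utils::modifyList(default_config(), raw)
  class(cfg) <- "tacelen_config"
  cfg
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(unclass(config), path),
    json = jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}

#' Stable hash of a configuration (provenance tag on result tables)
#' @param config a `tacelen_config`.
#' @return character scalar.
#' @export
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 15)),
             collapse = "\n")
  # small polynomial rolling hash; avoids extra dependencies
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# survival curves of one strategy under a config
strategy_curves <- function(config, strategy = c("tacelen", "lenvatinib")) {
  strategy <- match.arg(strategy)
  pfs <- surv_params("loglogistic", config$pfs$scale, config$pfs$shape)
  os <- surv_params("loglogistic", config$os$scale, config$os$shape)
  if (strategy == "tacelen") {
    pfs <- apply_hr(pfs, config$hr_pfs$point)
    os <- apply_hr(os, config$hr_os$point)
  }
  list(pfs = pfs, os = os)
}
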