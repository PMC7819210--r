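# analysis configuration: defaults, validation, file round-trip (YAML/JSON)

#' Build an analysis configuration
#'
#' Bundles every tunable of the cost-effectiveness engine with the
#' documented base-case defaults: 10,000 Monte Carlo samples per patient,
#' 3%/year discounting, willingness-to-pay thresholds of $100k/$250k/$500k
#' per QALY, upfront costs of $20,257 (photon) / $36,659 (proton) for 33
#' fractions, proton-cost scenarios $31,659/$26,659/$21,659, dysphagia
#' chronic in 50% of cases (scenarios 0% and 100%), utility and
#' management-cost tables with their 95% CIs, and the smoking hazard
#' ratio 1.73 (95% CI 1.17–2.57, sampled on the log scale).
#'
#' @param n_samples Monte Carlo replicates per patient.
#' @param seed Master seed; per-patient substreams are derived from it and
#'   the patient id, so cohort order does not change results.
#' @param discount_rate Annual discount rate for QALYs and cost annuities.
#' @param thresholds Willingness-to-pay thresholds ($/QALY), ascending.
#' @param mode `"full_psa"` (sample all uncertain parameters) or
#'   `"base_case"` (parameters fixed at base values; complication events
#'   remain Monte Carlo).
#' @param upfront Upfront cost list ([default_upfront_costs()]).
#' @param proton_cost_scenarios One-way scenario values for the proton
#'   upfront cost.
#' @param dysphagia_chronic_proportion Base proportion of dysphagia cases
#'   that are chronic (rest resolve within 5 years).
#' @param dysphagia_chronic_scenarios One-way scenario values for that
#'   proportion.
#' @param utilities Utility spec table ([default_utility_specs()]).
#' @param cost_items Cost item table ([default_cost_items()]).
#' @param hr_base,hr_ci,hr_scale Smoking hazard-ratio base value, 95% CI
#'   and sampling scale (see [sample_hazard_ratio()]).
#' @param horizon Survival horizon in years.
#' @param event_coupling `"common"` (common random numbers: one uniform per
#'   complication compared against both modalities' NTCP — paired design,
#'   default) or `"independent"`.
#' @param utility_combination `"multiplicative"` (default) or `"additive"`
#'   combination of concurrent health-state utilities.
#' @param management_mode `"expected"` (management proportions applied as
#'   expected-cost weights, default) or `"bernoulli"` (management events
#'   drawn per sample).
#' @param truncnorm_mode Truncation handling for CI-matched normal
#'   proportions: `"resample"` (default) or `"clip"`.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(n_samples = 10000L,
                            seed = 1L,
                            discount_rate = 0.03,
                            thresholds = c(100000, 250000, 500000),
                            mode = c("full_psa", "base_case"),
                            upfront = default_upfront_costs(),
                            proton_cost_scenarios = c(31659, 26659, 21659),
                            dysphagia_chronic_proportion = 0.5,
                            dysphagia_chronic_scenarios = c(0, 1),
                            utilities = default_utility_specs(),
                            cost_items = default_cost_items(),
                            hr_base = 1.73,
                            hr_ci = c(1.17, 2.57),
                            hr_scale = c("log", "linear"),
                            horizon = 40L,
                            event_coupling = c("common", "independent"),
                            utility_combination = c("multiplicative", "additive"),
                            management_mode = c("expected", "bernoulli"),
                            truncnorm_mode = c("resample", "clip")) {
  mode <- match.arg(mode)
  hr_scale <- match.arg(hr_scale)
  event_coupling <- match.arg(event_coupling)
  utility_combination <- match.arg(utility_combination)
  management_mode <- match.arg(management_mode)
  truncnorm_mode <- match.arg(truncnorm_mode)
  if (n_samples < 1) stop_config("'n_samples' must be > 0")
  if (length(thresholds) < 1 || any(thresholds <= 0) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop_config("'thresholds' must be positive and strictly ascending")
  }
  if (!length(proton_cost_scenarios)) {
    stop_config("'proton_cost_scenarios' must be non-empty")
  }
  if (!length(dysphagia_chronic_scenarios)) {
    stop_config("'dysphagia_chronic_scenarios' must be non-empty")
  }
  check_probability(dysphagia_chronic_proportion, "dysphagia_chronic_proportion")
  check_probability(dysphagia_chronic_scenarios, "dysphagia_chronic_scenarios")
  if (discount_rate < 0) stop_config("'discount_rate' must be >= 0")
  validate_utility_specs(utilities)
  cost_items <- validate_cost_items(cost_items)
  structure(list(
    schema_version = 1L,
    n_samples = as.integer(n_samples), seed = as.integer(seed),
    discount_rate = discount_rate, thresholds = thresholds, mode = mode,
    upfront = upfront, proton_cost_scenarios = proton_cost_scenarios,
    dysphagia_chronic_proportion = dysphagia_chronic_proportion,
    dysphagia_chronic_scenarios = dysphagia_chronic_scenarios,
    utilities = utilities, cost_items = cost_items,
    hr_base = hr_base, hr_ci = hr_ci, hr_scale = hr_scale,
    horizon = as.integer(horizon), event_coupling = event_coupling,
    utility_combination = utility_combination,
    management_mode = management_mode, truncnorm_mode = truncnorm_mode
  ), class = "analysis_config")
}

# data.frame <-> plain list-of-columns for YAML/JSON round-trips
df_to_list <- function(df) lapply(as.list(df), function(col) unname(col))
list_to_df <- function(lst) data.frame(lst, stringsAsFactors = FALSE)

#' Write an analysis configuration to file
#'
#' YAML (default) or JSON, chosen by extension (`.json` for JSON). The file
#' carries a `schema_version` key and round-trips through
#' [read_analysis_config()].
#'
#' @param config An [analysis_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  payload <- unclass(config)
  payload$utilities <- df_to_list(payload$utilities)
  payload$cost_items <- df_to_list(payload$cost_items)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(payload), path)
  }
  invisible(path)
}

#' Read an analysis configuration from file
#'
#' @param path YAML or JSON file written by [write_analysis_config()] (or
#'   hand-edited with the same keys; missing keys fall back to defaults).
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$schema_version) && raw$schema_version != 1L) {
    stop_config("unsupported config schema_version %s", raw$schema_version)
  }
  raw$schema_version <- NULL
  if (!is.null(raw$utilities)) raw$utilities <- list_to_df(raw$utilities)
  if (!is.null(raw$cost_items)) raw$cost_items <- list_to_df(raw$cost_items)
  if (!is.null(raw$hr_ci)) raw$hr_ci <- as.numeric(raw$hr_ci)
  if (!is.null(raw$thresholds)) raw$thresholds <- as.numeric(raw$thresholds)
  do.call(analysis_config, raw)
}

# survival spec consistent with a config (default life table / cancer curves)
survival_spec_from_config <- function(config,
                                      life_table = default_life_table(),
                                      cancer_survival = default_cancer_survival()) {
  survival_model_spec(
    life_table = life_table, cancer_survival = cancer_survival,
    hr_base = config$hr_base, hr_ci = config$hr_ci,
    hr_scale = config$hr_scale, horizon = config$horizon
  )
}
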