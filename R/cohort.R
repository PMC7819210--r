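# synthetic cohort generation and cohort CSV I/O
#
# A cohort is a plain data.frame with one row per patient:
#   patient_id, age, sex ("male"/"female"), p16 (0/1), heavy_smoker (0/1),
#   laterality ("bilateral"/"unilateral"), and ten NTCP columns
#   <complication>_photon / <complication>_proton for the five modeled
#   complications. Booleans are stored 0/1 so the CSV round-trips exactly.

cohort_ntcp_columns <- function() {
  as.vector(t(outer(.COMPLICATIONS, .MODALITIES, paste, sep = "_")))
}

cohort_columns <- function() {
  c("patient_id", "age", "sex", "p16", "heavy_smoker", "laterality",
    cohort_ntcp_columns())
}

#' Default per-complication photon-NTCP sampling ranges
#'
#' Emulation constants for the synthetic cohort generator: for each
#' complication and nodal-irradiation stratum, the `(low, high)` bounds of
#' the uniform distribution the photon NTCP is drawn from. Bilateral
#' (comprehensive) nodal irradiation exposes more normal tissue, so every
#' bilateral bound sits above its unilateral counterpart; the unilateral
#' bounds are low enough that a substantial fraction of Monte Carlo samples
#' show no complication difference between modalities. These are documented
#' constants describing the cohort the generator emulates, not estimates
#' fitted to any dataset.
#'
#' @return A data.frame with columns `complication`, `stratum`, `low`, `high`.
#' @export
default_ntcp_ranges <- function() {
  rbind(
    data.frame(
      complication = .COMPLICATIONS, stratum = "bilateral",
      low  = c(0.25, 0.10, 0.35, 0.20, 0.25),
      high = c(0.70, 0.40, 0.80, 0.60, 0.60)
    ),
    data.frame(
      complication = .COMPLICATIONS, stratum = "unilateral",
      low  = c(0.10, 0.05, 0.20, 0.10, 0.10),
      high = c(0.45, 0.25, 0.60, 0.40, 0.40)
    )
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients (default 33).
#' @param frac_bilateral Proportion treated with bilateral comprehensive
#'   nodal irradiation (default 21/33); the bilateral count is
#'   `round(n_patients * frac_bilateral)`.
#' @param ntcp_ranges Data.frame as [default_ntcp_ranges()]: per-complication
#'   `(low, high)` photon-NTCP bounds for each laterality stratum.
#' @param rr_range Range `(low, high)` in \[0, 1\] of the proton/photon
#'   relative risk; each patient-complication entry draws
#'   `p_proton = p_photon * rr` with `rr` uniform on this range, so proton
#'   NTCP never exceeds photon NTCP.
#' @param age_range Integer ages drawn uniformly on this range (default
#'   45–75).
#' @param p16_prop Proportion p16-positive (default 0.55).
#' @param smoker_prop Proportion with a >10 pack-year smoking history
#'   (default 0.4).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#'
#' @return A list of class `cohort_gen_config`.
#' @export
#' @examples
#' cfg <- cohort_gen_config(seed = 1)
#' cohort <- generate_cohort(cfg)
#' table(cohort$laterality)
cohort_gen_config <- function(n_patients = 33L,
                              frac_bilateral = 21 / 33,
                              ntcp_ranges = default_ntcp_ranges(),
                              rr_range = c(0.2, 0.7),
                              age_range = c(45L, 75L),
                              p16_prop = 0.55,
                              smoker_prop = 0.4,
                              seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_config("'n_patients' must be a positive count")
  }
  check_probability(frac_bilateral, "frac_bilateral")
  check_probability(p16_prop, "p16_prop")
  check_probability(smoker_prop, "smoker_prop")
  check_range(rr_range, "rr_range")
  check_probability(rr_range, "rr_range")
  check_range(age_range, "age_range")
  need <- c("complication", "stratum", "low", "high")
  if (!all(need %in% names(ntcp_ranges))) {
    stop_config("'ntcp_ranges' must have columns %s", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(ntcp_ranges))) {
    nm <- sprintf("ntcp_ranges[%s, %s]", ntcp_ranges$complication[i],
                  ntcp_ranges$stratum[i])
    check_range(c(ntcp_ranges$low[i], ntcp_ranges$high[i]), nm)
    check_probability(c(ntcp_ranges$low[i], ntcp_ranges$high[i]), nm)
  }
  for (str in c("bilateral", "unilateral")) {
    miss <- setdiff(.COMPLICATIONS,
                    ntcp_ranges$complication[ntcp_ranges$stratum == str])
    if (length(miss)) {
      stop_config("'ntcp_ranges' is missing %s bounds for: %s",
                  str, paste(miss, collapse = ", "))
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), frac_bilateral = frac_bilateral,
    ntcp_ranges = ntcp_ranges, rr_range = rr_range,
    age_range = as.integer(age_range), p16_prop = p16_prop,
    smoker_prop = smoker_prop, seed = as.integer(seed)
  ), class = "cohort_gen_config")
}

#' Generate a synthetic patient cohort
#'
#' Emulates the statistical structure the analysis assumes: `n_patients`
#' oropharyngeal cancer patients split into bilateral and unilateral
#' nodal-irradiation strata, each with photon NTCP drawn uniformly from the
#' stratum's per-complication range and proton NTCP equal to the photon NTCP
#' times a uniform relative-risk draw (so proton risk never exceeds photon
#' risk). Ages, sex, p16 status and smoking history are drawn independently.
#'
#' @param config A [cohort_gen_config()].
#' @return A data.frame, one row per patient (see [read_cohort()] for the
#'   column contract), bilateral patients first.
#' @export
generate_cohort <- function(config = cohort_gen_config()) {
  if (!inherits(config, "cohort_gen_config")) {
    config <- do.call(cohort_gen_config, config)
  }
  n <- config$n_patients
  n_bi <- as.integer(round(n * config$frac_bilateral))
  laterality <- rep(c("bilateral", "unilateral"), c(n_bi, n - n_bi))

  set.seed(config$seed)
  age <- sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  p16 <- as.integer(stats::runif(n) < config$p16_prop)
  smoker <- as.integer(stats::runif(n) < config$smoker_prop)

  cohort <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = age, sex = sex, p16 = p16, heavy_smoker = smoker,
    laterality = laterality, stringsAsFactors = FALSE
  )
  rng <- config$ntcp_ranges
  for (comp in .COMPLICATIONS) {
    lo <- hi <- numeric(n)
    for (str in c("bilateral", "unilateral")) {
      row <- rng[rng$complication == comp & rng$stratum == str, ]
      idx <- laterality == str
      lo[idx] <- row$low[1]
      hi[idx] <- row$high[1]
    }
    p_photon <- stats::runif(n, lo, hi)
    rr <- stats::runif(n, config$rr_range[1], config$rr_range[2])
    cohort[[paste0(comp, "_photon")]] <- p_photon
    cohort[[paste0(comp, "_proton")]] <- p_photon * rr
  }
  cohort[, cohort_columns()]
}

#' Write a cohort to CSV
#'
#' @param cohort Cohort data.frame (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort, warn_ordering = FALSE)
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Expects the documented header
#' `patient_id,age,sex,p16,heavy_smoker,laterality,dysphagia_photon,dysphagia_proton,...`
#' with booleans coded 0/1 and laterality `bilateral|unilateral`. Any
#' probability outside \[0, 1\] or malformed field is rejected with the row
#' and column identified. User-supplied cohorts with `p_proton > p_photon`
#' are accepted with a warning (only generated cohorts guarantee the
#' ordering).
#'
#' @param path CSV file path.
#' @return Validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop_config("cohort file '%s' is missing columns: %s", path,
                paste(missing_cols, collapse = ", "))
  }
  validate_cohort(cohort, warn_ordering = TRUE)
  cohort[, cohort_columns()]
}

#' Validate a cohort table
#'
#' @param cohort Cohort data.frame.
#' @param warn_ordering Warn (rather than ignore) rows where a proton NTCP
#'   exceeds its photon counterpart.
#' @return `cohort`, invisibly; errors identify the offending row/column.
#' @export
validate_cohort <- function(cohort, warn_ordering = TRUE) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop_config("cohort is missing columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cohort$patient_id)) {
    stop_config("duplicate patient_id values in cohort")
  }
  if (any(!cohort$sex %in% c("male", "female"))) {
    bad <- which(!cohort$sex %in% c("male", "female"))[1]
    stop_config("row %d: 'sex' must be male|female (got '%s')",
                bad, cohort$sex[bad])
  }
  if (any(!cohort$laterality %in% c("bilateral", "unilateral"))) {
    bad <- which(!cohort$laterality %in% c("bilateral", "unilateral"))[1]
    stop_config("row %d: 'laterality' must be bilateral|unilateral (got '%s')",
                bad, cohort$laterality[bad])
  }
  for (col in c("p16", "heavy_smoker")) {
    if (any(!cohort[[col]] %in% c(0L, 1L))) {
      bad <- which(!cohort[[col]] %in% c(0L, 1L))[1]
      stop_config("row %d: '%s' must be 0/1", bad, col)
    }
  }
  if (any(!is.finite(cohort$age)) || any(cohort$age < 18)) {
    bad <- which(!is.finite(cohort$age) | cohort$age < 18)[1]
    stop_config("row %d: 'age' must be an integer >= 18", bad)
  }
  for (col in cohort_ntcp_columns()) {
    v <- cohort[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      bad <- which(!is.finite(v) | v < 0 | v > 1)[1]
      stop_config("row %d, column '%s': probability outside [0, 1] (got %s)",
                  bad, col, format(v[bad]))
    }
  }
  if (warn_ordering) {
    for (comp in .COMPLICATIONS) {
      ph <- cohort[[paste0(comp, "_photon")]]
      pr <- cohort[[paste0(comp, "_proton")]]
      if (any(pr > ph)) {
        warning(sprintf(
          "%d row(s) have %s proton NTCP above photon NTCP (first: row %d); accepted as supplied",
          sum(pr > ph), comp, which(pr > ph)[1]), call. = FALSE)
      }
    }
  }
  invisible(cohort)
}
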