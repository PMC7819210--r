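# cohort summaries: ICER medians/IQRs, threshold proportions, dominance
# fractions, subgroup breakdowns, acceptability curves

# summary statistics for one set of sample rows
sample_stats <- function(samples, thresholds) {
  tr <- samples$icer[samples$dominance == "tradeoff"]
  qs <- if (length(tr)) stats::quantile(tr, c(0.25, 0.5, 0.75), names = FALSE)
        else rep(NA_real_, 3)
  mean_dq <- mean(samples$delta_qaly)
  prop_ce <- vapply(thresholds, function(th)
    mean(is_cost_effective(samples$dominance, samples$icer, th)), 0)
  list(
    n = nrow(samples),
    median_icer = qs[2], icer_q25 = qs[1], icer_q75 = qs[3],
    # secondary pooling: ratio of mean differences (the conventional
    # cohort ICER), defined when the mean QALY difference is positive
    icer_ratio_of_means = if (mean_dq > 0) mean(samples$delta_cost) / mean_dq
                          else NA_real_,
    frac_photon_dominates = mean(samples$dominance == "photon_dominates"),
    frac_proton_dominates = mean(samples$dominance == "proton_dominates"),
    frac_tradeoff = mean(samples$dominance == "tradeoff"),
    frac_no_difference = mean(samples$no_difference),
    prop_cost_effective = stats::setNames(prop_ce, as.character(thresholds))
  )
}

stats_row <- function(stats, thresholds) {
  cbind(
    data.frame(n = stats$n, median_icer = stats$median_icer,
               icer_q25 = stats$icer_q25, icer_q75 = stats$icer_q75,
               icer_ratio_of_means = stats$icer_ratio_of_means,
               frac_photon_dominates = stats$frac_photon_dominates,
               frac_proton_dominates = stats$frac_proton_dominates,
               frac_tradeoff = stats$frac_tradeoff,
               frac_no_difference = stats$frac_no_difference),
    as.data.frame(as.list(stats::setNames(
      stats$prop_cost_effective, thr_col(thresholds))))
  )
}

#' Summarise a PSA sample table
#'
#' Pooled, per-patient and subgroup summaries of the Monte Carlo samples:
#' median and IQR of per-sample ICERs among trade-off samples (the
#' ratio-of-means cohort ICER is emitted alongside as a secondary
#' statistic, and so is the median of per-patient medians, since several
#' pooling conventions coexist in the literature), dominance fractions,
#' the fraction of samples with no QALY difference, and the proportion of
#' samples cost-effective at each willingness-to-pay threshold. Subgroups:
#' p16 status, age below/at-or-above 65, nodal-irradiation laterality.
#'
#' @param samples Sample table from [run_psa()].
#' @param cohort Matching cohort data.frame (for covariates).
#' @param thresholds Willingness-to-pay thresholds ($/QALY).
#' @return List with `pooled`, `per_patient` (data.frame, bilateral
#'   patients first), `subgroups` (data.frame),
#'   `median_of_patient_medians`, `thresholds`.
#' @export
summarize_psa <- function(samples, cohort,
                          thresholds = c(100000, 250000, 500000)) {
  if (!nrow(samples)) stop_config("no samples to summarise")
  pooled <- sample_stats(samples, thresholds)

  ord <- order(match(cohort$laterality, c("bilateral", "unilateral")))
  cohort <- cohort[ord, ]
  per_patient <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    sub <- samples[samples$patient_id == cohort$patient_id[i], , drop = FALSE]
    cbind(data.frame(patient_id = cohort$patient_id[i],
                     laterality = cohort$laterality[i],
                     p16 = cohort$p16[i], age = cohort$age[i],
                     stringsAsFactors = FALSE),
          stats_row(sample_stats(sub, thresholds), thresholds))
  }))

  cov <- cohort[match(samples$patient_id, cohort$patient_id), ]
  groups <- list(
    p16_positive = cov$p16 == 1, p16_negative = cov$p16 == 0,
    age_lt65 = cov$age < 65, age_ge65 = cov$age >= 65,
    bilateral = cov$laterality == "bilateral",
    unilateral = cov$laterality == "unilateral"
  )
  subgroups <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- samples[groups[[g]], , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    cbind(data.frame(subgroup = g, stringsAsFactors = FALSE),
          stats_row(sample_stats(sub, thresholds), thresholds))
  }))

  list(
    pooled = pooled,
    per_patient = per_patient,
    subgroups = subgroups,
    median_of_patient_medians =
      stats::median(per_patient$median_icer, na.rm = TRUE),
    thresholds = thresholds
  )
}

#' Cost-effectiveness acceptability curve
#'
#' Proportion of samples cost-effective as a function of the
#' willingness-to-pay threshold. Non-decreasing in the threshold, bounded
#' below by the proton-dominant fraction and above by one minus the
#' photon-dominant fraction.
#'
#' @param samples Sample table from [run_psa()].
#' @param thresholds Thresholds to evaluate ($/QALY).
#' @return Data.frame with columns `threshold`, `prop_cost_effective`.
#' @export
ceac <- function(samples, thresholds) {
  data.frame(
    threshold = thresholds,
    prop_cost_effective = vapply(thresholds, function(th)
      mean(is_cost_effective(samples$dominance, samples$icer, th)), 0)
  )
}

#' Threshold-by-scenario cost-effectiveness grid
#'
#' Builds the threshold x proton-cost grid from a proton-cost scenario
#' analysis: for every willingness-to-pay threshold (rows) and proton
#' upfront cost (columns, base case first) the pooled proportion of
#' cost-effective samples, with the minimum and maximum over individual
#' patients in parentheses-style companion columns (the least / most
#' likely patient).
#'
#' @param scen A `cea_scenarios` object from [one_way_scenarios()]
#'   including the `proton_cost` family.
#' @return Data.frame with columns `threshold`, `proton_cost`, `pooled`,
#'   `patient_min`, `patient_max`.
#' @export
report_threshold_grid <- function(scen) {
  tab <- scen$table[scen$table$scenario %in% c("base_case", "proton_cost"), ]
  pp <- scen$per_patient[
    scen$per_patient$scenario %in% c("base_case", "proton_cost"), ]
  if (!nrow(tab)) stop_config("no samples: scenario table is empty")
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    sc <- tab$scenario[i]; val <- tab$value[i]
    ppi <- pp[pp$scenario == sc &
                (is.na(val) | pp$value == val), , drop = FALSE]
    for (th in scen$thresholds) {
      col <- thr_col(th)
      rows[[length(rows) + 1]] <- data.frame(
        threshold = th,
        proton_cost = if (sc == "base_case") NA_real_ else val,
        scenario = sc,
        pooled = tab[[col]][i],
        patient_min = min(ppi[[col]]),
        patient_max = max(ppi[[col]]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$threshold, -xtfrm(out$scenario == "base_case"),
            -out$proton_cost, na.last = FALSE), ]
}

#' Per-patient threshold proportions (acceptability by patient)
#'
#' One row per patient — bilateral (comprehensive) nodal irradiation
#' first — with the proportion of that patient's samples cost-effective
#' at each threshold, plus covariates.
#'
#' @param result A `cea_psa` object from [run_psa()].
#' @return Data.frame.
#' @export
report_per_patient <- function(result) {
  if (!nrow(result$samples)) stop_config("no samples in result")
  result$summary$per_patient
}
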