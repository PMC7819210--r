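# Monte Carlo probabilistic sensitivity analysis engine
#
# Per patient, n_samples replicates are drawn from a dedicated RNG
# substream (seeded from the master seed and the patient id, so cohort
# order cannot change results). Draw order within a substream is fixed and
# documented, so scenario runs sharing a seed are harmonized draw-for-draw:
#   1. event uniforms, photon (n x 5, complication order)
#   2. event uniforms, proton (only under independent coupling)
#   3. dysphagia chronic-flag uniforms (n)
#   4. management-event uniforms (only under bernoulli management)
#   5. full PSA only: utility uniforms (per complication), hazard-ratio
#      uniforms, proportion-parameter uniforms (item-table order of
#      parameter groups), amount-parameter uniforms
# All distribution draws are inverse-CDF transforms of these uniforms, so
# collapsing a CI to a point leaves every other draw untouched.

#' Incremental cost-effectiveness ratio of one sample
#'
#' `delta_cost / delta_qaly` when the sample is a trade-off (both
#' differences positive); `NA` otherwise — zero or negative QALY
#' difference means photon therapy dominates, positive QALY difference at
#' non-positive cost difference means proton therapy dominates (see
#' [classify_dominance()]).
#'
#' @param delta_cost Cost difference, proton minus photon (dollars).
#' @param delta_qaly QALY difference, proton minus photon.
#' @return Numeric vector: $/QALY for trade-off samples, `NA` elsewhere.
#' @export
#' @examples
#' icer(15000, 0.1) # 150000
icer <- function(delta_cost, delta_qaly) {
  out <- rep(NA_real_, length(delta_qaly))
  tr <- delta_qaly > 0 & delta_cost > 0
  out[tr] <- delta_cost[tr] / delta_qaly[tr]
  out
}

#' Classify a sample's dominance status
#'
#' Exhaustive, mutually exclusive sign rule: a zero or negative QALY
#' difference means `photon_dominates`; a positive QALY difference with a
#' zero or negative cost difference means `proton_dominates`; both
#' positive is a `tradeoff` (the only case with a defined ICER).
#'
#' @inheritParams icer
#' @return Character vector with values `photon_dominates`,
#'   `proton_dominates`, `tradeoff`.
#' @export
classify_dominance <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly <= 0, "photon_dominates",
         ifelse(delta_cost <= 0, "proton_dominates", "tradeoff"))
}

#' Is a sample cost-effective at a willingness-to-pay threshold?
#'
#' `TRUE` iff proton therapy dominates, or the sample is a trade-off with
#' ICER at or below the threshold (inclusive comparison). Photon-dominant
#' samples — including those with no QALY difference — are never
#' cost-effective.
#'
#' @param dominance Labels from [classify_dominance()].
#' @param icer ICER values (NA for non-trade-off samples).
#' @param threshold Willingness-to-pay threshold ($/QALY).
#' @return Logical vector.
#' @export
is_cost_effective <- function(dominance, icer, threshold) {
  dominance == "proton_dominates" |
    (dominance == "tradeoff" & !is.na(icer) & icer <= threshold)
}

# parameter groups of the cost-item table with an uncertain proportion /
# amount, in stable item-table order
uncertain_prop_groups <- function(items) {
  has <- !is.na(items$prop_ci_low) & !is.na(items$prop_ci_high)
  unique(items$param_group[has])
}
uncertain_amount_groups <- function(items) {
  has <- !is.na(items$amount_ci_low) & !is.na(items$amount_ci_high)
  unique(items$param_group[has])
}

# one patient's replicate block; returns a data.frame of n_samples rows
psa_patient <- function(patient, config, spec) {
  n <- config$n_samples
  comps <- .COMPLICATIONS
  items <- validate_cost_items(config$cost_items)
  full_psa <- config$mode == "full_psa"

  set.seed(patient_seed(config$seed, patient$patient_id))

  ## --- draws (fixed order, see header) -------------------------------
  U_ph <- matrix(stats::runif(n * 5L), n, 5L, dimnames = list(NULL, comps))
  U_pr <- if (config$event_coupling == "independent") {
    matrix(stats::runif(n * 5L), n, 5L, dimnames = list(NULL, comps))
  } else U_ph
  u_chronic <- stats::runif(n)
  U_mg <- if (config$management_mode == "bernoulli") {
    matrix(stats::runif(n * nrow(items)), n, nrow(items))
  } else NULL

  uspecs <- config$utilities[match(comps, config$utilities$complication), ]
  u_mat <- matrix(rep(uspecs$utility, each = n), n, 5L,
                  dimnames = list(NULL, comps))
  hr_draws <- rep(config$hr_base, n)
  prop_draws <- list()
  amount_draws <- list()
  if (full_psa) {
    for (i in seq_along(comps)) {
      u <- stats::runif(n)
      if (uspecs$ci_low[i] < uspecs$ci_high[i]) {
        sh <- fit_beta_from_ci(uspecs$ci_low[i], uspecs$ci_high[i])
        u_mat[, i] <- stats::qbeta(u, sh[1], sh[2])
      } else {
        u_mat[, i] <- uspecs$ci_low[i]
      }
    }
    hspec <- list(hr_ci = config$hr_ci, hr_scale = config$hr_scale)
    hr_draws <- sample_hazard_ratio(hspec, n)
    for (g in uncertain_prop_groups(items)) {
      row <- items[items$param_group == g &
                     !is.na(items$prop_ci_low), ][1, ]
      fit <- fit_truncnorm_from_ci(row$prop_ci_low, row$prop_ci_high)
      prop_draws[[g]] <- qtruncnorm(stats::runif(n), fit$mean, fit$sd,
                                    0, 1, mode = config$truncnorm_mode)
    }
    for (g in uncertain_amount_groups(items)) {
      row <- items[items$param_group == g &
                     !is.na(items$amount_ci_low), ][1, ]
      fit <- fit_truncnorm_from_ci(row$amount_ci_low, row$amount_ci_high,
                                   bounds = c(0, Inf))
      amount_draws[[g]] <- qtruncnorm(stats::runif(n), fit$mean, fit$sd,
                                      0, Inf, mode = config$truncnorm_mode)
    }
  }

  ## --- events ---------------------------------------------------------
  p_ph <- vapply(comps, function(cp) patient[[paste0(cp, "_photon")]], 0)
  p_pr <- vapply(comps, function(cp) patient[[paste0(cp, "_proton")]], 0)
  E_ph <- sweep(U_ph, 2, p_ph, "<")
  E_pr <- sweep(U_pr, 2, p_pr, "<")
  dys_chronic <- u_chronic < config$dysphagia_chronic_proportion

  ## --- survival -------------------------------------------------------
  hr_eff <- if (patient$heavy_smoker == 1) hr_draws else rep(1, n)
  bg <- background_survival(patient$age, patient$sex, spec)
  lca <- cancer_log_survival(patient$p16 == 1, spec)
  S <- exp(hr_eff %o% lca)
  S <- sweep(S, 2, bg, "*")
  H <- spec$horizon
  w <- (1 + config$discount_rate)^-(seq_len(H) - 1)
  k5 <- seq_len(min(5L, H))
  DLY <- as.vector(S %*% w)
  D5 <- as.vector(S[, k5, drop = FALSE] %*% w[k5])
  S1 <- S[, 1]

  qaly_ph <- qalys_vectorized(E_ph, dys_chronic, u_mat, S1, DLY, D5,
                              uspecs, config$utility_combination)
  qaly_pr <- qalys_vectorized(E_pr, dys_chronic, u_mat, S1, DLY, D5,
                              uspecs, config$utility_combination)

  ## --- costs ----------------------------------------------------------
  mgmt <- function(E) {
    total <- rep(0, n)
    for (i in seq_len(nrow(items))) {
      ev <- as.numeric(E[, items$complication[i]])
      prop <- prop_draws[[items$param_group[i]]] %||% items$proportion[i]
      amount <- amount_draws[[items$param_group[i]]] %||% items$amount[i]
      weight <- if (!is.null(U_mg)) as.numeric(U_mg[, i] < prop) else prop
      annuity <- switch(items$recurrence[i],
        one_time = 1,
        per_year = if (identical(items$duration[i], "dysphagia_rule")) {
          ifelse(dys_chronic, DLY, D5)
        } else DLY)
      total <- total + ev * amount * weight * annuity
    }
    total
  }
  cost_ph <- config$upfront$photon + mgmt(E_ph)
  cost_pr <- config$upfront$proton + mgmt(E_pr)

  if (any(!is.finite(c(qaly_ph, qaly_pr, cost_ph, cost_pr)))) {
    bad <- which(!is.finite(qaly_ph + qaly_pr + cost_ph + cost_pr))[1]
    stop_config("non-finite result for patient %s, replicate %d",
                patient$patient_id, bad)
  }

  dq <- qaly_pr - qaly_ph
  dc <- cost_pr - cost_ph
  dom <- classify_dominance(dc, dq)
  data.frame(
    patient_id = patient$patient_id, replicate = seq_len(n),
    qaly_photon = qaly_ph, qaly_proton = qaly_pr,
    cost_photon = cost_ph, cost_proton = cost_pr,
    delta_qaly = dq, delta_cost = dc,
    icer = icer(dc, dq), dominance = dom,
    no_difference = dq == 0,
    stringsAsFactors = FALSE
  )
}

# vectorized QALY computation over n samples (one patient, one modality);
# agrees with compute_qalys() case-for-case (property-tested)
qalys_vectorized <- function(E, dys_chronic, u_mat, S1, DLY, D5,
                             uspecs, combination) {
  n <- nrow(E)
  comps <- uspecs$complication
  chronic <- comps[uspecs$rule == "chronic_lifelong"]
  mixed <- comps[uspecs$rule == "mixed_chronic_or_5yr"]
  acute <- which(uspecs$rule == "acute")

  if (combination == "multiplicative") {
    Uc <- rep(1, n)
    for (cp in chronic) Uc <- Uc * ifelse(E[, cp], u_mat[, cp], 1)
    Ufull <- Uc
    Ulate <- Uc
    for (cp in mixed) {
      Ufull <- Ufull * ifelse(E[, cp], u_mat[, cp], 1)
      Ulate <- Ulate * ifelse(E[, cp] & dys_chronic, u_mat[, cp], 1)
    }
  } else {
    decr_full <- decr_late <- rep(0, n)
    for (cp in chronic) {
      d <- E[, cp] * (1 - u_mat[, cp])
      decr_full <- decr_full + d
      decr_late <- decr_late + d
    }
    for (cp in mixed) {
      decr_full <- decr_full + E[, cp] * (1 - u_mat[, cp])
      decr_late <- decr_late + (E[, cp] & dys_chronic) * (1 - u_mat[, cp])
    }
    Ufull <- pmax(1 - decr_full, 0)
    Ulate <- pmax(1 - decr_late, 0)
  }

  qaly <- Ufull * D5 + Ulate * (DLY - D5)

  if (length(acute)) {
    d <- uspecs$acute_weeks[acute] / 52
    ord <- order(d)
    d <- d[ord]; acute <- acute[ord]
    if (combination == "multiplicative") {
      K <- length(acute)
      P <- rep(1, n)
      m <- rep(1 - d[K], n)
      bounds <- c(0, d)
      for (k in rev(seq_len(K))) {
        P <- P * ifelse(E[, comps[acute[k]]], u_mat[, comps[acute[k]]], 1)
        m <- m + (bounds[k + 1] - bounds[k]) * P
      }
      qaly <- qaly + S1 * Ufull * (m - 1)
    } else {
      loss <- rep(0, n)
      for (k in seq_along(acute)) {
        loss <- loss + d[k] * E[, comps[acute[k]]] *
          (1 - u_mat[, comps[acute[k]]])
      }
      qaly <- qaly - S1 * pmin(loss, Ufull)
    }
  }
  qaly
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' For every patient in the cohort, draws `config$n_samples` replicates:
#' complication events per modality (common random numbers by default, so
#' the photon/proton comparison is paired), utility / hazard-ratio /
#' management-proportion parameter values (in `full_psa` mode), then
#' computes discounted QALYs and total costs for both modalities, the
#' per-sample ICER and the dominance classification. A fixed seed
#' reproduces the sample table bit-identically.
#'
#' @param cohort Cohort data.frame ([generate_cohort()] / [read_cohort()]).
#' @param config An [analysis_config()].
#' @param survival_spec Optional [survival_model_spec()]; defaults to the
#'   packaged life table and cancer curves with the config's hazard-ratio
#'   settings and horizon.
#' @return Object of class `cea_psa`: list with `samples` (one row per
#'   patient x replicate), `summary` (see [summarize_psa()]), `config`,
#'   `survival_spec`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_gen_config(n_patients = 4, seed = 1))
#' res <- run_psa(cohort, analysis_config(n_samples = 200))
#' res$summary$pooled$median_icer
run_psa <- function(cohort, config = analysis_config(), survival_spec = NULL) {
  validate_cohort(cohort, warn_ordering = FALSE)
  if (is.null(survival_spec)) survival_spec <- survival_spec_from_config(config)
  blocks <- lapply(seq_len(nrow(cohort)), function(i) {
    psa_patient(as.list(cohort[i, ]), config, survival_spec)
  })
  samples <- do.call(rbind, blocks)
  structure(list(
    samples = samples,
    summary = summarize_psa(samples, cohort, config$thresholds),
    config = config, survival_spec = survival_spec
  ), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  p <- x$summary$pooled
  cat(sprintf(
    "<cea_psa> %d patients x %d replicates (%s mode)\n",
    length(unique(x$samples$patient_id)), x$config$n_samples, x$config$mode))
  cat(sprintf("  median ICER (trade-off samples): $%s/QALY (IQR $%s-$%s)\n",
              format(round(p$median_icer), big.mark = ","),
              format(round(p$icer_q25), big.mark = ","),
              format(round(p$icer_q75), big.mark = ",")))
  cat(sprintf("  dominance: photon %.1f%%, proton %.1f%%, trade-off %.1f%% (no QALY difference %.1f%%)\n",
              100 * p$frac_photon_dominates, 100 * p$frac_proton_dominates,
              100 * p$frac_tradeoff, 100 * p$frac_no_difference))
  ce <- x$summary$pooled$prop_cost_effective
  cat("  cost-effective:",
      paste(sprintf("%.1f%% at $%s", 100 * ce,
                    format(x$summary$thresholds, big.mark = ",")),
            collapse = ", "), "\n")
  invisible(x)
}

#' One-way scenario analyses
#'
#' Reruns [run_psa()] varying exactly one component per scenario — the
#' upfront proton cost (base $36,659 plus the configured scenario values)
#' and the dysphagia chronicity proportion (base 50% plus 0%/100%) —
#' with all random draws harmonized through the shared seed, so only
#' outputs that depend on the varied component change.
#'
#' @param cohort Cohort data.frame.
#' @param config An [analysis_config()].
#' @param scenarios Which scenario families to run.
#' @param survival_spec Optional [survival_model_spec()].
#' @param keep_samples Keep each run's sample table (memory-hungry).
#' @return Object of class `cea_scenarios`: list with `table` (one row per
#'   scenario, base case first: pooled median ICER, dominance fractions and
#'   threshold proportions), `per_patient` (per-scenario per-patient
#'   threshold proportions, used by [report_threshold_grid()]), and
#'   optionally `runs`.
#' @export
one_way_scenarios <- function(cohort, config = analysis_config(),
                              scenarios = c("proton_cost",
                                            "dysphagia_chronicity"),
                              survival_spec = NULL, keep_samples = FALSE) {
  valid <- c("proton_cost", "dysphagia_chronicity")
  bad <- setdiff(scenarios, valid)
  if (length(bad)) {
    stop_config("unknown scenario(s) %s; valid: %s",
                paste(bad, collapse = ", "), paste(valid, collapse = ", "))
  }
  grid <- data.frame(scenario = "base_case", value = NA_real_,
                     stringsAsFactors = FALSE)
  if ("proton_cost" %in% scenarios) {
    grid <- rbind(grid, data.frame(scenario = "proton_cost",
                                   value = config$proton_cost_scenarios))
  }
  if ("dysphagia_chronicity" %in% scenarios) {
    grid <- rbind(grid, data.frame(scenario = "dysphagia_chronicity",
                                   value = config$dysphagia_chronic_scenarios))
  }
  runs <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  per_patient <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    if (grid$scenario[i] == "proton_cost") {
      cfg$upfront$proton <- grid$value[i]
    } else if (grid$scenario[i] == "dysphagia_chronicity") {
      cfg$dysphagia_chronic_proportion <- grid$value[i]
    }
    res <- run_psa(cohort, cfg, survival_spec)
    p <- res$summary$pooled
    ce <- stats::setNames(p$prop_cost_effective, thr_col(config$thresholds))
    rows[[i]] <- cbind(
      data.frame(scenario = grid$scenario[i], value = grid$value[i],
                 median_icer = p$median_icer, icer_q25 = p$icer_q25,
                 icer_q75 = p$icer_q75,
                 frac_photon_dominates = p$frac_photon_dominates,
                 frac_proton_dominates = p$frac_proton_dominates,
                 frac_no_difference = p$frac_no_difference,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(ce)))
    pp <- res$summary$per_patient
    pp$scenario <- grid$scenario[i]
    pp$value <- grid$value[i]
    per_patient[[i]] <- pp
    if (keep_samples) runs[[i]] <- res
  }
  structure(list(
    table = do.call(rbind, rows),
    per_patient = do.call(rbind, per_patient),
    runs = if (keep_samples) runs else NULL,
    thresholds = config$thresholds
  ), class = "cea_scenarios")
}
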