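# fixtures built in code: small deterministic cohorts and event vectors

# a hand-written cohort with controllable NTCP values
make_test_cohort <- function(ntcp_photon, rr = 0.5,
                             laterality = NULL, p16 = NULL, age = NULL,
                             smoker = NULL, sex = NULL) {
  n <- length(ntcp_photon[[1]])
  stopifnot(all(lengths(ntcp_photon) == n))
  cohort <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    age = age %||% rep(60L, n),
    sex = sex %||% rep("female", n),
    p16 = p16 %||% rep(1L, n),
    heavy_smoker = smoker %||% rep(0L, n),
    laterality = laterality %||% rep("bilateral", n),
    stringsAsFactors = FALSE
  )
  for (comp in complication_names()) {
    cohort[[paste0(comp, "_photon")]] <- ntcp_photon[[comp]]
    cohort[[paste0(comp, "_proton")]] <- ntcp_photon[[comp]] * rr
  }
  cohort
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# cohort where nothing can happen
zero_ntcp_cohort <- function(n = 3) {
  make_test_cohort(setNames(rep(list(rep(0, n)), 5), complication_names()))
}

# moderate-risk cohort used across engine tests
risk_cohort <- function(n = 4) {
  base <- c(dysphagia = 0.4, esophagitis = 0.2, xerostomia = 0.5,
            hypothyroidism = 0.3, mucositis = 0.35)
  make_test_cohort(lapply(base, function(p) rep(p, n)),
                   rr = 0.5,
                   laterality = rep(c("bilateral", "unilateral"),
                                    length.out = n),
                   p16 = rep(c(1L, 0L), length.out = n),
                   age = seq(50L, by = 7L, length.out = n),
                   smoker = rep(c(0L, 1L), length.out = n))
}

# event list helper
make_events <- function(..., chronic = FALSE) {
  occurred <- c(...)
  ev <- setNames(rep(FALSE, 5), complication_names())
  ev[occurred] <- TRUE
  list(events = ev, dysphagia_chronic = chronic)
}

# analysis config collapsing every CI to its base value (degenerate PSA)
collapsed_ci_config <- function(...) {
  cfg <- analysis_config(...)
  cfg$utilities$ci_low <- cfg$utilities$utility
  cfg$utilities$ci_high <- cfg$utilities$utility
  cfg$hr_ci <- c(cfg$hr_base, cfg$hr_base)
  has_prop <- !is.na(cfg$cost_items$prop_ci_low)
  cfg$cost_items$prop_ci_low[has_prop] <- cfg$cost_items$proportion[has_prop]
  cfg$cost_items$prop_ci_high[has_prop] <- cfg$cost_items$proportion[has_prop]
  has_amt <- !is.na(cfg$cost_items$amount_ci_low)
  cfg$cost_items$amount_ci_low[has_amt] <- cfg$cost_items$amount[has_amt]
  cfg$cost_items$amount_ci_high[has_amt] <- cfg$cost_items$amount[has_amt]
  cfg
}
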