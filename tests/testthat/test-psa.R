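test_that("ICER evaluates trade-offs and routes other sign patterns to dominance", {
  expect_equal(icer(15000, 0.1), 150000)
  expect_true(is.na(icer(15000, 0)))
  expect_true(is.na(icer(-500, 0.2)))
  expect_equal(classify_dominance(15000, 0), "photon_dominates")
  expect_equal(classify_dominance(-500, 0.2), "proton_dominates")
  expect_equal(classify_dominance(10, 0.01), "tradeoff")
  expect_equal(classify_dominance(0, 0), "photon_dominates")
})

test_that("dominance classification matches a brute-force sign-table oracle on a 441-point grid", {
  # independently coded oracle: explicit case analysis
  oracle <- function(dc, dq) {
    if (dq < 0) return("photon_dominates")
    if (dq == 0) return("photon_dominates")
    if (dc < 0) return("proton_dominates")
    if (dc == 0) return("proton_dominates")
    "tradeoff"
  }
  grid <- expand.grid(dc = seq(-1e5, 1e5, length.out = 21),
                      dq = seq(-1, 1, length.out = 21))
  got <- classify_dominance(grid$dc, grid$dq)
  want <- mapply(oracle, grid$dc, grid$dq)
  expect_equal(nrow(grid), 441)
  expect_equal(got, unname(want))
  # exhaustive and mutually exclusive: exactly one label everywhere
  expect_true(all(got %in% c("photon_dominates", "proton_dominates",
                             "tradeoff")))
})

test_that("cost-effectiveness at a threshold follows the dominance rules", {
  expect_true(is_cost_effective("proton_dominates", NA, 1))
  expect_false(is_cost_effective("tradeoff", 150000, 100000))
  expect_true(is_cost_effective("tradeoff", 150000, 250000))
  expect_true(is_cost_effective("tradeoff", 250000, 250000)) # inclusive
  expect_false(is_cost_effective("photon_dominates", NA, 1e9))
})

test_that("zero-NTCP cohorts are 100% photon-dominant at exactly the upfront difference", {
  cohort <- zero_ntcp_cohort(3)
  res <- run_psa(cohort, analysis_config(n_samples = 200, seed = 4))
  expect_true(all(res$samples$dominance == "photon_dominates"))
  expect_true(all(res$samples$no_difference))
  expect_true(all(res$samples$delta_qaly == 0))
  expect_true(all(res$samples$delta_cost == 16402))
  expect_equal(res$summary$pooled$frac_photon_dominates, 1)
})

test_that("fixed seed reproduces the sample table bit-identically; seed changes it", {
  cohort <- risk_cohort(3)
  cfg <- analysis_config(n_samples = 300, seed = 123)
  a <- run_psa(cohort, cfg)
  b <- run_psa(cohort, cfg)
  expect_identical(a$samples, b$samples)
  c2 <- run_psa(cohort, analysis_config(n_samples = 300, seed = 124))
  expect_false(identical(a$samples, c2$samples))
})

test_that("cohort order does not change per-patient results (substream independence)", {
  cohort <- risk_cohort(4)
  cfg <- analysis_config(n_samples = 200, seed = 9)
  a <- run_psa(cohort, cfg)$samples
  b <- run_psa(cohort[rev(seq_len(nrow(cohort))), ], cfg)$samples
  for (pid in cohort$patient_id) {
    x <- a[a$patient_id == pid, ]
    y <- b[b$patient_id == pid, ]
    rownames(x) <- rownames(y) <- NULL
    expect_identical(x, y)
  }
})

test_that("common random numbers make the QALY difference non-negative (paired design)", {
  cohort <- risk_cohort(4)
  res <- run_psa(cohort, analysis_config(n_samples = 500, seed = 21))
  expect_true(all(res$samples$delta_qaly >= 0))
  # under independent coupling negative differences appear
  res_ind <- run_psa(cohort, analysis_config(n_samples = 500, seed = 21,
                                             event_coupling = "independent"))
  expect_true(any(res_ind$samples$delta_qaly < 0))
})

test_that("equal upfront costs make every differing sample proton-dominant", {
  cohort <- risk_cohort(3)
  cfg <- analysis_config(n_samples = 400, seed = 31)
  cfg$upfront$proton <- cfg$upfront$photon
  res <- run_psa(cohort, cfg)
  s <- res$samples
  expect_true(all(s$dominance[s$delta_qaly > 0] == "proton_dominates"))
  expect_false(any(s$dominance == "tradeoff" & s$delta_cost > 0))
})

test_that("dominance fractions partition the samples for every patient", {
  cohort <- risk_cohort(4)
  res <- run_psa(cohort, analysis_config(n_samples = 300, seed = 2))
  pp <- res$summary$per_patient
  expect_equal(pp$frac_photon_dominates + pp$frac_proton_dominates +
                 pp$frac_tradeoff, rep(1, nrow(pp)))
})

test_that("CEAC is non-decreasing and bounded by the dominance fractions", {
  cohort <- risk_cohort(4)
  res <- run_psa(cohort, analysis_config(n_samples = 500, seed = 14))
  thresholds <- c(1e4, 5e4, 1e5, 2.5e5, 5e5, 1e6)
  curve <- ceac(res$samples, thresholds)
  expect_true(all(diff(curve$prop_cost_effective) >= 0))
  p <- res$summary$pooled
  expect_true(all(curve$prop_cost_effective >= p$frac_proton_dominates))
  expect_true(all(curve$prop_cost_effective <= 1 - p$frac_photon_dominates))
  # threshold proportions in the summary share the monotonicity
  ce <- p$prop_cost_effective
  expect_true(all(diff(ce) >= 0))
})

test_that("pooled median ICER strictly decreases as the proton upfront cost falls", {
  cohort <- generate_cohort(cohort_gen_config(n_patients = 8, seed = 6))
  cfg <- analysis_config(n_samples = 500, seed = 17)
  scen <- one_way_scenarios(cohort, cfg, scenarios = "proton_cost")
  tab <- scen$table
  expect_equal(tab$scenario, c("base_case", rep("proton_cost", 3)))
  costs <- c(36659, tab$value[-1])
  expect_equal(costs, c(36659, 31659, 26659, 21659))
  expect_true(all(diff(tab$median_icer) < 0))
})

test_that("chronicity scenarios only touch dysphagia-dependent output", {
  ntcp <- list(dysphagia = c(0, 0.5), esophagitis = c(0.3, 0.3),
               xerostomia = c(0.4, 0.4), hypothyroidism = c(0.2, 0.2),
               mucositis = c(0.3, 0.3))
  cohort <- make_test_cohort(ntcp)
  cfg <- analysis_config(n_samples = 300, seed = 8)
  scen <- one_way_scenarios(cohort, cfg, scenarios = "dysphagia_chronicity",
                            keep_samples = TRUE)
  expect_equal(nrow(scen$table), 3) # base + 0% + 100%
  base <- scen$runs[[1]]$samples
  for (k in 2:3) {
    alt <- scen$runs[[k]]$samples
    # the patient with zero dysphagia NTCP is untouched by the scenario
    expect_identical(base[base$patient_id == "T01", ],
                     alt[alt$patient_id == "T01", ])
    expect_false(identical(base[base$patient_id == "T02", ],
                           alt[alt$patient_id == "T02", ]))
  }
  # determinism: rerunning a scenario reproduces its summary exactly
  scen2 <- one_way_scenarios(cohort, cfg, scenarios = "dysphagia_chronicity")
  expect_identical(scen$table, scen2$table)
  expect_error(one_way_scenarios(cohort, cfg, scenarios = "discounting"),
               "discounting")
})

test_that("base case and full PSA coincide when every CI collapses to its base value", {
  cohort <- risk_cohort(3)
  cfg_psa <- collapsed_ci_config(n_samples = 250, seed = 77, mode = "full_psa")
  cfg_base <- collapsed_ci_config(n_samples = 250, seed = 77, mode = "base_case")
  a <- run_psa(cohort, cfg_psa)$samples
  b <- run_psa(cohort, cfg_base)$samples
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("engine samples match an independent scalar recomputation (oracle equivalence)", {
  cohort <- risk_cohort(2)
  cfg <- analysis_config(n_samples = 40, seed = 55, mode = "base_case")
  res <- run_psa(cohort, cfg)
  spec <- res$survival_spec
  items <- default_cost_items()
  uspecs <- default_utility_specs()
  u <- sample_utilities(psa = FALSE)
  for (i in seq_len(nrow(cohort))) {
    pat <- as.list(cohort[i, ])
    # replay the documented draw order for this patient's substream
    set.seed(protonCEA:::patient_seed(cfg$seed, pat$patient_id))
    U <- matrix(runif(cfg$n_samples * 5), cfg$n_samples, 5,
                dimnames = list(NULL, complication_names()))
    u_chr <- runif(cfg$n_samples)
    S <- survival_curve(pat, spec, hr_draw = cfg$hr_base)
    rows <- res$samples[res$samples$patient_id == pat$patient_id, ]
    for (k in seq_len(cfg$n_samples)) {
      uu <- list(events = U[k, ], chronic = u_chr[k])
      ev_ph <- sample_events(pat, "photon", u = uu)
      ev_pr <- sample_events(pat, "proton", u = uu)
      q_ph <- compute_qalys(ev_ph, u, S, cfg$discount_rate, uspecs)
      q_pr <- compute_qalys(ev_pr, u, S, cfg$discount_rate, uspecs)
      c_ph <- total_cost("photon", cfg$upfront, ev_ph, items, S,
                         cfg$discount_rate)
      c_pr <- total_cost("proton", cfg$upfront, ev_pr, items, S,
                         cfg$discount_rate)
      expect_equal(rows$qaly_photon[k], q_ph, tolerance = 1e-10)
      expect_equal(rows$qaly_proton[k], q_pr, tolerance = 1e-10)
      expect_equal(rows$cost_photon[k], c_ph, tolerance = 1e-10)
      expect_equal(rows$cost_proton[k], c_pr, tolerance = 1e-10)
    }
  }
})

test_that("summary statistics equal an independent one-pass recomputation", {
  cohort <- risk_cohort(3)
  res <- run_psa(cohort, analysis_config(n_samples = 400, seed = 3))
  s <- res$samples
  p <- res$summary$pooled
  tr <- s$icer[s$dominance == "tradeoff"]
  expect_equal(p$median_icer, unname(stats::median(tr)))
  expect_equal(p$icer_q25, unname(stats::quantile(tr, 0.25)))
  expect_equal(p$icer_q75, unname(stats::quantile(tr, 0.75)))
  expect_equal(p$frac_photon_dominates,
               sum(s$dominance == "photon_dominates") / nrow(s))
  expect_equal(unname(p$prop_cost_effective[2]),
               mean(s$dominance == "proton_dominates" |
                      (!is.na(s$icer) & s$icer <= 250000)))
  expect_equal(p$icer_ratio_of_means,
               mean(s$delta_cost) / mean(s$delta_qaly))
})

test_that("additive utility combination and bernoulli management run and stay coherent", {
  cohort <- risk_cohort(2)
  res_add <- run_psa(cohort, analysis_config(n_samples = 150, seed = 12,
                                             utility_combination = "additive"))
  expect_true(all(res_add$samples$delta_qaly >= 0))
  res_bern <- run_psa(cohort, analysis_config(n_samples = 150, seed = 12,
                                              management_mode = "bernoulli"))
  expect_true(all(is.finite(res_bern$samples$cost_photon)))
  # bernoulli management realizes whole item costs, never fractional weights
  s <- res_bern$samples
  expect_true(all(s$cost_photon >= 20257))
})
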