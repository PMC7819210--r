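# cost model: upfront radiotherapy cost + complication-management bundles
#
# Per sample and modality:
#   Cost_total = Cost_RT + sum_i Cost_management_i * Event_i * P_management_i
# where P_management is applied as a multiplicative expected-cost weight
# within the sample (PSA uncertainty enters by sampling the proportions
# themselves); a Bernoulli-management mode draws the management event
# instead. Lifelong items (Levothyroxine, chronic PEG tube) are annuities
# over the patient's remaining discounted survival. All amounts are 2018
# US dollars.

#' Default complication-management cost items
#'
#' One row per management/procedure item: the complication it applies to,
#' the 2018 USD amount, recurrence (`one_time` or `per_year`), the
#' proportion of cases in which the management is employed, optional 95%
#' CIs for the proportion and the amount (sampled in full PSA), and for
#' recurring items the duration rule (`lifelong`, or `dysphagia_rule`:
#' lifelong when the sample's dysphagia is chronic, otherwise capped at
#' 5 years, mirroring the dysphagia health-state duration).
#'
#' The grade >= 3 mucositis/esophagitis bundle: Fentanyl patch $168.8,
#' Percocet $1514.1, mucositis cocktail $37.0 (6 weeks each), weekly IV
#' hydration $154.2 (4 weeks), PEG tube placement $5686 in 30% of cases,
#' emergency room visit $2096 (15% mucositis / 10% esophagitis),
#' inpatient hospitalization $19,672 in 10% of cases, one month of lost
#' work $2718. Dysphagia: chronic PEG tube $18,836/year in 10% of cases,
#' stricture dilation $1700 (midpoint of the $1200–$2200 charge range) in
#' 16% of patients. Hypothyroidism: lifelong Levothyroxine $174.2/year.
#' Xerostomia: Pilocarpine $231 (10 weeks) and Cevimeline $251.4 (6 weeks).
#'
#' @return Data.frame with columns `complication`, `label`, `amount`,
#'   `recurrence`, `duration`, `proportion`, `prop_ci_low`, `prop_ci_high`,
#'   `amount_ci_low`, `amount_ci_high`.
#' @export
default_cost_items <- function() {
  item <- function(complication, label, amount, recurrence = "one_time",
                   duration = NA_character_, proportion = 1,
                   prop_ci = c(NA, NA), amount_ci = c(NA, NA),
                   param_group = NA_character_) {
    data.frame(complication = complication, label = label, amount = amount,
               recurrence = recurrence, duration = duration,
               proportion = proportion,
               prop_ci_low = prop_ci[1], prop_ci_high = prop_ci[2],
               amount_ci_low = amount_ci[1], amount_ci_high = amount_ci[2],
               # uncertain proportions sharing a param_group are one PSA
               # parameter: hospital admission is a single proportion for
               # mucositis-or-esophagitis; the ER proportions are distinct
               param_group = if (is.na(param_group))
                 paste(complication, label, sep = ":") else param_group,
               stringsAsFactors = FALSE)
  }
  acute_bundle <- function(comp, er_prop, er_ci) rbind(
    item(comp, "fentanyl_patch_6wk", 168.8),
    item(comp, "percocet_6wk", 1514.1),
    item(comp, "mucositis_cocktail_6wk", 37.0),
    item(comp, "iv_hydration_4wk", 154.2),
    item(comp, "peg_tube_placement", 5686, proportion = 0.30),
    item(comp, "emergency_room_visit", 2096, proportion = er_prop,
         prop_ci = er_ci),
    item(comp, "inpatient_hospitalization", 19672, proportion = 0.10,
         prop_ci = c(0, 0.20), param_group = "inpatient_hospitalization"),
    item(comp, "lost_work_1mo", 2718)
  )
  rbind(
    acute_bundle("mucositis", 0.15, c(0.05, 0.25)),
    acute_bundle("esophagitis", 0.10, c(0, 0.20)),
    item("dysphagia", "chronic_peg_tube", 18836, recurrence = "per_year",
         duration = "dysphagia_rule", proportion = 0.10,
         prop_ci = c(0, 0.20)),
    item("dysphagia", "stricture_dilation", 1700, proportion = 0.16,
         prop_ci = c(0.11, 0.21), amount_ci = c(1200, 2200)),
    item("hypothyroidism", "levothyroxine", 174.2, recurrence = "per_year",
         duration = "lifelong"),
    item("xerostomia", "pilocarpine_10wk", 231),
    item("xerostomia", "cevimeline_6wk", 251.4)
  )
}

validate_cost_items <- function(items) {
  need <- c("complication", "label", "amount", "recurrence", "duration",
            "proportion", "prop_ci_low", "prop_ci_high",
            "amount_ci_low", "amount_ci_high")
  if (!all(need %in% names(items))) {
    stop_config("cost items must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(items$param_group)) {
    items$param_group <- paste(items$complication, items$label, sep = ":")
  }
  bad <- setdiff(items$complication, .COMPLICATIONS)
  if (length(bad)) {
    stop_config("cost items reference unknown complication(s): %s",
                paste(bad, collapse = ", "))
  }
  if (any(items$amount < 0)) stop_config("cost item amounts must be >= 0")
  check_probability(items$proportion, "cost item proportions")
  if (any(!items$recurrence %in% c("one_time", "per_year"))) {
    stop_config("cost item recurrence must be one_time|per_year")
  }
  invisible(items)
}

#' Default upfront radiotherapy costs (33 fractions)
#'
#' Upfront costs for a 33-fraction course: the quoted Medicare
#' reimbursements of $18,415 for 30 fractions of complex IMRT and $27,772
#' for 25 fractions of complex proton therapy, extrapolated linearly per
#' fraction to $20,257 (photon) and $36,659 (proton).
#'
#' @param target_fractions Fraction count of the course (default 33).
#' @return List with `photon`, `proton` (dollars at `target_fractions`)
#'   and the quoted sources.
#' @export
default_upfront_costs <- function(target_fractions = 33L) {
  list(
    photon = extrapolate_upfront(18415, 30, target_fractions),
    proton = extrapolate_upfront(27772, 25, target_fractions),
    quoted_photon = 18415, quoted_photon_fractions = 30L,
    quoted_proton = 27772, quoted_proton_fractions = 25L,
    target_fractions = as.integer(target_fractions)
  )
}

#' Extrapolate an upfront cost to a different fraction count
#'
#' Linear per-fraction scaling, rounded to the nearest dollar (halves
#' round up, the convention of the quoted amounts).
#'
#' @param cost Quoted cost in dollars.
#' @param quoted_fractions Fraction count the quote covers.
#' @param target_fractions Fraction count to scale to.
#' @return Dollars (integer-valued numeric).
#' @export
#' @examples
#' extrapolate_upfront(18415, 30, 33) # 20257
#' extrapolate_upfront(27772, 25, 33) # 36659
extrapolate_upfront <- function(cost, quoted_fractions, target_fractions) {
  if (quoted_fractions <= 0 || target_fractions <= 0) {
    stop_config("fraction counts must be > 0")
  }
  floor(cost * target_fractions / quoted_fractions + 0.5)
}

#' Management cost of one complication in one sampled case
#'
#' Sums the complication's cost items per the expected-cost reading of the
#' management proportions: one-time items contribute
#' `amount * proportion`; per-year items contribute
#' `amount * proportion * annuity`, where the annuity is the discounted
#' remaining survival ([discounted_life_years()]) for `lifelong` items and,
#' for the chronic-PEG `dysphagia_rule` item, the discounted survival over
#' the first 5 years when the sample's dysphagia is not chronic. PSA mode
#' substitutes sampled proportions/amounts via `sampled`.
#'
#' @param complication Complication name.
#' @param events Event list from [sample_events()].
#' @param items Cost item table ([default_cost_items()]).
#' @param S Survival sequence.
#' @param discount_rate Annual discount rate.
#' @param sampled Optional named list overriding `proportion` and/or
#'   `amount` by item label (as produced by the PSA engine).
#' @return Dollars (0 when the complication did not occur).
#' @export
management_cost <- function(complication, events, items, S,
                            discount_rate = 0.03, sampled = NULL) {
  validate_cost_items(items)
  if (!complication %in% .COMPLICATIONS) {
    stop_config("unknown complication '%s'", complication)
  }
  ev <- if (is.list(events)) events$events else events
  if (!isTRUE(ev[[complication]])) return(0)
  dys_chronic <- is.list(events) && isTRUE(events$dysphagia_chronic)
  rows <- items[items$complication == complication, , drop = FALSE]
  dly_full <- discounted_life_years(S, discount_rate)
  dly_5yr <- discounted_life_years(S[seq_len(min(5L, length(S)))], discount_rate)
  total <- 0
  for (i in seq_len(nrow(rows))) {
    amount <- rows$amount[i]
    prop <- rows$proportion[i]
    ov <- sampled[[rows$label[i]]]
    if (!is.null(ov)) {
      amount <- ov$amount %||% amount
      prop <- ov$proportion %||% prop
    }
    contrib <- amount * prop
    if (rows$recurrence[i] == "per_year") {
      annuity <- if (identical(rows$duration[i], "dysphagia_rule") && !dys_chronic)
        dly_5yr else dly_full
      contrib <- contrib * annuity
    }
    total <- total + contrib
  }
  total
}

#' Total cost of one modality in one sampled case
#'
#' Upfront radiotherapy cost plus the sum of [management_cost()] over the
#' five complications; equals the upfront cost exactly when no
#' complication occurred.
#'
#' @param modality `"photon"` or `"proton"`.
#' @param upfront Upfront cost list ([default_upfront_costs()]); the
#'   modality's entry is used.
#' @param events,items,S,discount_rate,sampled As in [management_cost()].
#' @return Dollars.
#' @export
#' @examples
#' S <- rep(1, 5)
#' ev <- list(events = setNames(rep(FALSE, 5), complication_names()),
#'            dysphagia_chronic = FALSE)
#' total_cost("photon", default_upfront_costs(), ev,
#'            default_cost_items(), S, 0.03) # 20257
total_cost <- function(modality, upfront, events, items, S,
                       discount_rate = 0.03, sampled = NULL) {
  if (!modality %in% .MODALITIES) {
    stop_config("unknown modality '%s' (use photon|proton)", modality)
  }
  base <- upfront[[modality]]
  mgmt <- vapply(.COMPLICATIONS, function(comp)
    management_cost(comp, events, items, S, discount_rate, sampled),
    numeric(1))
  base + sum(mgmt)
}
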