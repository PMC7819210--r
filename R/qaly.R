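# QALY model: complication events -> discounted quality-adjusted life years
#
# Health-state conventions (documented design choices):
#   * acute states (oral mucositis, esophagitis) occupy their duration in
#     year 1, undiscounted under the year-1 convention;
#   * chronic-lifelong states (xerostomia, hypothyroidism) occupy every
#     surviving year;
#   * dysphagia is mixed: a per-sample chronic flag decides lifelong vs
#     resolved within 5 years (base case 50/50);
#   * concurrent states combine multiplicatively on the utility scale
#     (an additive-decrement mode is available via `combination`).

#' Default utility (quality-adjustment factor) specifications
#'
#' One row per complication: the base-case utility multiplier applied to
#' time spent in the health state (1 = perfect health), its 95% CI (used
#' to fit beta distributions for PSA), and the duration rule. The oral
#' mucositis factor (0.06, CI 0.01–0.15) is far below the others; it is
#' applied literally as a utility multiplier over its 6-week acute window.
#' Readers preferring to interpret it as a disutility decrement can supply
#' an edited spec table — the engine only reads this table.
#'
#' Duration rules: `acute` with `acute_weeks` weeks in year 1;
#' `chronic_lifelong`; `mixed_chronic_or_5yr` (dysphagia — per-sample
#' chronic flag, chronic proportion set in the analysis config).
#'
#' @return Data.frame with columns `complication`, `utility`, `ci_low`,
#'   `ci_high`, `rule`, `acute_weeks`.
#' @export
default_utility_specs <- function() {
  data.frame(
    complication = .COMPLICATIONS,
    utility = c(0.83, 0.66, 0.82, 0.97, 0.06),
    ci_low  = c(0.70, 0.35, 0.72, 0.94, 0.01),
    ci_high = c(0.93, 0.90, 0.90, 0.98, 0.15),
    rule = c("mixed_chronic_or_5yr", "acute", "chronic_lifelong",
             "chronic_lifelong", "acute"),
    acute_weeks = c(NA, 6, NA, NA, 6),
    stringsAsFactors = FALSE
  )
}

validate_utility_specs <- function(specs) {
  need <- c("complication", "utility", "ci_low", "ci_high", "rule", "acute_weeks")
  if (!all(need %in% names(specs))) {
    stop_config("utility specs must have columns %s", paste(need, collapse = ", "))
  }
  if (!setequal(specs$complication, .COMPLICATIONS)) {
    stop_config("utility specs must cover exactly the five modeled complications")
  }
  ok <- specs$ci_low <= specs$utility & specs$utility <= specs$ci_high &
    specs$ci_low >= 0 & specs$ci_high <= 1
  if (any(!ok)) {
    stop_config("utility spec for '%s' violates 0 <= low <= base <= high <= 1",
                specs$complication[which(!ok)[1]])
  }
  invisible(specs)
}

#' Draw complication events for one patient and modality
#'
#' Each complication occurs as an independent Bernoulli draw at the
#' modality's NTCP. Under the default common-random-numbers coupling the
#' *same* uniform is compared against the photon and proton NTCP, so when
#' proton NTCP <= photon NTCP the proton events are a subset of the photon
#' events within a sample (a paired comparison); pass `u` to share draws
#' across modalities. The dysphagia `chronic` flag is a separate
#' Bernoulli(`chronic_prop`) draw.
#'
#' @param patient One cohort row.
#' @param modality `"photon"` or `"proton"`.
#' @param chronic_prop Proportion of dysphagia cases that are chronic
#'   (default 0.5).
#' @param u Optional list of shared uniforms: `events` (named, one per
#'   complication) and `chronic` (scalar); drawn fresh if omitted.
#' @return Named list: logical `events` (five complications),
#'   logical `dysphagia_chronic`.
#' @export
sample_events <- function(patient, modality, chronic_prop = 0.5, u = NULL) {
  if (!modality %in% .MODALITIES) {
    stop_config("unknown modality '%s' (use photon|proton)", modality)
  }
  if (is.null(u)) {
    u <- list(events = stats::setNames(stats::runif(5), .COMPLICATIONS),
              chronic = stats::runif(1))
  }
  ntcp <- vapply(.COMPLICATIONS,
                 function(comp) patient[[paste0(comp, "_", modality)]],
                 numeric(1))
  check_probability(ntcp, paste0("ntcp_", modality))
  list(events = u$events[.COMPLICATIONS] < ntcp,
       dysphagia_chronic = u$chronic < chronic_prop)
}

#' Draw utility values for all complications
#'
#' In PSA mode each utility is drawn from the beta distribution fitted to
#' its 95% CI ([fit_beta_from_ci()]); in base-case mode the base utilities
#' are returned exactly. Degenerate CIs (low == high) give a constant.
#'
#' @param specs Utility spec table ([default_utility_specs()]).
#' @param psa Draw from fitted betas (`TRUE`) or return base values.
#' @param n Number of draws per complication.
#' @return If `n == 1`, a named numeric vector; else an `n x 5` matrix with
#'   complication columns.
#' @export
sample_utilities <- function(specs = default_utility_specs(), psa = TRUE, n = 1L) {
  validate_utility_specs(specs)
  specs <- specs[match(.COMPLICATIONS, specs$complication), ]
  out <- matrix(rep(specs$utility, each = n), nrow = n,
                dimnames = list(NULL, .COMPLICATIONS))
  if (psa) {
    for (i in seq_along(.COMPLICATIONS)) {
      u <- stats::runif(n)
      if (specs$ci_low[i] == specs$ci_high[i]) {
        out[, i] <- specs$ci_low[i]
      } else {
        sh <- fit_beta_from_ci(specs$ci_low[i], specs$ci_high[i])
        out[, i] <- stats::qbeta(u, sh[1], sh[2])
      }
    }
  }
  if (n == 1L) out[1, ] else out
}

# year-1 multiplier for the acute states: partition the (sorted) acute
# durations into segments; within each segment the utilities of all still-
# active acute states multiply. Returns a value in (0, 1].
acute_year1_multiplier <- function(durations_weeks, utilities) {
  if (!length(durations_weeks)) return(1)
  frac <- durations_weeks / 52
  ord <- order(frac)
  frac <- frac[ord]; utilities <- utilities[ord]
  bounds <- c(0, frac)
  m <- 1 - frac[length(frac)]          # complication-free remainder of year 1
  for (k in seq_along(frac)) {
    seg <- bounds[k + 1] - bounds[k]
    m <- m + seg * prod(utilities[k:length(frac)])
  }
  m
}

#' Discounted quality-adjusted life years for one sampled case
#'
#' Starts from the discounted life expectancy of the survival sequence and
#' applies, for every complication that occurred, the utility multiplier
#' over the time spent in the health state: acute states occupy their
#' duration in year 1 (undiscounted), chronic-lifelong states every
#' surviving year, and dysphagia either every year (chronic) or years 1–5
#' (resolved within 5 years). Concurrent states multiply on the utility
#' scale by default; `combination = "additive"` subtracts utility
#' decrements instead (floored at utility 0 per year).
#'
#' @param events Event list from [sample_events()] (or a named logical
#'   vector of the five complications, with attribute-free chronic flag
#'   passed via the list form).
#' @param utilities Named utility vector (see [sample_utilities()]).
#' @param S Survival sequence from [survival_curve()].
#' @param discount_rate Annual discount rate (default 0.03).
#' @param specs Utility/duration spec table.
#' @param combination `"multiplicative"` (default) or `"additive"`.
#' @return QALYs in `[0, discounted_life_years(S, discount_rate)]`.
#' @export
#' @examples
#' S <- rep(1, 5)
#' ev <- list(events = c(dysphagia = FALSE, esophagitis = FALSE,
#'                       xerostomia = FALSE, hypothyroidism = TRUE,
#'                       mucositis = FALSE), dysphagia_chronic = FALSE)
#' u <- sample_utilities(psa = FALSE)
#' compute_qalys(ev, u, S, 0) # 0.97 * 5
compute_qalys <- function(events, utilities, S, discount_rate = 0.03,
                          specs = default_utility_specs(),
                          combination = c("multiplicative", "additive")) {
  combination <- match.arg(combination)
  if (is.list(events)) {
    ev <- events$events
    dys_chronic <- isTRUE(events$dysphagia_chronic)
  } else {
    ev <- events
    dys_chronic <- FALSE
  }
  ev <- ev[.COMPLICATIONS]
  utilities <- utilities[.COMPLICATIONS]
  check_probability(utilities, "utilities")
  validate_utility_specs(specs)
  specs <- specs[match(.COMPLICATIONS, specs$complication), ]
  H <- length(S)
  w <- (1 + discount_rate)^-(seq_len(H) - 1)
  if (discount_rate < 0) stop_config("'discount_rate' must be >= 0")

  # per-year utility factor from chronic-type states
  U <- matrix(1, nrow = H, ncol = 1)[, 1]
  combine <- function(U, u, years) {
    if (combination == "multiplicative") U[years] <- U[years] * u
    else U[years] <- pmax(U[years] - (1 - u), 0)
    U
  }
  for (i in seq_along(.COMPLICATIONS)) {
    comp <- .COMPLICATIONS[i]
    if (!isTRUE(ev[[comp]])) next
    rule <- specs$rule[i]
    if (rule == "chronic_lifelong") {
      U <- combine(U, utilities[[comp]], seq_len(H))
    } else if (rule == "mixed_chronic_or_5yr") {
      years <- if (dys_chronic) seq_len(H) else seq_len(min(5L, H))
      U <- combine(U, utilities[[comp]], years)
    }
  }
  qaly <- sum(w * S * U)

  # acute states: fraction of year 1, multiplying on top of U[1]
  acute_idx <- which(specs$rule == "acute" & as.logical(ev))
  if (length(acute_idx)) {
    m <- acute_year1_multiplier(specs$acute_weeks[acute_idx],
                                utilities[acute_idx])
    if (combination == "additive") {
      # additive decrement over the same acute occupancy
      loss <- sum((specs$acute_weeks[acute_idx] / 52) *
                    (1 - utilities[acute_idx]))
      qaly <- max(qaly - S[1] * min(loss, U[1]), 0)
    } else {
      qaly <- qaly + S[1] * U[1] * (m - 1)
    }
  }
  qaly
}
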