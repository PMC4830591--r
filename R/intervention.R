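# Intervention model: a price subsidy raises F-PIC consumption, which shifts
# the hemoglobin distribution of covered children to the right and reduces
# the prevalence of severe and moderate IDA (mild IDA may increase, as
# children move from moderate into the mild band faster than they leave it).

#' Define a subsidy scenario
#'
#' A scenario is either a fractional price discount or free distribution of
#' the full daily dose (50 g/day), applied to all wealth deciles up to
#' `highest_eligible_decile`.
#'
#' @param highest_eligible_decile eligibility extends to deciles
#'   `1..highest_eligible_decile`.
#' @param discount fractional price discount in `(0, 1)`, or `NULL` for the
#'   free-distribution scenario.
#' @param free_50g if `TRUE`, current- and potential-buyer children receive
#'   50 g/day for free (mutually exclusive with `discount`).
#' @param reference_sachet_price undiscounted sachet price, INR per 25 g.
#' @param full_dose_effect hemoglobin gain (g/l) of the full daily dose.
#' @param full_dose_qty full daily dose, g/day.
#' @return an object of class `intervention_scenario`.
#' @export
intervention_scenario <- function(highest_eligible_decile,
                                  discount = NULL,
                                  free_50g = FALSE,
                                  reference_sachet_price = 14,
                                  full_dose_effect = 8.7,
                                  full_dose_qty = 50) {
  if (!(highest_eligible_decile %in% 1:10)) {
    stop_domain("highest_eligible_decile must be in 1..10")
  }
  if (free_50g && !is.null(discount)) {
    stop_config("discount and free_50g are mutually exclusive")
  }
  if (!free_50g) {
    if (is.null(discount)) stop_config("either discount or free_50g must be given")
    if (discount < 0 || discount >= 1) stop_domain("discount must be in [0, 1)")
  }
  if (full_dose_qty <= 0) stop_config("full_dose_qty must be positive")
  if (reference_sachet_price <= 0) stop_config("reference_sachet_price must be positive")
  structure(list(highest_eligible_decile = as.integer(highest_eligible_decile),
                 discount = if (free_50g) NA_real_ else discount,
                 free_50g = free_50g,
                 reference_sachet_price = reference_sachet_price,
                 full_dose_effect = full_dose_effect,
                 full_dose_qty = full_dose_qty),
            class = "intervention_scenario")
}

scenario_label <- function(scenario) {
  if (scenario$free_50g) "50g/d for free"
  else sprintf("%d%% discount", round(100 * scenario$discount))
}

#' Hemoglobin shift from additional F-PIC intake
#'
#' The full daily dose (`full_dose_qty`, default 50 g/day) raises mean
#' hemoglobin by `full_dose_effect` (default 8.7 g/l); smaller increments
#' act proportionally and the benefit saturates at the full dose (additional
#' intake above it yields no further hemoglobin gain).
#'
#' @param delta_qty_daily additional intake, g/day (non-negative).
#' @param full_dose_qty saturating dose, g/day.
#' @param full_dose_effect hemoglobin gain at the full dose, g/l.
#' @return hemoglobin shift in g/l, in `[0, full_dose_effect]`.
#' @export
hb_shift <- function(delta_qty_daily, full_dose_qty = 50, full_dose_effect = 8.7) {
  if (any(delta_qty_daily < 0)) stop_domain("additional daily quantity must be non-negative")
  if (full_dose_qty <= 0) stop_domain("full_dose_qty must be positive")
  full_dose_effect * pmin(delta_qty_daily, full_dose_qty) / full_dose_qty
}

#' Post-intervention severity prevalences for one decile
#'
#' Each buyer class's hemoglobin distribution is the decile's calibrated
#' Gaussian shifted right by the class's hemoglobin gain; the decile-level
#' prevalence is the buyer-class-share-weighted mixture of the shifted
#' distributions (non-buyers are never shifted).
#'
#' @param profile one row of a calibrated profile table (with `hb_mean`,
#'   `hb_sd` and `share_*` columns).
#' @param shift_by_class named numeric vector of hemoglobin gains (g/l) with
#'   entries `current`, `potential`, `non` (missing entries default to 0).
#' @param thresholds severity thresholds.
#' @return named vector `c(severe, moderate, mild, none)`; sums to 1.
#' @export
shifted_prevalence <- function(profile, shift_by_class,
                               thresholds = default_burden_params()$hb_thresholds) {
  if (is.null(profile$hb_mean) || is.null(profile$hb_sd) ||
      is.na(profile$hb_mean) || is.na(profile$hb_sd)) {
    stop_state("profile is not calibrated: run calibrate_profiles() first")
  }
  if (any(shift_by_class < 0)) stop_domain("hemoglobin shifts must be non-negative")
  shifts <- c(current = 0, potential = 0, non = 0)
  shifts[names(shift_by_class)] <- shift_by_class
  if (shifts[["non"]] != 0) {
    stop_domain("non-buyers receive no intervention and cannot be shifted")
  }
  shares <- c(current = profile$share_current,
              potential = profile$share_potential,
              non = profile$share_non)
  out <- c(severe = 0, moderate = 0, mild = 0, none = 0)
  for (cls in names(shares)) {
    out <- out + shares[[cls]] *
      gaussian_categories(profile$hb_mean + shifts[[cls]], profile$hb_sd, thresholds)
  }
  out
}

#' Run one intervention scenario through the burden model
#'
#' Pipeline for a single scenario: the subsidy's per-decile demand responses
#' (weekly grams, via [demand_response()] in linear average-marginal-effect
#' mode) are converted to g/day, mapped to hemoglobin shifts with
#' [hb_shift()], applied per buyer class with [shifted_prevalence()], and the
#' burden model is evaluated before (zero shift) and after.  The free
#' scenario sets the increment to the full 50 g/day for current and potential
#' buyers.  Both the before and the after prevalences are the ones implied by
#' the calibrated Gaussian distributions, so the averted burden is exactly
#' zero at zero discount.
#'
#' @param scenario an [intervention_scenario()].
#' @param profiles calibrated profile table ([calibrate_profiles()]).
#' @param fits list with [demand_fit()] elements `current` and `potential`.
#' @param params calibrated `burden_params` ([calibrate_costs()]).
#' @param full_compliance if `TRUE`, all children including non-buyers
#'   receive the intervention (upper-bound scenario).
#' @param mode response mode passed to [demand_response()].
#' @return an object of class `shift_result`: list with `by_decile` (demand
#'   increments in g/week and g/day per class, hemoglobin shifts, post
#'   prevalences), `dalys_averted`, `losses_averted` (million USD),
#'   `pct_dalys_averted` (percent of total cohort DALYs), and the
#'   `burden_before`/`burden_after` results.
#' @export
run_scenario <- function(scenario, profiles, fits, params,
                         full_compliance = FALSE, mode = "linear") {
  if (!inherits(scenario, "intervention_scenario")) {
    stop_config("'scenario' must be an intervention_scenario")
  }
  if (is.null(profiles$hb_mean)) {
    stop_state("profiles are not calibrated: run calibrate_profiles() first")
  }
  dem <- scenario_demand(scenario, profiles, fits, mode = mode)
  thresholds <- params$hb_thresholds

  shift_cur <- hb_shift(dem$dq_day_current, scenario$full_dose_qty,
                        scenario$full_dose_effect)
  shift_pot <- hb_shift(dem$dq_day_potential, scenario$full_dose_qty,
                        scenario$full_dose_effect)

  prev_before <- prev_after <- matrix(NA_real_, nrow(profiles), 3,
                                      dimnames = list(NULL, c("severe", "moderate", "mild")))
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    before <- shifted_prevalence(p, c(current = 0, potential = 0), thresholds)
    if (full_compliance) {
      # every child (non-buyers included) receives the class-independent dose
      after <- gaussian_categories(p$hb_mean + shift_cur[i], p$hb_sd, thresholds)
    } else {
      after <- shifted_prevalence(p, c(current = shift_cur[i],
                                       potential = shift_pot[i]), thresholds)
    }
    prev_before[i, ] <- before[c("severe", "moderate", "mild")]
    prev_after[i, ] <- after[c("severe", "moderate", "mild")]
  }

  prof_before <- prof_after <- profiles
  prof_before[, c("prev_severe", "prev_moderate", "prev_mild")] <- prev_before
  prof_after[, c("prev_severe", "prev_moderate", "prev_mild")] <- prev_after

  burden_before <- compute_burden(prof_before, params)
  burden_after <- compute_burden(prof_after, params)

  dalys_averted <- burden_before$totals$dalys_total - burden_after$totals$dalys_total
  losses_averted <- burden_before$totals$losses_total - burden_after$totals$losses_total

  by_decile <- cbind(dem,
                     hb_shift_current = shift_cur,
                     hb_shift_potential = shift_pot,
                     post_severe = prev_after[, "severe"],
                     post_moderate = prev_after[, "moderate"],
                     post_mild = prev_after[, "mild"])

  structure(list(scenario = scenario,
                 by_decile = by_decile,
                 dalys_averted = dalys_averted,
                 losses_averted = losses_averted,
                 pct_dalys_averted = 100 * dalys_averted / burden_before$totals$dalys_total,
                 burden_before = burden_before,
                 burden_after = burden_after),
            class = "shift_result")
}

# Per-decile weekly/daily demand increments of a scenario, zero for
# ineligible deciles.  Used by both run_scenario() and subsidy_cost().
scenario_demand <- function(scenario, profiles, fits, mode = "linear") {
  eligible <- profiles$decile <= scenario$highest_eligible_decile
  ref_price <- scenario$reference_sachet_price / (GRAMS_PER_SACHET / 10)
  n <- nrow(profiles)
  dq_week_cur <- dq_week_pot <- numeric(n)

  if (scenario$free_50g) {
    dq_week_cur[eligible] <- scenario$full_dose_qty * 7
    dq_week_pot[eligible] <- scenario$full_dose_qty * 7
  } else if (scenario$discount > 0) {
    if (!all(c("current", "potential") %in% names(fits))) {
      stop_config("fits must be a list with elements 'current' and 'potential'")
    }
    for (i in which(eligible)) {
      d <- profiles$decile[i]
      dq_week_cur[i] <- demand_response(fits$current, d, scenario$discount,
                                        ref_price,
                                        baseline_qty = profiles$baseline_qty[i],
                                        mode = mode)
      dq_week_pot[i] <- demand_response(fits$potential, d, scenario$discount,
                                        ref_price, baseline_qty = 0,
                                        mode = mode)
    }
  }
  data.frame(decile = profiles$decile,
             eligible = eligible,
             dq_week_current = dq_week_cur,
             dq_week_potential = dq_week_pot,
             dq_day_current = dq_week_cur / 7,
             dq_day_potential = dq_week_pot / 7)
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("Scenario: %s, eligible up to decile %d\n",
              scenario_label(x$scenario), x$scenario$highest_eligible_decile))
  cat(sprintf("  DALYs averted:  %10.0f (%.1f%% of cohort total)\n",
              x$dalys_averted, x$pct_dalys_averted))
  cat(sprintf("  losses averted: %10.1f m USD\n", x$losses_averted))
  invisible(x)
}
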