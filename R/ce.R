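# Cost-effectiveness accounting.
#
# The provider pays the price cut on every gram sold at the discounted
# price: for current buyers this includes the baseline quantity they would
# have bought anyway (the windfall gain), for potential buyers only the
# newly induced quantity.  Net social cost subtracts the production losses
# averted; both are divided by the DALYs averted.

#' Provider cost of a subsidy scenario
#'
#' Per eligible decile, with `n_d` cohort children mapped 1:1 to surveyed
#' households: current-buyer children are subsidized on their entire
#' post-subsidy weekly quantity (baseline + increment); potential-buyer
#' children only on their induced quantity; non-buyers cost nothing.  The
#' subsidy per gram is `discount * price_per_gram` with the price per gram
#' taken from the undiscounted sachet price.  The free scenario pays the
#' full price on 350 g/week for current- and potential-buyer children.
#' Costs accrue over `duration_weeks` (default 78 weeks, ages 6-23 months)
#' and are converted INR to USD at `fx_rate`.
#'
#' @param scenario an [intervention_scenario()].
#' @param profiles SES profile table.
#' @param fits demand fits (list with `current`, `potential`).
#' @param fx_rate INR per USD.
#' @param duration_weeks subsidized weeks per child.
#' @param cohort_size cohort children mapped to the profile shares.
#' @param mode response mode passed to [demand_response()].
#' @return cost in million USD.
#' @export
subsidy_cost <- function(scenario, profiles, fits, fx_rate = 60,
                         duration_weeks = 78,
                         cohort_size = default_burden_params()$cohort_size,
                         mode = "linear") {
  if (fx_rate <= 0) stop_domain("fx_rate must be positive")
  if (duration_weeks <= 0) stop_domain("duration_weeks must be positive")
  dem <- scenario_demand(scenario, profiles, fits, mode = mode)
  n_children <- cohort_size * profiles$cohort_share
  price_per_gram <- scenario$reference_sachet_price / GRAMS_PER_SACHET

  if (scenario$free_50g) {
    covered <- n_children * (profiles$share_current + profiles$share_potential)
    weekly_inr <- covered * price_per_gram * scenario$full_dose_qty * 7
  } else {
    cur <- n_children * profiles$share_current *
      scenario$discount * price_per_gram *
      (profiles$baseline_qty + dem$dq_week_current)
    pot <- n_children * profiles$share_potential *
      scenario$discount * price_per_gram * dem$dq_week_potential
    weekly_inr <- cur + pot
  }
  weekly_inr[!dem$eligible] <- 0
  sum(weekly_inr) * duration_weeks / fx_rate / 1e6
}

#' Net social cost of an intervention
#'
#' Subsidy cost minus the production losses averted by reducing IDA.
#'
#' @param cost_subsidy million USD.
#' @param losses_averted million USD.
#' @return million USD (negative when the intervention is cost saving).
#' @export
net_social_cost <- function(cost_subsidy, losses_averted) {
  cost_subsidy - losses_averted
}

#' Cost-effectiveness ratios
#'
#' Provider perspective: subsidy cost per DALY averted.  Social perspective:
#' net social cost (subsidy minus production losses averted) per DALY
#' averted.
#'
#' @param cost_subsidy,losses_averted million USD.
#' @param dalys_averted DALYs (must be positive for defined ratios).
#' @return named list `ratio_provider`, `ratio_social` (USD per DALY) and
#'   `defined` (`FALSE`, with `NA` ratios, when `dalys_averted <= 0`).
#' @export
ce_ratios <- function(cost_subsidy, losses_averted, dalys_averted) {
  if (is.na(dalys_averted) || dalys_averted <= 0) {
    return(list(ratio_provider = NA_real_, ratio_social = NA_real_,
                defined = FALSE))
  }
  list(ratio_provider = cost_subsidy * 1e6 / dalys_averted,
       ratio_social = net_social_cost(cost_subsidy, losses_averted) * 1e6 / dalys_averted,
       defined = TRUE)
}

#' WHO cost-effectiveness classification
#'
#' An intervention is *cost saving* if its net social cost is negative;
#' otherwise it is classified by the provider ratio against GDP per capita:
#' *highly cost-effective* below 1x GDP, *cost-effective* below 3x GDP,
#' *not cost-effective* above.
#'
#' @param ratio_provider,ratio_social USD per DALY averted.
#' @param gdp_per_capita USD (default 1487, India 2013).
#' @return one of `"cost_saving"`, `"highly_cost_effective"`,
#'   `"cost_effective"`, `"not_cost_effective"` (`NA` for undefined ratios).
#' @export
who_classify <- function(ratio_provider, ratio_social, gdp_per_capita = 1487) {
  if (gdp_per_capita <= 0) stop_domain("gdp_per_capita must be positive")
  if (is.na(ratio_provider) || is.na(ratio_social)) return(NA_character_)
  if (ratio_social < 0) return("cost_saving")
  if (ratio_provider < gdp_per_capita) return("highly_cost_effective")
  if (ratio_provider < 3 * gdp_per_capita) return("cost_effective")
  "not_cost_effective"
}

#' Default scenario grid
#'
#' @param discounts fractional discounts.
#' @param eligibility highest eligible deciles.
#' @param free include the free-distribution scenario per eligibility level.
#' @return list of [intervention_scenario()] objects.
#' @export
default_scenarios <- function(discounts = c(0.2, 0.5, 0.8),
                              eligibility = c(2, 4, 6, 8, 10),
                              free = TRUE) {
  out <- list()
  for (k in eligibility) {
    for (disc in discounts) {
      out[[length(out) + 1]] <- intervention_scenario(k, discount = disc)
    }
    if (free) out[[length(out) + 1]] <- intervention_scenario(k, free_50g = TRUE)
  }
  out
}

#' Evaluate a grid of subsidy scenarios
#'
#' Runs every scenario through the intervention and cost models and returns
#' one row per scenario with the components of the cost-effectiveness
#' calculation: eligibility, intervention, provider cost, production losses
#' averted, DALYs averted, provider cost per DALY, net social cost per DALY,
#' and the WHO classification.  Duplicate scenarios are dropped with a
#' warning.
#'
#' @param scenarios list of [intervention_scenario()] objects.
#' @param profiles calibrated profile table.
#' @param fits demand fits (list with `current`, `potential`).
#' @param params calibrated `burden_params`.
#' @param fx_rate INR per USD.
#' @param duration_weeks subsidized weeks per child.
#' @param gdp_per_capita USD, for the WHO classification.
#' @return data frame of class `ce_grid`.
#' @export
scenario_grid <- function(scenarios, profiles, fits, params,
                          fx_rate = 60, duration_weeks = 78,
                          gdp_per_capita = 1487) {
  if (!length(scenarios)) stop_config("scenario list must be non-empty")
  keys <- vapply(scenarios, function(s) {
    sprintf("%d|%s", s$highest_eligible_decile, scenario_label(s))
  }, character(1))
  if (anyDuplicated(keys)) {
    warning("duplicate scenarios removed from the grid")
    scenarios <- scenarios[!duplicated(keys)]
  }
  rows <- lapply(scenarios, function(s) {
    res <- run_scenario(s, profiles, fits, params)
    cost <- subsidy_cost(s, profiles, fits, fx_rate = fx_rate,
                         duration_weeks = duration_weeks,
                         cohort_size = params$cohort_size)
    ratios <- ce_ratios(cost, res$losses_averted, res$dalys_averted)
    data.frame(eligibility = s$highest_eligible_decile,
               intervention = scenario_label(s),
               cost_musd = cost,
               losses_averted_musd = res$losses_averted,
               dalys_averted = res$dalys_averted,
               pct_dalys_averted = res$pct_dalys_averted,
               ratio_provider = ratios$ratio_provider,
               ratio_social = ratios$ratio_social,
               who_class = who_classify(ratios$ratio_provider,
                                        ratios$ratio_social, gdp_per_capita),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ce_grid", class(out))
  out
}

#' Published cost-effectiveness grid
#'
#' The cost-effectiveness components reported with the original study
#' (intervention cost, production losses averted and DALYs averted per
#' scenario), shipped as reference data so the ratio algebra can be
#' recomputed and cross-checked.
#'
#' @param path file path; defaults to the shipped copy.
#' @return data frame with columns `eligibility` (highest eligible decile),
#'   `intervention`, `cost_musd`, `losses_averted_musd`, `dalys_averted`.
#' @export
reference_ce_grid <- function(path = fpic_extdata("reference_ce_grid.tsv")) {
  read_table_headered(path)
}

#' Read scenario definitions from a config file
#'
#' The file is a TSV with columns `eligibility` (highest eligible decile)
#' and `intervention` (a fractional discount such as `0.5`, or `free`).
#'
#' @param path file path; defaults to the shipped default grid.
#' @return list of [intervention_scenario()] objects.
#' @export
read_scenarios <- function(path = fpic_extdata("scenarios.tsv")) {
  tab <- read_table_headered(path)
  if (!all(c("eligibility", "intervention") %in% names(tab))) {
    stop_config("scenario file must have columns 'eligibility' and 'intervention'")
  }
  lapply(seq_len(nrow(tab)), function(i) {
    iv <- tab$intervention[i]
    if (identical(tolower(as.character(iv)), "free")) {
      intervention_scenario(tab$eligibility[i], free_50g = TRUE)
    } else {
      intervention_scenario(tab$eligibility[i], discount = as.numeric(iv))
    }
  })
}
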