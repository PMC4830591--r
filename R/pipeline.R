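# End-to-end pipeline driver.
#
# Stages run in dependency order: simulate (synthetic survey) -> fit (demand
# estimation) -> burden (calibrated cohort burden) -> scenarios
# (cost-effectiveness grid).  Every output file carries a provenance header
# (package version, seed, configuration hash).

#' Run the pipeline
#'
#' `mode = "all"` executes every stage; the individual modes run one stage
#' against previously written artifacts in `out_dir` and fail with an
#' actionable dependency error when an upstream artifact is missing.
#'
#' Stage outputs in `out_dir`:
#' * `survey.tsv` — synthetic household panel ([generate_survey()]);
#' * `demand_fits.tsv` — first-difference estimates for both buyer classes
#'   plus marginal effects and exclusion counts;
#' * `burden_by_decile.tsv`, `burden_totals.tsv` — calibrated cohort burden;
#' * `ce_grid.tsv` — the scenario grid in report column order;
#' * `run_summary.txt` — parameter echo for the run.
#'
#' @param mode one of `"all"`, `"simulate"`, `"fit"`, `"burden"`,
#'   `"scenarios"`.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for the synthetic survey.
#' @param survey_config a [survey_config()]; its seed is overridden by
#'   `seed`.
#' @param profiles_path optional profile config file; defaults to the
#'   shipped table.
#' @param params burden parameters (calibrated internally).
#' @param scenarios list of [intervention_scenario()]s; defaults to
#'   [default_scenarios()].
#' @param use_fitted_demand if `TRUE` (default) the scenario stage uses the
#'   demand models fitted on the synthetic survey; otherwise the shipped
#'   published coefficients.
#' @param fx_rate,duration_weeks,gdp_per_capita cost-model settings.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the artifacts of the stages that ran.
#' @export
run_pipeline <- function(mode = c("all", "simulate", "fit", "burden", "scenarios"),
                         out_dir, seed = 1L,
                         survey_config = fpicce::survey_config(),
                         profiles_path = NULL,
                         params = default_burden_params(),
                         scenarios = default_scenarios(),
                         use_fitted_demand = TRUE,
                         fx_rate = 60, duration_weeks = 78,
                         gdp_per_capita = 1487,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  if (missing(out_dir) || !nzchar(out_dir)) stop_config("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list()

  survey_config$seed <- as.integer(seed)
  chash <- config_hash(list(survey_config = survey_config, fx_rate = fx_rate,
                            duration_weeks = duration_weeks))

  survey_path <- file.path(out_dir, "survey.tsv")
  fits_path <- file.path(out_dir, "demand_fits.tsv")

  if (mode %in% c("all", "simulate")) {
    say("simulate: generating %d synthetic households (seed %d)",
        survey_config$n_households, seed)
    survey <- generate_survey(survey_config)
    write_survey(survey, survey_path, seed = seed, config_hash = chash)
    out$survey <- survey
  }

  if (mode %in% c("all", "fit")) {
    if (is.null(out$survey)) {
      if (!file.exists(survey_path)) {
        stop_dependency("no survey artifact found: run the 'simulate' stage first")
      }
      out$survey <- read_survey(survey_path)
    }
    say("fit: first-difference demand estimation")
    kept <- exclude_uncertain(out$survey, quiet = !verbose)
    fit_cur <- fit_first_difference(kept, form = "log")
    fit_pot <- fit_first_difference(kept, form = "level")
    out$fits <- list(current = fit_cur, potential = fit_pot)
    fit_tab <- data.frame(model = c("current", "potential"),
                          form = c("log", "level"),
                          beta0 = c(fit_cur$beta0, fit_pot$beta0),
                          beta1 = c(fit_cur$beta1, fit_pot$beta1),
                          se_beta0 = c(fit_cur$se_beta0, fit_pot$se_beta0),
                          se_beta1 = c(fit_cur$se_beta1, fit_pot$se_beta1),
                          n_obs = c(fit_cur$n_obs, fit_pot$n_obs),
                          n_excluded = attr(kept, "n_excluded"))
    write_table_headered(fit_tab, fits_path, seed = seed, config_hash = chash)
    mfx <- rbind(cbind(model = "current", marginal_effects(fit_cur)),
                 cbind(model = "potential", marginal_effects(fit_pot)))
    write_table_headered(mfx, file.path(out_dir, "marginal_effects.tsv"),
                         seed = seed, config_hash = chash)
  }

  profiles <- if (is.null(profiles_path)) {
    default_ses_profiles(attribution = params$attribution)
  } else {
    read_ses_profiles(profiles_path, attribution = params$attribution)
  }

  if (mode %in% c("all", "burden", "scenarios")) {
    say("burden: calibrating hemoglobin distributions and cost parameters")
    profiles <- calibrate_profiles(profiles, params)
    params <- calibrate_costs(profiles, params)
    out$profiles <- profiles
    out$params <- params
    burden <- compute_burden(profiles, params)
    out$burden <- burden
    if (mode %in% c("all", "burden")) {
      write_table_headered(burden$by_decile,
                           file.path(out_dir, "burden_by_decile.tsv"),
                           seed = seed, config_hash = chash)
      totals <- data.frame(component = names(burden$totals),
                           value = unlist(burden$totals))
      write_table_headered(totals, file.path(out_dir, "burden_totals.tsv"),
                           seed = seed, config_hash = chash)
    }
  }

  if (mode %in% c("all", "scenarios")) {
    if (use_fitted_demand) {
      if (is.null(out$fits)) {
        if (!file.exists(fits_path)) {
          stop_dependency("no demand-fit artifact found: run the 'fit' stage first")
        }
        tab <- read_table_headered(fits_path)
        eval_means <- data.frame(decile = profiles$decile,
                                 qty = profiles$baseline_qty,
                                 price = profiles$baseline_price)
        out$fits <- list(
          current = demand_fit("log", tab$beta0[1], tab$beta1[1],
                               tab$se_beta0[1], tab$se_beta1[1], tab$n_obs[1],
                               eval_means = eval_means),
          potential = demand_fit("level", tab$beta0[2], tab$beta1[2],
                                 tab$se_beta0[2], tab$se_beta1[2], tab$n_obs[2]))
      }
      fits <- out$fits
    } else {
      fits <- load_demand_estimates(profiles)
    }
    say("scenarios: evaluating %d subsidy scenarios", length(scenarios))
    grid <- scenario_grid(scenarios, profiles, fits, params,
                          fx_rate = fx_rate, duration_weeks = duration_weeks,
                          gdp_per_capita = gdp_per_capita)
    out$grid <- grid
    report <- grid
    report$cost_musd <- round(report$cost_musd, 1)
    report$losses_averted_musd <- round(report$losses_averted_musd, 1)
    report$dalys_averted <- round(report$dalys_averted)
    report$ratio_provider <- round(report$ratio_provider)
    report$ratio_social <- round(report$ratio_social)
    write_table_headered(report, file.path(out_dir, "ce_grid.tsv"),
                         seed = seed, config_hash = chash)
  }

  summary_path <- file.path(out_dir, "run_summary.txt")
  writeLines(c(sprintf("fpicce %s", utils::packageVersion("fpicce")),
               sprintf("mode: %s", mode),
               sprintf("seed: %d", seed),
               sprintf("config_hash: %s", chash),
               sprintf("fx_rate: %s INR/USD", fx_rate),
               sprintf("duration_weeks: %s", duration_weeks)),
             summary_path)
  invisible(out)
}
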