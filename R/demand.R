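# Demand models for F-PICs, estimated in first differences.
#
# Each household is observed in two states (actual and hypothetical), so the
# two-period fixed-effects models
#   log(Y_it) = b0 log(P_it) + b1 (SES_i x log(P_it)) + theta_i + e_it
#   Y_it      = b0 P_it      + b1 (SES_i x P_it)      + theta_i + e_it
# are estimated on within-household differences, which eliminates the
# household fixed effect theta_i exactly: dY = b0 dP + b1 (SES x dP) + de.

#' Construct a demand fit
#'
#' Container for an estimated (or externally supplied) demand model.  `form`
#' is `"log"` for the constant-elasticity model on log quantity/log price
#' (used for current buyers) or `"level"` for the linear model on quantity
#' and price in levels (used for potential buyers).
#'
#' @param form `"log"` or `"level"`.
#' @param beta0 price coefficient.
#' @param beta1 SES-by-price interaction coefficient.
#' @param se_beta0,se_beta1 standard errors (non-negative, may be `NA`).
#' @param n_obs number of households behind the estimates.
#' @param eval_means for `form = "log"`, a data frame with columns `decile`,
#'   `qty` (grams/week) and `price` (INR per 10 g): the per-decile sample
#'   means at which marginal effects are evaluated.
#' @return an object of class `demand_fit`.
#' @export
demand_fit <- function(form = c("log", "level"), beta0, beta1,
                       se_beta0 = NA_real_, se_beta1 = NA_real_,
                       n_obs = NA_integer_, eval_means = NULL) {
  form <- match.arg(form)
  if (!is.na(n_obs) && n_obs < 3) stop_sample("a demand fit requires n_obs >= 3")
  ses <- c(se_beta0, se_beta1)
  if (any(!is.na(ses) & ses < 0)) stop_domain("standard errors must be non-negative")
  if (!is.null(eval_means)) {
    req <- c("decile", "qty", "price")
    if (!all(req %in% names(eval_means))) {
      stop_config("eval_means must have columns decile, qty, price")
    }
  }
  structure(list(form = form, beta0 = beta0, beta1 = beta1,
                 se_beta0 = se_beta0, se_beta1 = se_beta1,
                 n_obs = n_obs, eval_means = eval_means),
            class = "demand_fit")
}

#' @export
print.demand_fit <- function(x, ...) {
  cat(sprintf("Demand fit (%s form), n = %s households\n", x$form, x$n_obs))
  cat(sprintf("  beta0 (price)       %10.4f  (SE %.4f)\n", x$beta0, x$se_beta0))
  cat(sprintf("  beta1 (SES x price) %10.4f  (SE %.4f)\n", x$beta1, x$se_beta1))
  invisible(x)
}

#' Drop uncertain hypothetical responses
#'
#' Applies the certainty-scale correction for hypothetical bias: households
#' that declared themselves uncertain about their stated purchase are removed
#' before estimation.  The number of exclusions is reported as the
#' `n_excluded` attribute and via a message.
#'
#' @param records survey data frame with a logical `certain` column.
#' @param quiet suppress the message.
#' @return the retained records, with attribute `n_excluded`.
#' @export
exclude_uncertain <- function(records, quiet = FALSE) {
  if (!"certain" %in% names(records)) {
    stop_config("records must carry a 'certain' flag")
  }
  keep <- records[records$certain, , drop = FALSE]
  n_excluded <- nrow(records) - nrow(keep)
  if (nrow(keep) == 0) stop_sample("all records are flagged uncertain")
  if (!quiet) {
    message(sprintf("certainty-scale exclusion: removed %d of %d records",
                    n_excluded, nrow(records)))
  }
  attr(keep, "n_excluded") <- n_excluded
  keep
}

#' Estimate a demand model by first differences
#'
#' Least-squares estimation, without intercept, of
#' `dY = beta0 * dP + beta1 * (SES x dP)` where `dY` and `dP` are
#' within-household differences between the hypothetical and the actual state
#' (in logs for `form = "log"`).  This is the within estimator of the
#' two-period fixed-effects model, so any household-specific constant in the
#' outcome cancels.  Estimates are computed from the normal equations in
#' closed form; standard errors use the conventional homoskedastic
#' least-squares formula.
#'
#' For `form = "log"` the per-decile sample means of actual quantity and
#' price are stored as the evaluation points for [marginal_effect()]; they
#' can be overridden with `eval_means`.
#'
#' @param records survey data frame (see [generate_survey()]).
#' @param form `"log"` (current buyers) or `"level"` (potential buyers).
#' @param buyer_class which buyer class to estimate on; defaults to
#'   `"current"` for the log form and `"potential"` for the level form.
#' @param eval_means optional data frame (`decile`, `qty`, `price`)
#'   overriding the sample-mean evaluation points of the log form.
#' @return a [demand_fit()].
#' @export
fit_first_difference <- function(records, form = c("log", "level"),
                                 buyer_class = NULL, eval_means = NULL) {
  form <- match.arg(form)
  buyer_class <- buyer_class %||% switch(form, log = "current", level = "potential")
  rec <- records[records$buyer_class == buyer_class, , drop = FALSE]
  if (nrow(rec) < 3) {
    stop_sample(sprintf("need at least 3 '%s' households with both states, got %d",
                        buyer_class, nrow(rec)))
  }

  if (form == "log") {
    vals <- c(rec$qty_actual, rec$qty_hypothetical, rec$price_actual, rec$price_offered)
    if (any(vals <= 0)) {
      stop_domain(paste("log form requires strictly positive prices and",
                        "quantities in both states; use the level form for",
                        "households with zero purchases"))
    }
    dy <- log(rec$qty_hypothetical) - log(rec$qty_actual)
    dp <- log(rec$price_offered) - log(rec$price_actual)
  } else {
    dy <- rec$qty_hypothetical - rec$qty_actual
    dp <- rec$price_offered - rec$price_actual
  }

  if (all(abs(dp) < 1e-12)) {
    stop_identification("no price variation between states (all price differences are zero)")
  }

  X <- cbind(dp = dp, ses_dp = rec$ses_decile * dp)
  XtX <- crossprod(X)
  if (abs(det(XtX)) < 1e-10 * prod(diag(XtX) + 1e-300)) {
    stop_identification("price and SES-by-price differences are collinear; coefficients not identified")
  }
  beta <- drop(solve(XtX, crossprod(X, dy)))
  resid <- dy - drop(X %*% beta)
  df_resid <- nrow(rec) - 2L
  sigma2 <- if (df_resid > 0) sum(resid^2) / df_resid else 0
  vcov <- sigma2 * solve(XtX)
  se <- sqrt(pmax(diag(vcov), 0))

  if (form == "log" && is.null(eval_means)) {
    eval_means <- stats::aggregate(
      cbind(qty = rec$qty_actual, price = rec$price_actual),
      by = list(decile = rec$ses_decile), FUN = mean)
  }

  demand_fit(form = form, beta0 = beta[[1]], beta1 = beta[[2]],
             se_beta0 = se[[1]], se_beta1 = se[[2]],
             n_obs = nrow(rec), eval_means = eval_means)
}

#' Marginal effect of price on weekly quantity
#'
#' Change in weekly grams bought when the price rises by 1 INR per 10 g, for
#' a given wealth decile.  For the level form this is `beta0 + beta1 * s`;
#' for the log form the elasticity term `beta0 + beta1 * s` is converted to a
#' level effect at the decile's sample-mean quantity and price,
#' `(beta0 + beta1 * s) * qty_s / price_s`.
#'
#' @param fit a [demand_fit()].
#' @param decile wealth decile, integer in 1..10.
#' @return grams/week per (INR per 10 g); negative when demand slopes down.
#' @export
marginal_effect <- function(fit, decile) {
  if (!inherits(fit, "demand_fit")) stop_config("'fit' must be a demand_fit")
  if (any(!(decile %in% 1:10))) stop_domain("decile must be in 1..10")
  term <- fit$beta0 + fit$beta1 * decile
  if (fit$form == "level") return(term)
  if (is.null(fit$eval_means)) {
    stop_state("log-form marginal effects need eval_means (per-decile mean quantity and price)")
  }
  idx <- match(decile, fit$eval_means$decile)
  if (any(is.na(idx))) {
    stop_state(sprintf("eval_means has no entry for decile %s",
                       paste(decile[is.na(idx)], collapse = ", ")))
  }
  term * fit$eval_means$qty[idx] / fit$eval_means$price[idx]
}

#' All ten per-decile marginal effects
#'
#' @param fit a [demand_fit()].
#' @return data frame with columns `decile` and `mfx`.
#' @export
marginal_effects <- function(fit) {
  data.frame(decile = 1:10, mfx = marginal_effect(fit, 1:10))
}

#' Weekly demand increase induced by a price subsidy
#'
#' Translates a fractional price discount into a change in weekly grams
#' bought.  The default `"linear"` mode extrapolates the marginal effect:
#' `-mfx * discount * reference_price` (the absolute price cut is
#' `discount * reference_price` INR per 10 g).  The `"structural"` mode uses
#' the fitted functional form instead: for the log form
#' `Y0 * ((1 - discount)^(beta0 + beta1 * s) - 1)`, for the level form the
#' same expression as the linear mode.  The response is clamped below at
#' `-baseline_qty` (demand cannot fall below zero).
#'
#' `fit` may also be a single numeric marginal effect (grams/week per INR per
#' 10 g), e.g. an average across deciles, in which case `decile` is ignored
#' and only the linear mode is available.
#'
#' @param fit a [demand_fit()] or a numeric marginal effect.
#' @param decile wealth decile in 1..10.
#' @param discount fractional price discount in `[0, 1)`.
#' @param reference_price undiscounted price, INR per 10 g.
#' @param baseline_qty pre-subsidy weekly quantity (grams); used by the
#'   structural log mode and as the lower clamp.
#' @param mode `"linear"` or `"structural"`.
#' @return change in weekly grams bought (usually positive for a discount).
#' @export
demand_response <- function(fit, decile = NULL, discount, reference_price,
                            baseline_qty = 0, mode = c("linear", "structural")) {
  mode <- match.arg(mode)
  if (any(discount < 0) || any(discount >= 1)) {
    stop_domain("discount must be in [0, 1)")
  }
  if (reference_price <= 0) stop_domain("reference_price must be positive")
  if (any(baseline_qty < 0)) stop_domain("baseline_qty must be non-negative")

  if (is.numeric(fit)) {
    if (mode != "linear") stop_config("a bare marginal effect supports only the linear mode")
    resp <- -fit * discount * reference_price
  } else if (mode == "linear") {
    resp <- -marginal_effect(fit, decile) * discount * reference_price
  } else if (fit$form == "log") {
    term <- fit$beta0 + fit$beta1 * decile
    resp <- baseline_qty * ((1 - discount)^term - 1)
  } else {
    resp <- -(fit$beta0 + fit$beta1 * decile) * discount * reference_price
  }
  pmax(resp, -baseline_qty)
}

#' Demand fits from the published coefficient estimates
#'
#' Builds the pair of [demand_fit()] objects from the coefficient table
#' shipped with the package (constant-elasticity model for current buyers,
#' level model for potential buyers, both estimated on the 2013 twelve-city
#' market survey).  Evaluation points for the log form's marginal effects are
#' the per-decile baseline quantity and price from the SES profile table.
#'
#' @param profiles SES profile data frame (see [default_ses_profiles()]);
#'   used for the log form's `eval_means`.
#' @param path coefficient file; defaults to the shipped copy.
#' @return list with elements `current` and `potential`.
#' @export
load_demand_estimates <- function(profiles = default_ses_profiles(),
                                  path = fpic_extdata("demand_coefficients.tsv")) {
  tab <- read_table_headered(path)
  need <- c("model", "form", "beta0", "beta1", "se_beta0", "se_beta1", "n_obs")
  if (!all(need %in% names(tab))) {
    stop_config("demand coefficient file must have columns: model, form, beta0, beta1, se_beta0, se_beta1, n_obs")
  }
  eval_means <- data.frame(decile = profiles$decile,
                           qty = profiles$baseline_qty,
                           price = profiles$baseline_price)
  fits <- lapply(seq_len(nrow(tab)), function(i) {
    demand_fit(form = tab$form[i], beta0 = tab$beta0[i], beta1 = tab$beta1[i],
               se_beta0 = tab$se_beta0[i], se_beta1 = tab$se_beta1[i],
               n_obs = tab$n_obs[i],
               eval_means = if (tab$form[i] == "log") eval_means else NULL)
  })
  names(fits) <- tab$model
  fits[c("current", "potential")]
}

#' Published per-decile marginal effects
#'
#' The marginal-effect columns reported with the original survey estimates
#' (change in weekly grams per 1 INR per 10 g price increase), shipped as
#' reference data for reproduction checks and for average-marginal-effect
#' response calculations.
#'
#' @param path file path; defaults to the shipped copy.
#' @return data frame with columns `model` (`current`/`potential`),
#'   `decile`, `mfx`.
#' @export
reported_marginal_effects <- function(path = fpic_extdata("reported_marginal_effects.tsv")) {
  read_table_headered(path)
}
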