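# Synthetic market-survey generator.
#
# Emulates the statistical structure of a 12-city market survey of households
# with a 6-23-month-old child: each household is observed in two states, the
# actual purchase state and a hypothetical state in which F-PICs are offered
# at a randomly discounted price.  Current buyers receive a percentage
# discount on the brand they already buy; potential and non-buyers are offered
# a 25 g sachet at one of five fixed price points.  Only the first offered
# price is used for quantity generation and estimation; lower follow-up
# offers enter solely through the potential/non-buyer classification.

DISCOUNT_MENU <- c(0.2, 0.4, 0.6, 0.8)          # current buyers
SACHET_PRICE_MENU <- c(14, 11, 8, 5, 2)         # INR per 25 g, others
SACHET_REFERENCE_PRICE <- 14                     # undiscounted INR per 25 g
GRAMS_PER_SACHET <- 25

#' Default SES distribution of surveyed households
#'
#' Wealth-decile sampling probabilities reproducing the unbalanced SES
#' composition of the underlying market survey, in which households were
#' classified against population-wide decile break points: quintile counts
#' 500, 1341, 1814, 943, 203 out of 4801, split evenly within quintiles.
#'
#' @return numeric vector of length 10 summing to 1.
#' @export
survey_ses_shares <- function() {
  q <- c(500, 1341, 1814, 943, 203) / 4801
  rep(q / 2, each = 2)
}

#' Default buyer-class shares by SES decile
#'
#' Observed shares of current buyers (bought F-PICs in the last 7 days),
#' potential buyers (would buy at some offered discounted price) and
#' non-buyers (would not buy at any offered price) per wealth decile.
#'
#' @return a 10 x 3 matrix with columns `current`, `potential`, `non`;
#'   rows sum to 1.
#' @export
buyer_class_shares <- function() {
  current <- c(0.106, 0.155, 0.187, 0.280, 0.307, 0.311, 0.345, 0.380, 0.351, 0.288)
  potential <- c(0.659, 0.614, 0.630, 0.553, 0.499, 0.505, 0.471, 0.406, 0.477, 0.481)
  m <- cbind(current = current, potential = potential,
             non = 1 - current - potential)
  rownames(m) <- 1:10
  m
}

#' Configuration of the synthetic survey generator
#'
#' Defaults emulate the observed survey: 4801 households, the survey's SES
#' composition, buyer-class shares per decile, and current buyers' baseline
#' weekly quantity and price moments (survey-weighted means across wealth
#' quintiles: 514 g/week (SD 765) at 5.29 INR per 10 g (SD 2.41)).  The
#' ground-truth demand parameters default to the two estimated demand models:
#' a constant-elasticity (log-log) law for current buyers and a level law for
#' potential buyers, both with an SES interaction.
#'
#' @param n_households number of households to simulate.
#' @param ses_shares length-10 decile sampling probabilities (sum to 1).
#' @param class_shares 10 x 3 matrix of buyer-class probabilities per decile
#'   (columns `current`, `potential`, `non`; rows sum to 1).
#' @param baseline_price_mean,baseline_price_sd moments of current buyers'
#'   actual price, INR per 10 g.
#' @param baseline_qty_mean,baseline_qty_sd moments of current buyers' actual
#'   weekly quantity, grams.
#' @param true_beta0_log,true_beta1_log elasticity intercept and SES
#'   interaction of the current-buyer constant-elasticity law.
#' @param true_beta0_level,true_beta1_level level-law price coefficient and
#'   SES interaction (grams/week per INR per 10 g) for potential buyers.
#' @param noise_sd_log standard deviation of the multiplicative log-normal
#'   disturbance on current buyers' hypothetical quantity (log scale).
#' @param noise_sd_level standard deviation (grams/week) of the additive
#'   disturbance on potential buyers' hypothetical quantity, truncated so
#'   quantities stay non-negative.
#' @param uncertain_rate probability that a household's hypothetical response
#'   is flagged as uncertain (and later excluded from estimation).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return an object of class `survey_config`.
#' @export
survey_config <- function(n_households = 4801,
                          ses_shares = survey_ses_shares(),
                          class_shares = buyer_class_shares(),
                          baseline_price_mean = 5.29,
                          baseline_price_sd = 2.41,
                          baseline_qty_mean = 514,
                          baseline_qty_sd = 765,
                          true_beta0_log = -0.328,
                          true_beta1_log = 0.016,
                          true_beta0_level = -35.000,
                          true_beta1_level = 1.557,
                          noise_sd_log = 0.6,
                          noise_sd_level = 30,
                          uncertain_rate = 0.1,
                          seed = NULL) {
  if (length(ses_shares) != 10 || abs(sum(ses_shares) - 1) > 1e-9) {
    stop_config("ses_shares must have length 10 and sum to 1")
  }
  assert_probability(ses_shares, "ses_shares")
  if (!is.matrix(class_shares) || !identical(dim(class_shares), c(10L, 3L))) {
    stop_config("class_shares must be a 10 x 3 matrix")
  }
  assert_probability(class_shares, "class_shares")
  if (any(abs(rowSums(class_shares) - 1) > 1e-9)) {
    stop_config("each row of class_shares must sum to 1")
  }
  scales <- c(baseline_price_mean = baseline_price_mean,
              baseline_price_sd = baseline_price_sd,
              baseline_qty_mean = baseline_qty_mean,
              baseline_qty_sd = baseline_qty_sd)
  if (any(scales <= 0)) stop_config("scale parameters must be strictly positive")
  if (noise_sd_log < 0 || noise_sd_level < 0) {
    stop_config("noise standard deviations must be non-negative")
  }
  assert_probability(uncertain_rate, "uncertain_rate")
  structure(list(n_households = as.integer(n_households),
                 ses_shares = ses_shares,
                 class_shares = class_shares,
                 baseline_price_mean = baseline_price_mean,
                 baseline_price_sd = baseline_price_sd,
                 baseline_qty_mean = baseline_qty_mean,
                 baseline_qty_sd = baseline_qty_sd,
                 true_beta0_log = true_beta0_log,
                 true_beta1_log = true_beta1_log,
                 true_beta0_level = true_beta0_level,
                 true_beta1_level = true_beta1_level,
                 noise_sd_log = noise_sd_log,
                 noise_sd_level = noise_sd_level,
                 uncertain_rate = uncertain_rate,
                 seed = seed),
            class = "survey_config")
}

# Log-normal draws with given arithmetic mean and SD (keeps prices and
# quantities strictly positive while matching the configured moments).
rlnorm_moments <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate a synthetic household survey panel
#'
#' Draws `n_households` households with an SES decile and a buyer class, then
#' fills in the two-state price-quantity panel:
#'
#' * **current buyers** have a positive actual quantity and price; their
#'   hypothetical quantity at a randomly discounted price follows the
#'   constant-elasticity law
#'   `Y1 = Y0 * (P1/P0)^(beta0 + beta1 * SES)` times a log-normal disturbance;
#' * **potential buyers** have zero actual quantity; their hypothetical
#'   quantity at a randomly offered sachet price follows the level law
#'   `Y1 = max(0, (beta0 + beta1 * SES) * (P1 - P0) + noise)` where `P0` is
#'   the undiscounted sachet reference price (14 INR per 25 g);
#' * **non-buyers** buy nothing in either state.
#'
#' Certainty flags are drawn independently with probability
#' `1 - uncertain_rate`.
#'
#' @param config a [survey_config()].
#' @return a data frame with one row per household and columns
#'   `household_id`, `ses_decile`, `buyer_class`, `price_actual`,
#'   `price_offered` (INR per 10 g), `qty_actual`, `qty_hypothetical`
#'   (grams/week), `discount_assigned` (discount fraction for current buyers,
#'   offered sachet price in INR per 25 g otherwise) and `certain`.
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "survey_config")) {
    stop_config("'config' must be created with survey_config()")
  }
  n <- config$n_households
  if (n < 2) stop_sample("at least 2 households are required")
  if (!is.null(config$seed)) set.seed(config$seed)

  ses <- sample.int(10, n, replace = TRUE, prob = config$ses_shares)
  classes <- colnames(config$class_shares)
  buyer_class <- vapply(ses, function(s) {
    sample(classes, 1L, prob = config$class_shares[s, ])
  }, character(1))

  price_actual <- rep(SACHET_REFERENCE_PRICE / (GRAMS_PER_SACHET / 10), n)
  price_offered <- qty_actual <- qty_hyp <- numeric(n)
  discount_assigned <- numeric(n)

  cur <- buyer_class == "current"
  if (any(cur)) {
    ncur <- sum(cur)
    p0 <- rlnorm_moments(ncur, config$baseline_price_mean, config$baseline_price_sd)
    y0 <- rlnorm_moments(ncur, config$baseline_qty_mean, config$baseline_qty_sd)
    disc <- sample(DISCOUNT_MENU, ncur, replace = TRUE)
    p1 <- (1 - disc) * p0
    elast <- config$true_beta0_log + config$true_beta1_log * ses[cur]
    eps <- if (config$noise_sd_log > 0) {
      stats::rnorm(ncur, 0, config$noise_sd_log)
    } else 0
    y1 <- y0 * (p1 / p0)^elast * exp(eps)
    price_actual[cur] <- p0
    price_offered[cur] <- p1
    qty_actual[cur] <- y0
    qty_hyp[cur] <- y1
    discount_assigned[cur] <- disc
  }

  pot <- buyer_class == "potential"
  if (any(pot)) {
    npot <- sum(pot)
    sachet <- sample(SACHET_PRICE_MENU, npot, replace = TRUE)
    p1 <- sachet / (GRAMS_PER_SACHET / 10)
    p0 <- SACHET_REFERENCE_PRICE / (GRAMS_PER_SACHET / 10)
    slope <- config$true_beta0_level + config$true_beta1_level * ses[pot]
    eps <- if (config$noise_sd_level > 0) {
      stats::rnorm(npot, 0, config$noise_sd_level)
    } else 0
    y1 <- pmax(0, slope * (p1 - p0) + eps)
    price_offered[pot] <- p1
    qty_hyp[pot] <- y1
    discount_assigned[pot] <- sachet
  }

  non <- buyer_class == "non"
  if (any(non)) {
    sachet <- sample(SACHET_PRICE_MENU, sum(non), replace = TRUE)
    price_offered[non] <- sachet / (GRAMS_PER_SACHET / 10)
    discount_assigned[non] <- sachet
  }

  certain <- stats::runif(n) >= config$uncertain_rate

  data.frame(household_id = seq_len(n),
             ses_decile = ses,
             buyer_class = buyer_class,
             price_actual = price_actual,
             price_offered = price_offered,
             qty_actual = qty_actual,
             qty_hypothetical = qty_hyp,
             discount_assigned = discount_assigned,
             certain = certain,
             stringsAsFactors = FALSE)
}

#' Validate and assign buyer classes from observed quantities
#'
#' A household is a *current* buyer if and only if it bought a positive
#' quantity in the actual state; among non-purchasing households, a positive
#' hypothetical quantity at the first offered price identifies a *potential*
#' buyer.  A household that declined the first offer may still be a potential
#' buyer at a lower follow-up price; that information is carried by the
#' recorded `buyer_class` label, which is kept for zero-quantity households
#' already labelled `potential` or `non`.
#'
#' @param records survey data frame as returned by [generate_survey()].
#' @return `records` with `buyer_class` validated (and filled in where
#'   derivable from quantities).
#' @export
classify_buyers <- function(records) {
  needed <- c("qty_actual", "qty_hypothetical")
  if (!all(needed %in% names(records))) {
    stop_config("records must carry qty_actual and qty_hypothetical")
  }
  labelled <- records$buyer_class %||% rep(NA_character_, nrow(records))

  inferred <- ifelse(records$qty_actual > 0, "current",
                     ifelse(records$qty_hypothetical > 0, "potential", NA))
  # zero in both states: keep an existing potential/non label (follow-up
  # offers are not recorded), default to non otherwise
  keep <- is.na(inferred) & labelled %in% c("potential", "non")
  inferred[keep] <- labelled[keep]
  inferred[is.na(inferred)] <- "non"

  bad_hard <- which((labelled == "non" & (records$qty_actual > 0 |
                                            records$qty_hypothetical > 0)) |
                      (labelled == "current" & records$qty_actual == 0) |
                      (labelled != "current" & records$qty_actual > 0))
  if (length(bad_hard)) {
    stop_consistency(sprintf(
      "buyer-class label inconsistent with observed quantities for %d record(s), e.g. household %s",
      length(bad_hard), records$household_id[bad_hard[1]]))
  }
  records$buyer_class <- inferred
  records
}

#' Write / read a survey panel as delimited text
#'
#' Fixed column order: `household_id`, `ses_decile`, `buyer_class`,
#' `price_actual`, `price_offered`, `qty_actual`, `qty_hypothetical`,
#' `discount_assigned`, `certain`; one row per household.
#'
#' @param records survey data frame.
#' @param path file path.
#' @param seed,config_hash provenance recorded in the file header.
#' @return `path` (write) or the survey data frame (read).
#' @export
write_survey <- function(records, path, seed = NA, config_hash = NA) {
  cols <- c("household_id", "ses_decile", "buyer_class", "price_actual",
            "price_offered", "qty_actual", "qty_hypothetical",
            "discount_assigned", "certain")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop_config(sprintf("survey records lack column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  write_table_headered(records[, cols], path, seed = seed,
                       config_hash = config_hash)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  rec <- read_table_headered(path)
  rec$certain <- as.logical(rec$certain)
  rec
}
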