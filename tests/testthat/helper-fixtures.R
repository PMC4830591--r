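# Shared fixtures, all built in code.

# Survey config with all households in one buyer class.
single_class_config <- function(class = c("current", "potential", "non"),
                                n = 200, seed = 42, ...) {
  class <- match.arg(class)
  shares <- matrix(0, 10, 3, dimnames = list(1:10, c("current", "potential", "non")))
  shares[, class] <- 1
  survey_config(n_households = n, class_shares = shares, seed = seed, ...)
}

# Noise-free generator truths used in exact-recovery tests.
noiseless_config <- function(n = 500, seed = 7, ...) {
  survey_config(n_households = n, noise_sd_log = 0, noise_sd_level = 0,
                uncertain_rate = 0, seed = seed, ...)
}

# Severity targets implied exactly by a Gaussian Hb distribution.
gaussian_targets <- function(mean, sd, thresholds = c(70, 100, 110)) {
  p <- pnorm(thresholds, mean, sd)
  c(mild = p[3] - p[2], moderate = p[2] - p[1], severe = p[1])
}

# Calibrated default profiles + calibrated params, computed once per run.
calibrated_defaults <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- default_burden_params()
      profiles <- calibrate_profiles(default_ses_profiles(), params)
      params <- calibrate_costs(profiles, params)
      cache <<- list(profiles = profiles, params = params,
                     fits = load_demand_estimates(profiles))
    }
    cache
  }
})

# A minimal profile table: all burden in decile 1, hand-settable prevalences.
toy_profiles <- function(prev_mild = 0, prev_moderate = 0, prev_severe = 0,
                         share1 = 0.1, mortality = 4.2) {
  prof <- default_ses_profiles()
  prof$cohort_share <- rep((1 - share1) / 9, 10)
  prof$cohort_share[1] <- share1
  prof$prev_mild <- c(prev_mild, rep(0, 9))
  prof$prev_moderate <- c(prev_moderate, rep(0, 9))
  prof$prev_severe <- c(prev_severe, rep(0, 9))
  prof$annual_mortality <- mortality
  prof
}
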