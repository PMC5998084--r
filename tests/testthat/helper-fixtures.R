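# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# Small synthetic panel with intercept-only random effects and all
# covariate effects switched off (pure variance-components data).
make_vc_panel <- function(seed, n_counties = 6, watersheds_per_county = 8,
                          sigma2 = 0.2, tau_w = 1.0, tau_c = 0.5,
                          obs_years = c(1988, 1995, 2000, 2005, 2008, 2012),
                          missing_rate = 0) {
  fe <- npp_true_effects()
  fe[] <- 0
  fe["intercept"] <- 5
  cfg <- panel_config(n_counties = n_counties,
                      watersheds_per_county = watersheds_per_county,
                      obs_years = obs_years,
                      fixed_effects = fe,
                      sigma2_resid = sigma2,
                      tau_watershed = tau_w, tau_county = tau_c,
                      missing_rate = missing_rate, seed = seed)
  generate_panel(cfg)
}

# Balanced nested layout (a counties x m watersheds x r reps) generated
# directly, plus the closed-form nested-ANOVA variance-component
# estimators (which REML reproduces on balanced data with interior
# optima).
balanced_nested_data <- function(a = 6, m = 5, r = 4,
                                 sigma = 0.7, sd_w = 1.2, sd_c = 0.9,
                                 mu = 10, seed = 1) {
  set.seed(seed)
  county <- rep(seq_len(a), each = m * r)
  watershed <- rep(seq_len(a * m), each = r)
  y <- mu + rep(rnorm(a, 0, sd_c), each = m * r) +
    rep(rnorm(a * m, 0, sd_w), each = r) +
    rnorm(a * m * r, 0, sigma)
  df <- data.frame(y = y,
                   watershed_id = sprintf("W%03d", watershed),
                   county_id = sprintf("C%02d", county))

  # nested ANOVA mean squares
  gm <- mean(y)
  cm <- tapply(y, county, mean)
  wm <- tapply(y, watershed, mean)
  ms_c <- m * r * sum((cm - gm)^2) / (a - 1)
  ms_w <- r * sum((wm - rep(cm, each = m))^2) / (a * (m - 1))
  ms_e <- sum((y - rep(wm, each = r))^2) / (a * m * (r - 1))
  list(data = df,
       anova = c(sigma2 = ms_e,
                 tau_w = (ms_w - ms_e) / r,
                 tau_c = (ms_c - ms_w) / (m * r)))
}

# relative error with an absolute floor for boundary components
rel_err <- function(est, truth, floor = 1e-6) {
  abs(est - truth) / pmax(abs(truth), floor)
}

# seeds below 2^31 derived from a base seed
derive_seed <- function(base, k) (base * 1000L + k) %% .Machine$integer.max

# default term list of a ladder step (internal helper re-exposed for tests)
growth_terms_for_test <- function(step) nppgrowth:::growth_step_terms(step)
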