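test_that("ICC arithmetic reproduces the published decompositions", {
  # unconditional growth-model components
  d1 <- icc_from_components(0.160, 1.781, 1.354)
  expect_equal(round(d1$icc_watershed, 3), 0.541)
  expect_equal(round(d1$icc_county, 3), 0.411)

  # null-model components
  d2 <- icc_from_components(0.550, 0.977, 0.905)
  expect_equal(round(d2$icc_county, 4), 0.3721)
  expect_equal(round(d2$icc_watershed, 4), 0.4017)

  expect_equal(icc_from_components(0.5, 0.3, 0)$icc_county, 0)
  expect_error(icc_from_components(-0.1, 1, 1), "non-negative")
  expect_error(icc_from_components(0, 0, 0), "undefined")
})

test_that("ICC shares sum to one on every fit", {
  for (s in 1:3) {
    gen <- make_vc_panel(seed = derive_seed(30, s), n_counties = 4,
                         watersheds_per_county = 5,
                         sigma2 = runif(1, 0.1, 1), tau_w = runif(1, 0.1, 2),
                         tau_c = runif(1, 0.1, 2))
    dec <- icc(null_model(gen$panel))
    expect_equal(dec$icc_watershed + dec$icc_county + dec$residual_share,
                 1, tolerance = 1e-12)
    expect_true(all(unlist(dec[1:3]) >= 0 & unlist(dec[1:3]) <= 1))
  }
})

test_that("standardization is exact, invertible and scale-coherent", {
  df <- data.frame(precipitation = c(300, 458.5, 617),
                   temperature = rep(-2, 3))
  z <- standardize_covariates(df, mean_table = c(precipitation = 300,
                                                 temperature = -2))
  # covariate equal to its mean everywhere -> all zeros
  expect_equal(z$temperature, rep(0, 3))
  # a one-SD shift moves the standardized value by exactly 1
  expect_equal(z$precipitation[2] - z$precipitation[1], 1, tolerance = 1e-12)

  back <- unstandardize(z)
  expect_equal(back$precipitation, df$precipitation, tolerance = 1e-12)
  expect_equal(back$temperature, df$temperature, tolerance = 1e-12)

  expect_error(standardize_covariates(df, sd_table = c(precipitation = 0)),
               "precipitation")
})

test_that("standardized coefficients are invariant to raw-scale changes", {
  gen <- make_vc_panel(seed = 33, n_counties = 5, watersheds_per_county = 8)
  p <- gen$panel
  p$time <- p$year - 1988
  set.seed(33)
  p$xcov <- rnorm(nrow(p), 10, 4)
  p$lnpp <- log(p$npp) + 0.15 * (p$xcov - 10) / 4

  fit1 <- nested_lmm(lnpp ~ time + xcov,
                     standardize_covariates(p, sd_table = c(xcov = 4)))
  p2 <- p
  p2$xcov <- p2$xcov * 10   # rescale raw covariate, rescale its SD
  fit2 <- nested_lmm(lnpp ~ time + xcov,
                     standardize_covariates(p2, sd_table = c(xcov = 40)))
  expect_equal(coef(fit1)["xcov"], coef(fit2)["xcov"], tolerance = 1e-8)
})

test_that("null model recovers generative components", {
  # the estimator is judged against what it can see: the residual
  # variance against its configured value (the residual pool is huge) and
  # the group components against the realized variance of the drawn
  # effects, since with finitely many groups the draws themselves scatter
  # around the configured tau
  gen <- make_vc_panel(seed = 34, n_counties = 18,
                       watersheds_per_county = 40,
                       sigma2 = 0.550, tau_w = 0.977, tau_c = 0.905)
  fit <- null_model(gen$panel)
  expect_lt(rel_err(fit$vc$sigma2, 0.550), 0.10)
  realized_tw <- var(gen$truth$watershed_effects[, "intercept"])
  expect_lt(rel_err(fit$vc$tau_watershed[1, 1], realized_tw), 0.10)
  realized_tc <- var(gen$truth$county_effects[, "intercept"])
  expect_lt(rel_err(fit$vc$tau_county[1, 1], realized_tc), 0.35)
})

test_that("zero county variance lands at the boundary", {
  gen <- make_vc_panel(seed = 35, n_counties = 12, watersheds_per_county = 50,
                       sigma2 = 0.3, tau_w = 1.0, tau_c = 0)
  fit <- null_model(gen$panel)
  expect_lt(fit$vc$tau_county[1, 1], 0.05)
})

test_that("unconditional growth recovers a noise-free quadratic exactly", {
  fe <- npp_true_effects(); fe[] <- 0
  fe["intercept"] <- 5.135; fe["time"] <- -0.02; fe["time2"] <- 0.001
  cfg <- panel_config(n_counties = 3, watersheds_per_county = 4,
                      fixed_effects = fe, sigma2_resid = 0,
                      tau_watershed = 0, tau_county = 0,
                      missing_rate = 0, seed = 36)
  p <- generate_panel(cfg)$panel
  p$time <- p$year - 1988
  dm <- build_design(p, log(npp) ~ time + I(time^2))
  fit <- fit_lmm(dm, "ML", lmm_control(fix_theta = c(0, 0)))
  expect_equal(unname(coef(fit)), c(5.135, -0.02, 0.001), tolerance = 1e-9)
})

test_that("growth-model fixed effects are recovered under noise", {
  fe <- npp_true_effects(); fe[] <- 0
  fe["intercept"] <- 5.135; fe["time"] <- 0; fe["time2"] <- 0.001
  cfg <- panel_config(n_counties = 10, watersheds_per_county = 30,
                      fixed_effects = fe, sigma2_resid = 0.16,
                      tau_watershed = 0.5, tau_county = 0.3,
                      missing_rate = 0, seed = 37)
  p <- generate_panel(cfg)$panel
  fit <- unconditional_growth(p)
  truth <- c(5.135, 0, 0.001)
  expect_true(all(abs(coef(fit) - truth) <= 2 * fit$se))
})

test_that("AIC prefers the quadratic when curvature is real", {
  fe <- npp_true_effects(); fe[] <- 0
  fe["intercept"] <- 5; fe["time2"] <- 0.01
  cfg <- panel_config(n_counties = 6, watersheds_per_county = 10,
                      fixed_effects = fe, sigma2_resid = 0.2,
                      tau_watershed = 0.5, tau_county = 0.3,
                      missing_rate = 0, seed = 38)
  p <- generate_panel(cfg)$panel
  p$time <- p$year - 1988
  quad <- nested_lmm(log(npp) ~ time + I(time^2), p)
  lin <- nested_lmm(log(npp) ~ time, p)
  expect_lt(quad$aic, lin$aic)
})

test_that("the conditional ladder is nested and monotone in likelihood", {
  cfg <- panel_config(n_counties = 8, watersheds_per_county = 10,
                      missing_rate = 0, seed = 39)
  p <- generate_panel(cfg)$panel
  lls <- vapply(2:6, function(s)
    conditional_growth(p, step = s)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
  expect_error(conditional_growth(p, step = 7), "between 2 and 6")
  expect_error(conditional_growth(p, step = 1), "between 2 and 6")
})

test_that("a no-effect covariate changes nothing materially", {
  cfg <- panel_config(n_counties = 6, watersheds_per_county = 10,
                      missing_rate = 0, seed = 40)
  p <- generate_panel(cfg)$panel
  set.seed(4040)  # distinct from the generator seed: the generator's own
                  # stream starts with N(0,1) draws for the covariates
  p$inert <- rnorm(nrow(p))  # true coefficient zero
  base <- conditional_growth(p, step = 2)
  aug <- conditional_growth(p, step = 2,
                            terms = c(growth_terms_for_test(2), "inert"))
  expect_lt(abs(aug$loglik - base$loglik), 3)
  expect_lt(abs(coef(aug)["inert"]), 3 * aug$se["inert"])
})

test_that("published-scale socioeconomic effects are recovered", {
  # county-level covariates have only counties x years effective cells,
  # so single-panel estimates scatter; average the recovery over
  # replicates and demand the signs every time
  n_rep <- 6
  est <- matrix(NA_real_, n_rep, 4,
                dimnames = list(NULL, c("gdp", "hpd", "tp", "tt")))
  for (k in seq_len(n_rep)) {
    cfg <- panel_config(n_counties = 18, watersheds_per_county = 12,
                        missing_rate = 0, seed = derive_seed(41, k))
    p <- generate_panel(cfg)$panel
    fit <- conditional_growth(p, step = 6)
    est[k, ] <- coef(fit)[c("gdp", "hpd", "time:precipitation",
                            "time:temperature")]
  }
  expect_lt(abs(mean(est[, "gdp"]) - (-0.093)), 0.03)
  expect_lt(abs(mean(est[, "hpd"]) - (-0.299)), 0.03)
  expect_true(all(est[, "gdp"] < 0))
  expect_true(all(est[, "hpd"] < 0))
  # interaction signs from the generative defaults
  expect_true(all(est[, "tp"] < 0))
  expect_true(all(est[, "tt"] > 0))
})

test_that("interaction trajectories order as the coefficient signs dictate", {
  cfg <- panel_config(n_counties = 12, watersheds_per_county = 15,
                      missing_rate = 0, seed = 42)
  p <- generate_panel(cfg)$panel
  fit <- conditional_growth(p, step = 6)
  prof <- as.data.frame(as.list(colMeans(
    p[c("precipitation", "temperature", "sunlight", "grassland_pct",
        "dem", "slope", "soil_n", "soil_p", "soil_k",
        "d2water", "d2highway", "d2village", "gdp", "hpd", "meat")])))
  prof$grassland_type <- factor("ASAG",
                                levels = c("ASAG", "ASAM", "DG", "MDW"))
  prof$nnr <- 0L
  sdp <- npp_sd_defaults()[["precipitation"]]
  hi <- prof; hi$precipitation <- hi$precipitation + sdp
  lo <- prof; lo$precipitation <- lo$precipitation - sdp
  # refit-time standardization uses sample means, so predict via the
  # standardized panel's own transform
  zpan <- standardize_covariates(p)
  mns <- attr(zpan, "standardize_means"); sds <- attr(zpan, "standardize_sds")
  zprof <- function(pr) {
    for (v in names(mns)) pr[[v]] <- (pr[[v]] - mns[[v]]) / sds[[v]]
    pr
  }
  grid <- seq(0, 24, by = 4)
  t_hi <- predict_trajectory(fit, zprof(hi), grid)
  t_lo <- predict_trajectory(fit, zprof(lo), grid)
  gap <- t_hi$pred - t_lo$pred
  # negative time-by-precipitation: the wet-minus-dry gap narrows in time
  expect_lt(gap[length(gap)], gap[1])
})

test_that("variance-share comparisons are plain arithmetic", {
  stub <- function(s2, tw, tc) structure(
    list(vc = list(sigma2 = s2, tau_watershed = matrix(tw),
                   tau_county = matrix(tc)), n_obs = 100L),
    class = "nested_lmm")
  a <- stub(0.160, 1.781, 1.354)
  expect_equal(unname(variance_shares(a, a)), c(0, 0, 0))

  b <- stub(0.088, 1.2, 0.9)
  vs <- variance_shares(a, b)
  expect_equal(round(100 * vs[["within"]], 1), 45.0)
  expect_equal(vs[["watershed"]], (1.781 - 1.2) / 1.781, tolerance = 1e-12)
  expect_equal(vs[["county"]], (1.354 - 0.9) / 1.354, tolerance = 1e-12)
})
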