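test_that("design construction is exact on a hand-checkable toy", {
  toy <- data.frame(y = c(1, 2, 3, 4),
                    t = c(0, 1, 2, 3),
                    watershed_id = c("a", "a", "b", "b"),
                    county_id = c("c1", "c1", "c2", "c2"))
  dm <- build_design(toy, y ~ t + I(t^2))
  expect_equal(matrix(dm$X, 4, 3),
               cbind(1, c(0, 1, 2, 3), c(0, 1, 4, 9)))
  expect_equal(colnames(dm$X), c("(Intercept)", "t", "I(t^2)"))
  expect_equal(dim(dm$Z), c(4L, 4L))  # 2 watersheds + 2 counties
})

test_that("rows with missing required fields are dropped and counted", {
  set.seed(3)
  df <- data.frame(npp = exp(rnorm(10, 5, 1)),
                   x = rnorm(10),
                   watershed_id = rep(c("w1", "w2", "w3", "w4"),
                                      c(3, 2, 3, 2)),
                   county_id = rep(c("c1", "c2"), each = 5))
  df$x[4] <- NA
  dm <- build_design(df, log(npp) ~ x)
  expect_equal(length(dm$y), 9L)
  expect_equal(dm$n_dropped, 1L)
})

test_that("categorical terms expand against the declared reference", {
  df <- make_vc_panel(seed = 4, n_counties = 3,
                      watersheds_per_county = 10)$panel
  df$grassland_type <- relevel(factor(
    sample(c("ASAG", "ASAM", "DG", "MDW"), nrow(df), TRUE)), ref = "ASAG")
  dm <- build_design(df, log(npp) ~ grassland_type)
  dummies <- dm$X[, -1, drop = FALSE]
  expect_equal(ncol(dummies), 3L)
  expect_equal(unname(rowSums(dummies)),
               as.numeric(df$grassland_type != "ASAG"))
})

test_that("design errors are informative", {
  df <- make_vc_panel(seed = 5, n_counties = 3,
                      watersheds_per_county = 4)$panel
  expect_error(build_design(df, log(npp) ~ not_a_column), "not_a_column")
  df$z1 <- rnorm(nrow(df)); df$z2 <- 2 * df$z1
  expect_error(build_design(df, log(npp) ~ z1 + z2), "z2")
  dfbad <- df
  dfbad$county_id[dfbad$watershed_id == dfbad$watershed_id[1]] <-
    c("CX", "CY")
  expect_error(build_design(dfbad, log(npp) ~ 1), "nesting violation")
})

test_that("REML matches closed-form ANOVA estimators on balanced data", {
  for (s in 1:3) {
    bn <- balanced_nested_data(a = 6, m = 5, r = 4, seed = s)
    fit <- nested_lmm(y ~ 1, bn$data, method = "REML")
    expect_lt(rel_err(fit$vc$sigma2, bn$anova[["sigma2"]]), 1e-4)
    expect_lt(rel_err(fit$vc$tau_watershed[1, 1], bn$anova[["tau_w"]]), 1e-4)
    expect_lt(rel_err(fit$vc$tau_county[1, 1], bn$anova[["tau_c"]]), 1e-4)
  }
})

test_that("zero between-group signal drives tau to the boundary", {
  # identical group means everywhere: no between-group variance
  df <- data.frame(
    y = rep(c(-1, 0, 1), 8) + 5,
    watershed_id = rep(sprintf("w%d", 1:8), each = 3),
    county_id = rep(sprintf("c%d", 1:4), each = 6))
  fit <- nested_lmm(y ~ 1, df, method = "ML")
  expect_lt(fit$vc$tau_watershed[1, 1], 1e-6)
  expect_lt(fit$vc$tau_county[1, 1], 1e-6)
  n <- nrow(df)
  expect_equal(fit$vc$sigma2, var(df$y) * (n - 1) / n, tolerance = 1e-4)
})

test_that("marginal likelihood matches a dense multivariate-normal oracle", {
  # 5-observation toy evaluated against brute-force dense algebra
  df <- data.frame(y = c(1.2, 0.7, 2.1, 1.9, 1.4),
                   x = c(0, 1, 0, 1, 2),
                   watershed_id = c("w1", "w1", "w2", "w3", "w3"),
                   county_id = c("c1", "c1", "c1", "c2", "c2"))
  dm <- build_design(df, y ~ x)
  sigma2 <- 0.3; tw <- 0.8; tc <- 0.5
  beta <- c(1.0, 0.2)

  Zw <- outer(df$watershed_id, c("w1", "w2", "w3"), "==") * 1
  Zc <- outer(df$county_id, c("c1", "c2"), "==") * 1
  V <- sigma2 * diag(5) + tw * tcrossprod(Zw) + tc * tcrossprod(Zc)
  r <- df$y - cbind(1, df$x) %*% beta
  ll_dense <- -0.5 * (5 * log(2 * pi) +
                        determinant(V, logarithm = TRUE)$modulus +
                        t(r) %*% solve(V, r))
  ll_pkg <- loglik_at(dm, sigma2, tw, tc, beta)
  expect_equal(ll_pkg, as.numeric(ll_dense), tolerance = 1e-10)
})

test_that("with zero random effects the likelihood reduces to OLS", {
  df <- make_vc_panel(seed = 6, n_counties = 3,
                      watersheds_per_county = 4)$panel
  df$lnpp <- log(df$npp)
  ols <- lm(lnpp ~ 1, df)
  dm <- build_design(df, lnpp ~ 1)
  n <- nrow(df)
  s2_ml <- sum(resid(ols)^2) / n
  ll <- loglik_at(dm, s2_ml, matrix(0, 1, 1), matrix(0, 1, 1), coef(ols))
  expect_equal(ll, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("the fitted optimum dominates perturbed variance components", {
  gen <- make_vc_panel(seed = 7, n_counties = 5, watersheds_per_county = 6)
  fit <- nested_lmm(log(npp) ~ 1, gen$panel, method = "ML")
  ll_hat <- loglik_at(fit, fit$vc$sigma2, fit$vc$tau_watershed,
                      fit$vc$tau_county, coef(fit))
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  for (f in c(0.9, 1.1)) {
    ll_pert <- loglik_at(fit, fit$vc$sigma2 * f,
                         fit$vc$tau_watershed * f,
                         fit$vc$tau_county * f, coef(fit))
    expect_lte(ll_pert, ll_hat + 1e-8)
  }
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  for (s in 1:5) {
    gen <- make_vc_panel(seed = derive_seed(55, s),
                         n_counties = sample(4:6, 1),
                         watersheds_per_county = sample(4:7, 1),
                         sigma2 = runif(1, 0.1, 0.6),
                         tau_w = runif(1, 0.3, 1.5),
                         tau_c = runif(1, 0.2, 1.0),
                         obs_years = c(1988, 1995, 2000, 2005))
    p <- gen$panel
    p$time <- p$year - 1988
    fit <- nested_lmm(log(npp) ~ time, p, method = "ML")
    ref <- lme4::lmer(log(npp) ~ time + (1 | county_id / watershed_id),
                      data = p, REML = FALSE)
    expect_lt(max(rel_err(coef(fit), lme4::fixef(ref))), 1e-4)
    vc <- as.data.frame(lme4::VarCorr(ref))
    expect_lt(rel_err(fit$vc$tau_watershed[1, 1], vc$vcov[1]), 1e-3)
    expect_lt(rel_err(fit$vc$tau_county[1, 1], vc$vcov[2]), 1e-3)
    expect_lt(rel_err(fit$vc$sigma2, vc$vcov[3]), 1e-3)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  }
})

test_that("GLS fixed effects coincide for ML and REML at equal components", {
  gen <- make_vc_panel(seed = 16, n_counties = 4, watersheds_per_county = 5)
  dm <- build_design(gen$panel, log(npp) ~ 1)
  th <- c(0.3, -0.2)
  f_ml <- fit_lmm(dm, "ML", lmm_control(fix_theta = th))
  f_reml <- fit_lmm(dm, "REML", lmm_control(fix_theta = th))
  expect_equal(coef(f_ml), coef(f_reml), tolerance = 1e-12)
})

test_that("response shift moves only the intercept", {
  gen <- make_vc_panel(seed = 17, n_counties = 4, watersheds_per_county = 6)
  p <- gen$panel
  p$time <- p$year - 1988
  f1 <- nested_lmm(log(npp) ~ time, p)
  p2 <- p
  p2$npp <- p2$npp * exp(10)   # +10 on the log scale
  f2 <- nested_lmm(log(npp) ~ time, p2)
  expect_equal(unname(coef(f2)["(Intercept)"] - coef(f1)["(Intercept)"]),
               10, tolerance = 1e-6)
  expect_equal(unname(coef(f2)["time"]), unname(coef(f1)["time"]),
               tolerance = 1e-6)
  expect_equal(f2$vc$sigma2, f1$vc$sigma2, tolerance = 1e-6)
  expect_equal(f2$vc$tau_watershed, f1$vc$tau_watershed, tolerance = 1e-5)
})

test_that("likelihood-ratio machinery is arithmetically exact", {
  gen <- make_vc_panel(seed = 18, n_counties = 5, watersheds_per_county = 6,
                       tau_w = 1.5, tau_c = 0.8)
  p <- gen$panel
  p$time <- p$year - 1988
  full <- nested_lmm(log(npp) ~ time, p, method = "ML")
  red <- nested_lmm(log(npp) ~ 1, p, method = "ML")
  lr <- lr_test(full, red)
  expect_equal(lr$chi2, 2 * (full$loglik - red$loglik), tolerance = 1e-10)
  expect_equal(lr$df, 1L)

  # identical models: chi2 0, p 1
  lr0 <- lr_test(full, full)
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p_value, 1)

  # multilevel vs pooled OLS baseline
  ols <- lm(log(npp) ~ time, p)
  lr1 <- lr_test(full, ols)
  expect_equal(lr1$chi2, 2 * (full$loglik - as.numeric(logLik(ols))),
               tolerance = 1e-8)
  expect_equal(lr1$df, 2L)   # two variance components
  expect_lt(lr1$p_value, 1e-6)

  reml <- nested_lmm(log(npp) ~ time, p, method = "REML")
  expect_error(lr_test(reml, red), "REML")
})

test_that("null-vs-pooled chi-squared grows with group variance signal", {
  chi_at <- function(nW) {
    gen <- make_vc_panel(seed = 19, n_counties = 5,
                         watersheds_per_county = nW,
                         tau_w = 1.5, tau_c = 0.8)
    p <- gen$panel
    fit <- nested_lmm(log(npp) ~ 1, p, method = "ML")
    lr_test(fit, lm(log(npp) ~ 1, p))$chi2
  }
  expect_gt(chi_at(12), chi_at(4))
})

test_that("predictions follow the fitted fixed-effect surface", {
  gen <- make_vc_panel(seed = 21, n_counties = 4, watersheds_per_county = 6)
  p <- gen$panel
  p$time <- p$year - 1988

  f0 <- nested_lmm(log(npp) ~ 1, p)
  tr <- predict_trajectory(f0, profile = data.frame(dummy = 1),
                           time_grid = 0:24)
  expect_true(all(abs(tr$pred - coef(f0)[1]) < 1e-12))

  f2 <- nested_lmm(log(npp) ~ time + I(time^2), p)
  grid <- c(0, 5, 12, 24)
  tr2 <- predict_trajectory(f2, profile = data.frame(dummy = 1),
                            time_grid = grid)
  expect_equal(tr2$pred,
               unname(coef(f2)[1] + coef(f2)[2] * grid +
                        coef(f2)[3] * grid^2),
               tolerance = 1e-12)
  expect_error(predict(f2, newdata = data.frame(z = 1)), "time")
})

test_that("group-level predictions add the matched BLUPs", {
  gen <- make_vc_panel(seed = 22, n_counties = 4, watersheds_per_county = 5)
  p <- gen$panel
  fit <- nested_lmm(log(npp) ~ 1, p)
  nd <- data.frame(watershed_id = p$watershed_id[1],
                   county_id = p$county_id[1])
  pr <- predict(fit, newdata = nd, level = "group")
  manual <- coef(fit)[1] +
    fit$blups$watershed[p$watershed_id[1], "intercept"] +
    fit$blups$county[p$county_id[1], "intercept"]
  expect_equal(as.numeric(pr), unname(manual), tolerance = 1e-10)
})

test_that("fixed-effect confidence intervals attain nominal coverage", {
  # 500 small panels; coverage of the (truly zero) time slope, whose
  # effective degrees of freedom are large enough for the reported
  # asymptotic-z intervals (the intercept at 8 counties is not: its
  # effective df is the county count)
  n_rep <- 500
  cover <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    gen <- make_vc_panel(seed = derive_seed(700, k), n_counties = 8,
                         watersheds_per_county = 5,
                         sigma2 = 0.3, tau_w = 0.8, tau_c = 0.4,
                         obs_years = c(1988, 1995, 2000, 2005))
    p <- gen$panel
    p$time <- p$year - 1988
    fit <- nested_lmm(log(npp) ~ time, p, method = "REML")
    cover[k] <- abs(coef(fit)["time"] - 0) <= qnorm(0.975) * fit$se["time"]
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})
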