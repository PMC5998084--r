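#' Configuration for the synthetic multilevel NPP panel generator
#'
#' Describes a study region in which watersheds are nested in counties and
#' grassland NPP is observed in a fixed set of calendar years.  Defaults
#' emulate the structure of the motivating study region: 18 counties,
#' 1,817 watersheds, six unevenly spaced observation years between 1988
#' and 2012, a log-scale response with quadratic time trend, random
#' intercept-and-slope heterogeneity at both levels, and about 2.2%
#' missing observations.
#'
#' @param n_counties number of counties.
#' @param watersheds_per_county scalar or length-`n_counties` vector;
#'   default distributes 1,817 watersheds over 18 counties.
#' @param obs_years strictly increasing calendar years.
#' @param fixed_effects named coefficient vector on the standardized-
#'   covariate scale; see [npp_true_effects()] for names and defaults.
#' @param sigma2_resid residual variance of log-NPP.
#' @param tau_watershed,tau_county random-effect covariance at each level:
#'   a scalar (random intercept only) or a 2x2 matrix over
#'   (intercept, time slope).  Must be symmetric positive semi-definite.
#' @param covariate_sds,covariate_means per-covariate dispersion/location
#'   of the simulated (independent Gaussian) drivers; SDs default to
#'   [npp_sd_defaults()].
#' @param grassland_type_probs sampling proportions of the four grassland
#'   types (meadow MDW kept rare by default).
#' @param nnr_prob probability a watershed lies inside a national nature
#'   reserve.
#' @param missing_rate fraction of watershed-year cells dropped completely
#'   at random, in [0, 1).
#' @param seed integer seed; identical seeds give identical panels.
#' @return a list of class `"synthetic_config"`.
#' @export
panel_config <- function(n_counties = 18L,
                         watersheds_per_county = NULL,
                         obs_years = c(1988, 1995, 2000, 2005, 2008, 2012),
                         fixed_effects = npp_true_effects(),
                         sigma2_resid = 0.160,
                         tau_watershed = matrix(c(1.781, 0, 0, 0.002), 2),
                         tau_county = matrix(c(1.354, 0, 0, 0.001), 2),
                         covariate_sds = npp_sd_defaults(),
                         covariate_means = npp_mean_defaults(),
                         grassland_type_probs = c(ASAG = 0.40, ASAM = 0.45,
                                                  DG = 0.146, MDW = 0.004),
                         nnr_prob = 0.4,
                         missing_rate = 239 / 10902,
                         seed = 1L) {
  if (is.null(watersheds_per_county)) {
    base <- 1817L %/% n_counties
    extra <- 1817L %% n_counties
    watersheds_per_county <- rep(base, n_counties) +
      c(rep(1L, extra), rep(0L, n_counties - extra))
  }
  if (length(watersheds_per_county) == 1L)
    watersheds_per_county <- rep(watersheds_per_county, n_counties)
  stopifnot(length(watersheds_per_county) == n_counties,
            all(watersheds_per_county >= 1))
  if (is.unsorted(obs_years, strictly = TRUE))
    stop("obs_years must be strictly increasing")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (sigma2_resid < 0) stop("sigma2_resid must be non-negative")
  check_tau <- function(m, nm) {
    m <- as.matrix(m)
    if (!nrow(m) %in% 1:2 || nrow(m) != ncol(m))
      stop(nm, " must be a scalar or a 2x2 matrix")
    if (max(abs(m - t(m))) > 1e-10) stop(nm, " is not symmetric")
    if (any(eigen(m, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop(nm, " is not positive semi-definite")
    m
  }
  structure(list(
    n_counties = as.integer(n_counties),
    watersheds_per_county = as.integer(watersheds_per_county),
    obs_years = obs_years,
    fixed_effects = fixed_effects,
    sigma2_resid = sigma2_resid,
    tau_watershed = check_tau(tau_watershed, "tau_watershed"),
    tau_county = check_tau(tau_county, "tau_county"),
    covariate_sds = covariate_sds,
    covariate_means = covariate_means,
    grassland_type_probs = grassland_type_probs / sum(grassland_type_probs),
    nnr_prob = nnr_prob,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default generative coefficients (standardized-covariate scale)
#'
#' Named per-one-SD effects of each driver on log-NPP used by
#' [generate_panel()].  Time is in years since the first observation year;
#' grassland-type effects are offsets from the reference type ASAG, and
#' `nnr` is an inside-reserve dummy.  Values follow the reported growth-
#' model estimates where published (e.g. gdp -0.093, hpd -0.299,
#' meat 0.146, grassland_pct 0.033, time x grassland_pct -0.003,
#' grassland_pct x gdp -0.021) and plausible modest magnitudes with the
#' reported signs elsewhere (negative time x precipitation, positive
#' time x temperature, hump-shaped climate responses).
#'
#' @return named numeric vector.
#' @export
npp_true_effects <- function() {
  c(intercept = 5.135, time = 0.000, time2 = 0.001,
    precipitation = 0.10, precipitation2 = -0.02,
    temperature = 0.08, temperature2 = -0.02,
    sunlight = 0.05, sunlight2 = 0.01,
    grassland_pct = 0.033,
    gt_ASAM = 0.20, gt_DG = -0.80, gt_MDW = 0.30,
    nnr = 0.03,
    dem = -0.05, slope = -0.02,
    soil_n = 0.02, soil_p = 0.01, soil_k = 0.02,
    d2water = -0.03, d2highway = -0.01, d2village = -0.01,
    gdp = -0.093, hpd = -0.299, meat = 0.146,
    time_x_precipitation = -0.010, time_x_temperature = 0.010,
    time_x_sunlight = 0.0005, time_x_grassland_pct = -0.003,
    time_x_gt_ASAM = 0.003, time_x_gt_DG = 0.045, time_x_gt_MDW = -0.133,
    time_x_nnr = -0.005,
    gpct_x_gdp = -0.021, gpct_x_hpd = -0.009, gpct_x_meat = 0.006)
}

#' Default covariate means for the generator
#'
#' Locations of the simulated Gaussian drivers (units as in
#' [npp_sd_defaults()]).  The growth models consume standardized
#' covariates, so these affect only the raw columns, not recovery of
#' coefficients.
#' @return named numeric vector.
#' @export
npp_mean_defaults <- function() {
  c(precipitation = 450, temperature = -2, sunlight = 2550,
    grassland_pct = 60, dem = 4500, slope = 10,
    soil_k = 40, soil_n = 0.2, soil_p = 0.05,
    d2water = 30, d2highway = 200, d2village = 60,
    gdp = 300, hpd = 10, meat = 5)
}

#' Generative parameters in fit-result naming
#'
#' Returns the ground-truth parameters of a configuration in the same
#' structure a fitted model reports, so recovery comparisons are direct:
#' fixed effects, variance components (as matrices over intercept/slope),
#' and the implied intercept-component ICC decomposition.
#'
#' @param config a [panel_config()].
#' @return list with `fixed_effects`, `sigma2`, `tau_watershed`,
#'   `tau_county`, `icc` (an `"icc_decomposition"`).
#' @export
true_values <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tot <- config$sigma2_resid + config$tau_watershed[1L, 1L] +
    config$tau_county[1L, 1L]
  list(fixed_effects = config$fixed_effects,
       sigma2 = config$sigma2_resid,
       tau_watershed = config$tau_watershed,
       tau_county = config$tau_county,
       icc = if (tot > 0)
         icc_from_components(config$sigma2_resid,
                             config$tau_watershed[1L, 1L],
                             config$tau_county[1L, 1L])
       else NULL)
}

## lower Cholesky factor tolerant of exact zeros / PSD boundaries
psd_lower <- function(m) {
  out <- tryCatch(t(chol(m)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  es <- eigen(m, symmetric = TRUE)
  es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow(m)) %*% t(es$vectors)
}

#' Generate a synthetic multilevel NPP panel with known ground truth
#'
#' Simulates the full generative model: independent Gaussian covariates
#' with configured means/SDs (climate and grassland share varying by
#' watershed-year, watershed characteristics constant over time,
#' socioeconomic indicators varying by county-year), categorical grassland
#' type and reserve membership per watershed, then
#' \deqn{\log NPP = X\beta + b_{county} + b_{watershed} + \epsilon}
#' with the fixed predictor built from standardized covariates, random
#' intercept(-and-slope) draws at both levels, and i.i.d. Gaussian
#' residuals; NPP is returned on the natural scale by exponentiation.
#' Watershed-year cells are then dropped completely at random at the
#' configured rate.
#'
#' @param config a [panel_config()].
#' @return list with `panel` (data frame: `watershed_id`, `county_id`,
#'   `year`, `npp`, covariates, `grassland_type`, `nnr_zone`, `nnr`) and
#'   `truth` (the [true_values()] list plus the exact random-effect draws
#'   `county_effects`, `watershed_effects`, the per-row `linear_predictor`
#'   and residuals, all pre-missingness).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nC <- config$n_counties
  wpc <- config$watersheds_per_county
  nW <- sum(wpc)
  years <- config$obs_years
  nT <- length(years)
  tvals <- years - years[1L]

  county_id <- sprintf("C%02d", seq_len(nC))
  watershed_county <- rep(seq_len(nC), wpc)
  watershed_id <- sprintf("W%04d", seq_len(nW))

  ## long skeleton: watershed x year
  idx_w <- rep(seq_len(nW), each = nT)
  idx_c <- watershed_county[idx_w]
  year <- rep(years, times = nW)
  tt <- rep(tvals, times = nW)
  n <- length(idx_w)

  mu <- config$covariate_means
  sds <- config$covariate_sds
  rnorm_cov <- function(nm, ndraw) stats::rnorm(ndraw, mu[[nm]], sds[[nm]])

  ## watershed-year covariates
  climate <- c("precipitation", "temperature", "sunlight")
  panel <- data.frame(watershed_id = watershed_id[idx_w],
                      county_id = county_id[idx_c],
                      year = year, stringsAsFactors = FALSE)
  for (nm in climate) panel[[nm]] <- rnorm_cov(nm, n)
  panel$grassland_pct <- pmin(pmax(rnorm_cov("grassland_pct", n), 0), 100)

  ## watershed-constant covariates
  wconst <- c("dem", "slope", "soil_n", "soil_p", "soil_k",
              "d2water", "d2highway", "d2village")
  for (nm in wconst) panel[[nm]] <- rnorm_cov(nm, nW)[idx_w]

  ## county-year covariates
  cyear <- c("gdp", "hpd", "meat")
  for (nm in cyear) {
    draws <- matrix(rnorm_cov(nm, nC * nT), nC, nT)
    panel[[nm]] <- draws[cbind(idx_c, rep(seq_len(nT), times = nW))]
  }

  ## categorical watershed attributes
  gt_levels <- names(config$grassland_type_probs)
  gt_w <- sample(gt_levels, nW, replace = TRUE,
                 prob = config$grassland_type_probs)
  panel$grassland_type <- factor(gt_w[idx_w], levels = gt_levels)
  in_nnr <- stats::runif(nW) < config$nnr_prob
  zone_w <- ifelse(in_nnr,
                   sample(c("core", "buffer", "trial"), nW, replace = TRUE,
                          prob = c(0.3, 0.3, 0.4)),
                   "outside")
  panel$nnr_zone <- factor(zone_w[idx_w],
                           levels = c("outside", "core", "buffer", "trial"))
  panel$nnr <- as.integer(panel$nnr_zone != "outside")

  ## fixed linear predictor on the standardized scale
  z <- function(nm) (panel[[nm]] - mu[[nm]]) / sds[[nm]]
  fe <- config$fixed_effects
  g <- function(nm) if (nm %in% names(fe)) fe[[nm]] else 0
  zg <- z("grassland_pct")
  eta <- g("intercept") + g("time") * tt + g("time2") * tt^2 +
    g("precipitation") * z("precipitation") +
    g("precipitation2") * z("precipitation")^2 +
    g("temperature") * z("temperature") +
    g("temperature2") * z("temperature")^2 +
    g("sunlight") * z("sunlight") + g("sunlight2") * z("sunlight")^2 +
    g("grassland_pct") * zg +
    g("dem") * z("dem") + g("slope") * z("slope") +
    g("soil_n") * z("soil_n") + g("soil_p") * z("soil_p") +
    g("soil_k") * z("soil_k") +
    g("d2water") * z("d2water") + g("d2highway") * z("d2highway") +
    g("d2village") * z("d2village") +
    g("gdp") * z("gdp") + g("hpd") * z("hpd") + g("meat") * z("meat") +
    g("nnr") * panel$nnr +
    g("time_x_precipitation") * tt * z("precipitation") +
    g("time_x_temperature") * tt * z("temperature") +
    g("time_x_sunlight") * tt * z("sunlight") +
    g("time_x_grassland_pct") * tt * zg +
    g("time_x_nnr") * tt * panel$nnr +
    g("gpct_x_gdp") * zg * z("gdp") +
    g("gpct_x_hpd") * zg * z("hpd") +
    g("gpct_x_meat") * zg * z("meat")
  for (lev in setdiff(gt_levels, "ASAG")) {
    ind <- as.numeric(panel$grassland_type == lev)
    eta <- eta + g(paste0("gt_", lev)) * ind +
      g(paste0("time_x_gt_", lev)) * tt * ind
  }

  ## random effects: columns (intercept, slope)
  draw_effects <- function(tau, k) {
    d <- nrow(tau)
    L <- psd_lower(tau)
    raw <- matrix(stats::rnorm(d * k), d, k)
    eff <- t(L %*% raw)
    if (d == 1L) eff <- cbind(eff, 0)
    colnames(eff) <- c("intercept", "slope")
    eff
  }
  eff_c <- draw_effects(config$tau_county, nC)
  rownames(eff_c) <- county_id
  eff_w <- draw_effects(config$tau_watershed, nW)
  rownames(eff_w) <- watershed_id

  re <- eff_c[idx_c, "intercept"] + eff_c[idx_c, "slope"] * tt +
    eff_w[idx_w, "intercept"] + eff_w[idx_w, "slope"] * tt
  resid <- stats::rnorm(n, 0, sqrt(config$sigma2_resid))
  log_npp <- eta + re + resid
  panel$npp <- exp(log_npp)

  keep <- stats::runif(n) >= config$missing_rate
  truth <- true_values(config)
  truth$county_effects <- eff_c
  truth$watershed_effects <- eff_w
  truth$linear_predictor <- eta
  truth$random_part <- re
  truth$residuals <- resid
  truth$n_possible <- n
  truth$n_observed <- sum(keep)

  list(panel = panel[keep, , drop = FALSE], truth = truth)
}

#' Generate a synthetic gridded NPP time series with land-use change
#'
#' Builds a pixel grid whose NPP series is `intercept + slope * t + noise`
#' per pixel, together with start/end land-use layers realising requested
#' fractions of retained grassland, grassland converted in (other to
#' grass) and converted out (grass to other); remaining pixels are
#' non-grassland throughout.  A plain-array fixture for the trend and
#' change-accounting machinery.
#'
#' @param shape integer c(rows, cols).
#' @param n_years number of annual layers (>= 2).
#' @param intercept baseline NPP (gC m^-2).
#' @param slope true per-step trend: a scalar or a `shape` matrix.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param conversion_fractions named fractions `retained`, `converted_in`,
#'   `converted_out`, each in [0,1], summing to at most 1.
#' @param cell_area area of one pixel, km^2.
#' @param seed integer seed.
#' @return list of class `"synthetic_grid"`: `npp_stack` (rows x cols x
#'   years array), `landuse_start`, `landuse_end` (character matrices of
#'   `"grass"`/`"other"`), `true_slope_field`, `cell_area`.
#' @export
generate_grid <- function(shape = c(50L, 50L), n_years = 6L,
                          intercept = 250, slope = 2, noise_sd = 10,
                          conversion_fractions = c(retained = 0.9,
                                                   converted_in = 0.04,
                                                   converted_out = 0.04),
                          cell_area = 1, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1), n_years >= 2L,
            cell_area > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  cf <- conversion_fractions
  need <- c("retained", "converted_in", "converted_out")
  if (!all(need %in% names(cf)))
    stop("conversion_fractions must name: ", paste(need, collapse = ", "))
  cf <- cf[need]
  if (any(cf < 0) || any(cf > 1) || sum(cf) > 1 + 1e-12)
    stop("conversion fractions must lie in [0,1] and sum to at most 1")

  set.seed(seed)
  npix <- prod(shape)
  slope_field <- if (length(slope) == 1L) {
    matrix(slope, shape[1L], shape[2L])
  } else {
    stopifnot(all(dim(slope) == shape))
    slope
  }
  tt <- seq_len(n_years)
  stack <- array(NA_real_, c(shape, n_years))
  for (k in tt) {
    stack[, , k] <- intercept + slope_field * k +
      matrix(stats::rnorm(npix, 0, noise_sd), shape[1L], shape[2L])
  }

  counts <- round(cf * npix)
  ## integer rounding may overflow the grid by at most length(counts)-1
  while (sum(counts) > npix) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  cls <- rep(c("retained", "converted_in", "converted_out", "never"),
             c(counts, npix - sum(counts)))
  cls <- sample(cls)
  lu_start <- matrix(ifelse(cls %in% c("retained", "converted_out"),
                            "grass", "other"), shape[1L], shape[2L])
  lu_end <- matrix(ifelse(cls %in% c("retained", "converted_in"),
                          "grass", "other"), shape[1L], shape[2L])

  structure(list(npp_stack = stack, landuse_start = lu_start,
                 landuse_end = lu_end, true_slope_field = slope_field,
                 cell_area = cell_area),
            class = "synthetic_grid")
}
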