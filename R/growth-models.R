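#' Reference covariate dispersions for standardization
#'
#' Standard deviations used to express growth-model coefficients as the
#' proportional change in NPP per one-SD change in each driver: climate
#' (precipitation in mm, temperature in degrees C, sunlight hours),
#' watershed characteristics (grassland area percent, elevation in m,
#' slope in degrees, soil N/P/K percent, distances to water / highway /
#' village in km) and county socioeconomic indicators (GDP in million CNY,
#' human population density in thousand persons per km2, meat production
#' in thousand tons).
#'
#' @return named numeric vector of standard deviations.
#' @export
npp_sd_defaults <- function() {
  c(precipitation = 158.5, temperature = 2.28, sunlight = 201.05,
    grassland_pct = 23.99, dem = 395.18, slope = 5.8,
    soil_k = 37.17, soil_n = 0.17, soil_p = 0.01,
    d2water = 28.12, d2highway = 196.65, d2village = 55.76,
    gdp = 149, hpd = 30.6, meat = 2.66)
}

#' Standardize panel covariates to z-scores
#'
#' Replaces each listed covariate x by (x - mean) / SD so fitted
#' coefficients read as the response change per one-SD change in the
#' driver.  The response and the time variable are left untouched (the
#' growth models log-transform NPP in their formulas).  The applied means
#' and SDs are recorded in attributes for exact back-conversion.
#'
#' @param panel a panel data frame.
#' @param sd_table named numeric vector of SDs; default [npp_sd_defaults()].
#'   Only names present in the panel are used.
#' @param mean_table named numeric vector of centering means; defaults to
#'   the observed column means.
#' @return the panel with standardized covariate columns and attributes
#'   `"standardize_means"` / `"standardize_sds"`.
#' @seealso [unstandardize()]
#' @export
standardize_covariates <- function(panel, sd_table = npp_sd_defaults(),
                                   mean_table = NULL) {
  vars <- intersect(names(sd_table), names(panel))
  if (any(sd_table[vars] <= 0))
    stop("non-positive SD for covariate(s): ",
         paste(vars[sd_table[vars] <= 0], collapse = ", "))
  means <- numeric(0)
  for (v in vars) {
    m <- if (!is.null(mean_table) && v %in% names(mean_table))
      mean_table[[v]] else mean(panel[[v]], na.rm = TRUE)
    panel[[v]] <- (panel[[v]] - m) / sd_table[[v]]
    means[v] <- m
  }
  attr(panel, "standardize_means") <- means
  attr(panel, "standardize_sds") <- sd_table[vars]
  panel
}

#' Invert [standardize_covariates()]
#'
#' @param panel a panel previously returned by [standardize_covariates()].
#' @return the panel with covariates restored to their original scale.
#' @export
unstandardize <- function(panel) {
  means <- attr(panel, "standardize_means")
  sds <- attr(panel, "standardize_sds")
  if (is.null(means) || is.null(sds))
    stop("panel carries no standardization attributes")
  for (v in names(means)) panel[[v]] <- panel[[v]] * sds[[v]] + means[[v]]
  attr(panel, "standardize_means") <- NULL
  attr(panel, "standardize_sds") <- NULL
  panel
}

## adds the time coding used throughout the ladder: T = year - origin
add_time <- function(panel, origin = 1988) {
  if (!"year" %in% names(panel)) stop("panel must contain a `year` column")
  panel$time <- panel$year - origin
  panel
}

#' Two-level empty (null) model for log-NPP
#'
#' Intercept-only model with random intercepts for watersheds nested in
#' counties and no predictors: the variance-decomposition baseline whose
#' components feed [icc()] (what share of log-NPP variation sits between
#' counties, between watersheds within county, and within watershed over
#' time).
#'
#' @param panel a panel data frame with columns `npp`, `watershed_id`,
#'   `county_id`.
#' @param method `"ML"` (default) or `"REML"`.
#' @param ... passed to [nested_lmm()].
#' @return a `"nested_lmm"` fit.
#' @export
null_model <- function(panel, method = "ML", ...) {
  nested_lmm(log(npp) ~ 1, panel, random = "intercept", method = method, ...)
}

#' Unconditional three-level growth model
#'
#' Fixed quadratic time trend (intercept, T, T^2 with T = year - origin)
#' and random intercepts (default) or correlated intercept + slope at both
#' the watershed and county level; no covariates.
#'
#' @inheritParams null_model
#' @param origin calendar year at which T = 0 (default 1988, the first
#'   observation year).
#' @param random `"intercept"` or `"slope"`.
#' @return a `"nested_lmm"` fit.
#' @export
unconditional_growth <- function(panel, origin = 1988,
                                 random = c("intercept", "slope"),
                                 method = "ML", ...) {
  random <- match.arg(random)
  panel <- add_time(panel, origin)
  if (length(unique(panel$time)) < 3L)
    stop("need at least 3 distinct time points for a quadratic growth model")
  nested_lmm(log(npp) ~ time + I(time^2), panel, random = random,
             time = "time", method = method, ...)
}

## the stepwise term ladder; each step adds to the previous one
growth_step_terms <- function(step) {
  steps <- list(
    `2` = c("precipitation", "I(precipitation^2)", "temperature",
            "I(temperature^2)", "sunlight", "I(sunlight^2)"),
    `3` = c("grassland_pct", "grassland_type", "nnr",
            "time:grassland_pct", "time:grassland_type", "time:nnr"),
    `4` = c("dem", "slope", "soil_n", "soil_p", "soil_k",
            "d2water", "d2highway", "d2village"),
    `5` = c("gdp", "hpd", "meat"),
    `6` = c("time:precipitation", "time:temperature", "time:sunlight",
            "grassland_pct:gdp", "grassland_pct:hpd", "grassland_pct:meat")
  )
  unlist(steps[as.character(2:step)], use.names = FALSE)
}

#' Stepwise conditional three-level growth models
#'
#' Extends the unconditional growth model with blocks of explanatory
#' variables in the order climate, grassland, watershed characteristics,
#' socioeconomic, cross-level interactions:
#' \describe{
#'   \item{step 2}{climate main effects and quadratics (precipitation,
#'     temperature, sunlight).}
#'   \item{step 3}{grassland area percentage, grassland-type dummies
#'     (reference ASAG), nature-reserve dummy, and their interactions with
#'     time.}
#'   \item{step 4}{watershed characteristics: elevation, slope, soil
#'     N/P/K, distances to water, highway and village.}
#'   \item{step 5}{county socioeconomic main effects: GDP, population
#'     density, meat production.}
#'   \item{step 6}{time-by-climate and grassland-by-socioeconomic
#'     interactions (the full model).}
#' }
#' Covariates are z-standardized via [standardize_covariates()] unless
#' `standardize = FALSE`, so coefficients read per one-SD change.
#'
#' @inheritParams unconditional_growth
#' @param step integer in 2..6: the last block included.
#' @param terms optional character vector overriding the default term
#'   ladder (the exact step membership is configurable because different
#'   analyses group drivers differently).
#' @param standardize logical; standardize covariates before fitting.
#' @param sd_table passed to [standardize_covariates()].
#' @return a `"nested_lmm"` fit; the term list used is attached as
#'   attribute `"step_terms"` on the returned object (`$step`, `$terms`).
#' @export
conditional_growth <- function(panel, step, origin = 1988,
                               random = c("intercept", "slope"),
                               method = "ML", terms = NULL,
                               standardize = TRUE,
                               sd_table = npp_sd_defaults(), ...) {
  random <- match.arg(random)
  if (!is.numeric(step) || length(step) != 1L || step < 2 || step > 6)
    stop("step must be a single integer between 2 and 6")
  step <- as.integer(step)
  panel <- add_time(panel, origin)
  if (standardize) panel <- standardize_covariates(panel, sd_table)
  if ("grassland_type" %in% names(panel)) {
    panel$grassland_type <- stats::relevel(factor(panel$grassland_type),
                                           ref = "ASAG")
  }
  if ("nnr" %in% names(panel) && !is.numeric(panel$nnr)) {
    panel$nnr <- as.integer(panel$nnr %in% c("in", "core", "buffer", "trial",
                                             "TRUE", "1"))
  }
  if (is.null(terms)) terms <- growth_step_terms(step)
  fml <- stats::reformulate(c("time", "I(time^2)", terms),
                            response = quote(log(npp)))
  environment(fml) <- environment()
  fit <- nested_lmm(fml, panel, random = random,
                    time = if (random == "slope") "time" else NULL,
                    method = method, ...)
  fit$step <- step
  fit$terms_used <- terms
  fit
}

#' Intraclass correlation decomposition of a three-level fit
#'
#' Shares of total log-NPP variance attributable to each level, computed
#' from the intercept variance components only (slope variances are
#' excluded even when random slopes were fitted):
#' \deqn{ICC_w = \tau_{00,w} / (\sigma^2 + \tau_{00,w} + \tau_{00,c})}
#' and likewise for the county level; the residual share is the
#' complement.
#'
#' @param fit a `"nested_lmm"` fit, or omit and supply components directly
#'   via [icc_from_components()].
#' @return a list of class `"icc_decomposition"` with `icc_watershed`,
#'   `icc_county`, `residual_share` (summing to 1) and `components_used`.
#' @export
icc <- function(fit) {
  if (!inherits(fit, "nested_lmm")) stop("fit must be a nested_lmm object")
  icc_from_components(sigma2 = fit$vc$sigma2,
                      tau_watershed = fit$vc$tau_watershed[1L, 1L],
                      tau_county = fit$vc$tau_county[1L, 1L])
}

#' @rdname icc
#' @param sigma2 residual (within-watershed, over-time) variance.
#' @param tau_watershed,tau_county intercept variance at each level.
#' @export
icc_from_components <- function(sigma2, tau_watershed, tau_county) {
  if (any(c(sigma2, tau_watershed, tau_county) < 0))
    stop("variance components must be non-negative")
  tot <- sigma2 + tau_watershed + tau_county
  if (tot <= 0) stop("total variance is zero; ICC undefined")
  out <- list(icc_watershed = tau_watershed / tot,
              icc_county = tau_county / tot,
              residual_share = sigma2 / tot,
              components_used = c(sigma2 = sigma2,
                                  tau_watershed = tau_watershed,
                                  tau_county = tau_county))
  class(out) <- "icc_decomposition"
  out
}

#' @export
print.icc_decomposition <- function(x, digits = 4, ...) {
  cat("Variance decomposition (intercept components):\n")
  cat("  watershed share:", format(x$icc_watershed, digits = digits), "\n")
  cat("  county share:   ", format(x$icc_county, digits = digits), "\n")
  cat("  residual share: ", format(x$residual_share, digits = digits), "\n")
  invisible(x)
}

#' Proportional reduction in variance components between two fits
#'
#' For each component (watershed intercept variance, county intercept
#' variance, residual variance) returns (a - b) / a: the fraction of that
#' component in `fit_a` explained away by the extra terms in `fit_b` —
#' the usual comparison down a stepwise model ladder.
#'
#' @param fit_a,fit_b `"nested_lmm"` fits on the same rows (a = reference,
#'   typically the earlier/smaller model).
#' @return named numeric vector with elements `watershed`, `county`,
#'   `within` (residual).
#' @export
variance_shares <- function(fit_a, fit_b) {
  if (fit_a$n_obs != fit_b$n_obs)
    stop("fits use different numbers of rows; not comparable")
  comp <- function(f) c(watershed = f$vc$tau_watershed[1L, 1L],
                        county = f$vc$tau_county[1L, 1L],
                        within = f$vc$sigma2)
  a <- comp(fit_a); b <- comp(fit_b)
  (a - b) / a
}
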