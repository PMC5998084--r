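#' @export
print.nested_lmm <- function(x, digits = 4, ...) {
  cat("Nested linear mixed model (", x$method, ")\n", sep = "")
  cat("  formula: ", deparse(x$design$formula), "\n", sep = "")
  cat("  groups:  ", x$n_watersheds, " watersheds in ", x$n_counties,
      " counties; ", x$n_obs, " observations", sep = "")
  if (x$n_dropped > 0)
    cat(" (", x$n_dropped, " rows dropped for missingness)", sep = "")
  cat("\n  logLik ", format(x$loglik, digits = digits),
      "   AIC ", format(x$aic, digits = digits),
      if (!x$converged) "   [NOT CONVERGED]", "\n", sep = "")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  cat("Variance components:\n")
  cat("  sigma2 (residual):", format(x$vc$sigma2, digits = digits), "\n")
  cat("  tau (watershed):\n")
  print(round(x$vc$tau_watershed, digits))
  cat("  tau (county):\n")
  print(round(x$vc$tau_county, digits))
  invisible(x)
}

#' Summarise a nested mixed-model fit
#'
#' @param object a `"nested_lmm"` fit.
#' @param ... unused.
#' @return a list with the coefficient table (estimate, SE, asymptotic z,
#'   two-sided p), variance components, ICC decomposition and fit indices.
#' @export
summary.nested_lmm <- function(object, ...) {
  z <- object$t_values
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, vc = object$vc, icc = icc(object),
              loglik = object$loglik, aic = object$aic,
              n_obs = object$n_obs, n_watersheds = object$n_watersheds,
              n_counties = object$n_counties, method = object$method,
              converged = object$converged, call = object$call)
  class(out) <- "summary.nested_lmm"
  out
}

#' @export
print.summary.nested_lmm <- function(x, digits = 4, ...) {
  cat("Nested linear mixed model (", x$method, ")\n", sep = "")
  cat("Observations: ", x$n_obs, "  Watersheds: ", x$n_watersheds,
      "  Counties: ", x$n_counties, "\n", sep = "")
  cat("logLik: ", format(x$loglik, digits = digits),
      "  AIC: ", format(x$aic, digits = digits), "\n\n", sep = "")
  cat("Fixed effects (z statistics are asymptotic):\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nVariance components:\n")
  cat("  residual sigma2          :", format(x$vc$sigma2, digits = digits), "\n")
  cat("  watershed intercept var  :",
      format(x$vc$tau_watershed[1, 1], digits = digits), "\n")
  cat("  county intercept var     :",
      format(x$vc$tau_county[1, 1], digits = digits), "\n")
  cat("\nIntraclass correlations (intercept components):\n")
  cat("  watershed:", format(x$icc$icc_watershed, digits = digits),
      "  county:", format(x$icc$icc_county, digits = digits),
      "  residual:", format(x$icc$residual_share, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.nested_lmm <- function(object, ...) object$coefficients

#' @export
vcov.nested_lmm <- function(object, ...) object$vcov

#' @export
logLik.nested_lmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.nested_lmm <- function(object, ...) object$fitted

#' @export
residuals.nested_lmm <- function(object,
                                 type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "conditional") return(object$residuals)
  dm <- object$design
  dm$y - as.numeric(dm$X %*% object$coefficients)
}

#' Random-effect predictions (BLUPs) per level
#'
#' @param object a `"nested_lmm"` fit.
#' @param level `"watershed"` or `"county"`.
#' @param ... unused.
#' @return a matrix with one row per group and one column per random term.
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @rdname ranef
#' @export
ranef.nested_lmm <- function(object, level = c("watershed", "county"), ...) {
  level <- match.arg(level)
  object$blups[[level]]
}

#' Predict from a nested mixed-model fit
#'
#' @param object a `"nested_lmm"` fit.
#' @param newdata data frame supplying every model term; when omitted the
#'   training rows are used.
#' @param level `"population"` for the fixed-effects-only prediction, or
#'   `"group"` to add the BLUPs of the watershed/county identified by the
#'   grouping columns in `newdata` (unseen groups contribute zero).
#' @param ... unused.
#' @return numeric vector of predictions on the (transformed) response
#'   scale, with an attribute `"level"` recording which was produced.
#' @export
predict.nested_lmm <- function(object, newdata = NULL,
                               level = c("population", "group"), ...) {
  level <- match.arg(level)
  dm <- object$design
  if (is.null(newdata)) {
    X <- dm$X
    wid <- as.character(dm$watershed_index)
    cid <- as.character(dm$county_index)
    tval <- if (dm$random == "slope")
      as.numeric(dm$Z[, dm$levels$watershed$cols[2L]] * 0) else NULL
  } else {
    tt <- stats::delete.response(dm$terms)
    needed <- all.vars(tt)
    missing_terms <- setdiff(needed, names(newdata))
    if (length(missing_terms))
      stop("newdata is missing model term(s): ",
           paste(missing_terms, collapse = ", "))
    mf <- stats::model.frame(tt, newdata, xlev = dm$xlevels)
    X <- stats::model.matrix(tt, mf)
    wid <- if ("watershed_id" %in% names(newdata) ||
               !is.null(newdata[["watershed_id"]]))
      as.character(newdata[["watershed_id"]]) else NULL
    cid <- as.character(newdata[["county_id"]])
    if (length(cid) == 0L) cid <- NULL
  }
  pred <- as.numeric(X %*% object$coefficients)
  if (level == "group") {
    add_blup <- function(ids, blup_mat) {
      if (is.null(ids)) return(0)
      out <- numeric(length(ids))
      hit <- ids %in% rownames(blup_mat)
      if (any(hit)) {
        bm <- blup_mat[ids[hit], , drop = FALSE]
        contrib <- bm[, "intercept"]
        if (ncol(bm) == 2L && !is.null(newdata) &&
            !is.null(dm$time) && dm$time %in% names(newdata)) {
          contrib <- contrib + bm[, "slope"] * as.numeric(newdata[[dm$time]][hit])
        }
        out[hit] <- contrib
      }
      out
    }
    if (is.null(newdata)) {
      b <- as.numeric(object$fitted) # fitted already includes BLUPs
      pred <- b
    } else {
      pred <- pred + add_blup(wid, object$blups$watershed) +
        add_blup(cid, object$blups$county)
    }
  }
  attr(pred, "level") <- level
  pred
}

#' Simulate responses from a fitted nested mixed model
#'
#' Draws new county and watershed random effects from the estimated
#' covariance components and new residuals from the estimated residual
#' variance, added to the fixed-effect predictor of the training design.
#'
#' @param object a `"nested_lmm"` fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame with `nsim` columns, one simulated response per row
#'   of the original data (on the transformed response scale).
#' @export
simulate.nested_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dm <- object$design
  n <- length(dm$y)
  mu <- as.numeric(dm$X %*% object$coefficients)
  d <- dm$levels$watershed$dim
  draw_level <- function(tau, lev) {
    k <- lev$n_groups
    L <- t(chol(tau + diag(1e-12, nrow(tau))))
    b <- L %*% matrix(stats::rnorm(nrow(tau) * k), nrow(tau), k)
    as.numeric(b)   # column-major: per group (intercept[, slope])
  }
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    bw <- draw_level(object$vc$tau_watershed, dm$levels$watershed)
    bc <- draw_level(object$vc$tau_county, dm$levels$county)
    b <- c(bw, bc)
    out[, s] <- mu + as.numeric(dm$Z %*% b) +
      stats::rnorm(n, 0, sqrt(object$vc$sigma2))
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Population or group trajectory over a time grid
#'
#' Convenience wrapper around [predict.nested_lmm()]: holds a covariate
#' profile fixed, sweeps the time variable over a grid, and returns the
#' predicted log-NPP curve — the construction behind interaction plots
#' (e.g. mean and mean ± 1 SD climate profiles).
#'
#' @param fit a `"nested_lmm"` fit.
#' @param profile one-row data frame (or named list) giving every non-time
#'   model term.
#' @param time_grid numeric vector of time values.
#' @param time name of the time variable in the model.
#' @param level passed to [predict.nested_lmm()].
#' @return data frame with columns `time` and `pred` (log scale), plus an
#'   attribute `"level"`.
#' @export
predict_trajectory <- function(fit, profile, time_grid, time = "time",
                               level = c("population", "group")) {
  level <- match.arg(level)
  profile <- as.data.frame(profile, stringsAsFactors = FALSE)
  if (nrow(profile) != 1L) stop("profile must describe exactly one setting")
  nd <- profile[rep(1L, length(time_grid)), , drop = FALSE]
  nd[[time]] <- time_grid
  rownames(nd) <- NULL
  pred <- predict(fit, newdata = nd, level = level)
  structure(data.frame(time = time_grid, pred = as.numeric(pred)),
            level = attr(pred, "level"))
}
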