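#' Linear mixed models with two strictly nested random-effect levels
#'
#' `nested_lmm()` fits the Gaussian linear mixed model
#' \deqn{y = X\beta + Z_w b_w + Z_c b_c + \epsilon}
#' where observations (typically repeated yearly measurements of
#' log-transformed net primary productivity, NPP) are nested in watersheds,
#' and watersheds are strictly nested in counties.  Random effects at each
#' level are either a random intercept or a correlated random
#' intercept-and-slope pair in a time variable; residuals are i.i.d.
#' Gaussian.
#'
#' Estimation maximises the profiled ML or REML deviance over the relative
#' covariance factor of the random effects (a log-Cholesky, hence
#' unconstrained, parameterization that keeps every covariance matrix
#' positive semi-definite and degrades gracefully to the zero-variance
#' boundary).  For a candidate parameter the fixed effects, conditional
#' modes of the random effects and the residual variance all have closed
#' forms obtained from a sparse penalized least-squares solve, so the
#' numerical optimisation runs over at most six free parameters regardless
#' of data size.
#'
#' @param formula fixed-effects formula, e.g. `log(npp) ~ time + I(time^2)`.
#' @param data a data frame (a panel as produced by [generate_panel()] or
#'   [read_panel()]).
#' @param watershed,county names of the grouping columns.  Every watershed
#'   must belong to exactly one county.
#' @param random `"intercept"` for random intercepts at both levels, or
#'   `"slope"` for correlated random intercept + slope at both levels.
#' @param time name of the numeric column multiplying the random slope
#'   (required when `random = "slope"`).
#' @param method `"ML"` (default; comparable across fixed-effect
#'   specifications, used for AIC and likelihood-ratio tests) or `"REML"`.
#' @param control a list from [lmm_control()].
#'
#' @return an object of class `"nested_lmm"`; see [summary.nested_lmm()].
#'   Key components: `coefficients`, `se`, `vc` (list with `sigma2`,
#'   `tau_watershed`, `tau_county`), `loglik`, `aic`, `blups`, `converged`.
#'
#' @details t statistics are reported without any denominator-degrees-of-
#'   freedom correction and should be read as asymptotic z statistics.  The
#'   AIC parameter count is p fixed effects + free variance parameters
#'   (including the residual variance), the usual ML-AIC convention.
#'
#' @seealso [lr_test()], [loglik_at()], [icc()], [null_model()],
#'   [unconditional_growth()], [conditional_growth()]
#' @export
nested_lmm <- function(formula, data,
                       watershed = "watershed_id", county = "county_id",
                       random = c("intercept", "slope"), time = NULL,
                       method = c("ML", "REML"),
                       control = lmm_control()) {
  random <- match.arg(random)
  method <- match.arg(method)
  dm <- build_design(data, formula, watershed = watershed, county = county,
                     random = random, time = time)
  fit <- fit_lmm(dm, method = method, control = control)
  fit$call <- match.call()
  fit
}

#' Optimiser settings for [nested_lmm()]
#'
#' @param maxit maximum iterations for each optimisation stage.
#' @param reltol relative convergence tolerance on the profiled deviance.
#' @param fix_theta optionally a numeric vector of relative-covariance
#'   parameters (log-Cholesky scale) at which to evaluate without
#'   optimising; used for likelihood profiling and tests.
#' @param start starting value for the optimiser; default is the
#'   identity-scaled relative factor (all log-diagonals 0, covariances 0).
#' @return a list of settings.
#' @export
lmm_control <- function(maxit = 1000L, reltol = 1e-12, fix_theta = NULL,
                        start = NULL) {
  list(maxit = as.integer(maxit), reltol = reltol, fix_theta = fix_theta,
       start = start)
}

#' Construct design matrices and grouping structures for a nested LMM
#'
#' Builds the fixed-effect model matrix (via [stats::model.matrix()], so
#' categorical terms expand to treatment dummies against their reference
#' level and interactions follow formula order), the sparse random-effect
#' incidence matrix for both levels, and validates strict nesting.  Rows
#' with missing values in any required variable are dropped and counted.
#'
#' @inheritParams nested_lmm
#' @return a list of class `"lmm_design"` with elements `y`, `X`, `Z`,
#'   `levels` (per-level dimension and column spans), `watershed_index`,
#'   `county_index`, `watershed_county` (the watershed-to-county map),
#'   `n_dropped`, and bookkeeping needed by [fit_lmm()].
#' @export
build_design <- function(data, formula,
                         watershed = "watershed_id", county = "county_id",
                         random = c("intercept", "slope"), time = NULL) {
  random <- match.arg(random)
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  for (col in c(watershed, county)) {
    if (!col %in% names(data))
      stop("grouping column not found in data: ", col)
  }
  if (random == "slope") {
    if (is.null(time))
      stop("`time` must name the slope variable when random = \"slope\"")
    if (!time %in% names(data))
      stop("time column not found in data: ", time)
  }

  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("model term(s) not resolvable to panel columns: ",
         paste(missing_vars, collapse = ", "))

  needed <- unique(c(vars, watershed, county, time))
  keep <- stats::complete.cases(data[needed])
  n_dropped <- sum(!keep)
  df <- data[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete rows left after missing-data exclusion")

  mf <- stats::model.frame(formula, df)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric")
  X <- stats::model.matrix(attr(mf, "terms"), mf)

  ## collinearity check with named diagnosis
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  wfac <- factor(df[[watershed]])
  cfac <- factor(df[[county]])

  ## strict nesting: each watershed under exactly one county
  map <- unique(data.frame(w = as.character(wfac), c = as.character(cfac),
                           stringsAsFactors = FALSE))
  dup <- unique(map$w[duplicated(map$w)])
  if (length(dup))
    stop("nesting violation: watershed(s) observed under more than one county: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  w2c <- stats::setNames(map$c, map$w)

  n <- nrow(X)
  dim_per_group <- if (random == "slope") 2L else 1L
  tvec <- if (random == "slope") as.numeric(df[[time]]) else NULL

  make_Z <- function(fac) {
    k <- nlevels(fac)
    j <- as.integer(fac)
    if (dim_per_group == 1L) {
      Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1,
                           dims = c(n, k))
    } else {
      Matrix::sparseMatrix(i = rep(seq_len(n), 2L),
                           j = c(2L * j - 1L, 2L * j),
                           x = c(rep(1, n), tvec),
                           dims = c(n, 2L * k))
    }
  }
  Zw <- make_Z(wfac)
  Zc <- make_Z(cfac)
  Z <- cbind(Zw, Zc)

  nw <- nlevels(wfac)
  nc <- nlevels(cfac)
  if (nw < 2L || nc < 2L)
    stop("need at least 2 groups at each random level (got ",
         nw, " watersheds, ", nc, " counties)")

  levels_info <- list(
    watershed = list(dim = dim_per_group, n_groups = nw,
                     cols = seq_len(nw * dim_per_group),
                     labels = levels(wfac)),
    county = list(dim = dim_per_group, n_groups = nc,
                  cols = nw * dim_per_group + seq_len(nc * dim_per_group),
                  labels = levels(cfac))
  )

  structure(list(
    y = as.numeric(y), X = X, Z = Z, levels = levels_info,
    watershed_index = wfac, county_index = cfac,
    watershed_county = w2c,
    random = random, time = time,
    formula = formula, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    n_dropped = n_dropped
  ), class = "lmm_design")
}

## number of free covariance parameters for one level of dimension d
n_theta_level <- function(d) d * (d + 1L) / 2L

## relative Cholesky block (lower-triangular d x d) from its theta segment;
## diagonal on the log scale
theta_block <- function(theta, d) {
  if (d == 1L) {
    matrix(exp(min(max(theta[1L], -20), 20)), 1L, 1L)
  } else {
    d1 <- exp(min(max(theta[1L], -20), 20))
    c21 <- theta[2L]
    d2 <- exp(min(max(theta[3L], -20), 20))
    matrix(c(d1, c21, 0, d2), 2L, 2L)
  }
}

## sparse Lambda (q x q) repeating the per-level blocks over groups
build_lambda <- function(theta, levels_info) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  off_theta <- 0L
  for (lev in levels_info) {
    d <- lev$dim
    nt <- n_theta_level(d)
    blk <- theta_block(theta[off_theta + seq_len(nt)], d)
    off_theta <- off_theta + nt
    base <- lev$cols[1L] - 1L
    k <- lev$n_groups
    if (d == 1L) {
      idx <- base + seq_len(k)
      i <- c(i, idx); j <- c(j, idx); x <- c(x, rep(blk[1L, 1L], k))
    } else {
      g <- seq_len(k)
      c1 <- base + 2L * g - 1L
      c2 <- base + 2L * g
      i <- c(i, c1, c2, c2)
      j <- c(j, c1, c2, c1)
      x <- c(x, rep(blk[1L, 1L], k), rep(blk[2L, 2L], k), rep(blk[2L, 1L], k))
    }
  }
  q <- sum(vapply(levels_info, function(l) l$dim * l$n_groups, integer(1)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(q, q))
}

## Precomputed cross-products reused across deviance evaluations
lmm_precompute <- function(dm) {
  list(
    ZtZ = Matrix::crossprod(dm$Z),
    ZtX = as.matrix(Matrix::crossprod(dm$Z, dm$X)),
    Zty = as.numeric(Matrix::crossprod(dm$Z, dm$y)),
    XtX = crossprod(dm$X),
    Xty = as.numeric(crossprod(dm$X, dm$y)),
    n = length(dm$y), p = ncol(dm$X)
  )
}

## One profiled-deviance evaluation.  Solves the penalized least-squares
## system by a Schur complement on the sparse Cholesky factor of
## A = Lambda' Z'Z Lambda + I, yielding beta-hat, conditional modes u,
## the penalized RSS and both profiled criteria.
lmm_eval <- function(theta, dm, pc) {
  Lam <- build_lambda(theta, dm$levels)
  A <- Matrix::forceSymmetric(
    Matrix::crossprod(Lam, pc$ZtZ %*% Lam) + Matrix::Diagonal(nrow(Lam)))
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  B <- as.matrix(Matrix::crossprod(Lam, pc$ZtX))   # q x p
  a <- as.numeric(Matrix::crossprod(Lam, pc$Zty))  # q

  AinvB <- as.matrix(Matrix::solve(ch, B))
  Ainva <- as.numeric(Matrix::solve(ch, a))
  S <- pc$XtX - crossprod(B, AinvB)                # = RX'RX
  rhs <- pc$Xty - as.numeric(crossprod(B, Ainva))
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) return(NULL)
  beta <- backsolve(chS, forwardsolve(t(chS), rhs))
  u <- Ainva - as.numeric(AinvB %*% beta)

  e <- dm$y - as.numeric(dm$X %*% beta) -
    as.numeric(dm$Z %*% (Lam %*% u))
  r2 <- max(sum(e^2) + sum(u^2), 1e-300)  # keep deviance finite on
                                          # exactly interpolating data

  ldA <- as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
  ldS <- 2 * sum(log(diag(chS)))
  n <- pc$n; p <- pc$p
  dev_ml <- ldA + n * (1 + log(2 * pi * r2 / n))
  dev_reml <- ldA + ldS + (n - p) * (1 + log(2 * pi * r2 / (n - p)))

  list(beta = as.numeric(beta), u = u, r2 = r2, Lam = Lam,
       S = S, chS = chS, dev_ml = dev_ml, dev_reml = dev_reml,
       resid = e)
}

#' Fit a nested linear mixed model from prebuilt design matrices
#'
#' The workhorse behind [nested_lmm()]: numerical optimisation of the
#' profiled (RE)ML deviance over the log-Cholesky parameters, then GLS
#' fixed effects, standard errors, variance components, BLUPs, and fit
#' statistics at the optimum.  Deterministic: fixed identity-scaled start,
#' Nelder-Mead followed by a quasi-Newton polish, no randomness.
#'
#' @param dm an `"lmm_design"` from [build_design()].
#' @inheritParams nested_lmm
#' @return a `"nested_lmm"` object.
#' @export
fit_lmm <- function(dm, method = c("ML", "REML"), control = lmm_control()) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "lmm_design"))
  pc <- lmm_precompute(dm)
  if (pc$p >= pc$n) stop("more fixed-effect columns than observations")

  nt <- sum(vapply(dm$levels, function(l) n_theta_level(l$dim), numeric(1)))
  objective <- function(theta) {
    ev <- lmm_eval(theta, dm, pc)
    if (is.null(ev)) return(1e10)
    if (method == "ML") ev$dev_ml else ev$dev_reml
  }

  converged <- TRUE
  if (!is.null(control$fix_theta)) {
    theta_hat <- control$fix_theta
    if (length(theta_hat) != nt)
      stop("fix_theta must have length ", nt)
  } else {
    theta0 <- if (is.null(control$start)) rep(0, nt) else control$start
    if (length(theta0) != nt) stop("start must have length ", nt)
    o1 <- stats::optim(theta0, objective, method = "Nelder-Mead",
                       control = list(maxit = control$maxit,
                                      reltol = control$reltol))
    o2 <- suppressWarnings(
      stats::optim(o1$par, objective, method = "BFGS",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)))
    best <- if (o2$value <= o1$value) o2 else o1
    theta_hat <- best$par
    converged <- (best$convergence == 0L) ||
      abs(o1$value - o2$value) < 1e-6 * (abs(o1$value) + 1)
  }

  ev <- lmm_eval(theta_hat, dm, pc)
  if (is.null(ev)) stop("deviance not evaluable at the final parameters")
  n <- pc$n; p <- pc$p
  sigma2 <- if (method == "ML") ev$r2 / n else ev$r2 / (n - p)

  ## variance components on the data scale
  off <- 0L
  tau <- list()
  for (nm in names(dm$levels)) {
    d <- dm$levels[[nm]]$dim
    ntl <- n_theta_level(d)
    Tblk <- theta_block(theta_hat[off + seq_len(ntl)], d)
    off <- off + ntl
    tl <- sigma2 * tcrossprod(Tblk)
    dimnames(tl) <- if (d == 2L)
      list(c("intercept", "slope"), c("intercept", "slope"))
    else list("intercept", "intercept")
    tau[[nm]] <- tl
  }

  vcov_beta <- sigma2 * chol2inv(ev$chS)
  dimnames(vcov_beta) <- list(colnames(dm$X), colnames(dm$X))
  se <- sqrt(diag(vcov_beta))
  beta <- stats::setNames(ev$beta, colnames(dm$X))

  dev <- if (method == "ML") ev$dev_ml else ev$dev_reml
  loglik <- -dev / 2
  df <- p + nt + 1L   # fixed effects + covariance params + sigma2
  aic <- -2 * loglik + 2 * df

  ## BLUPs: b = sigma-free Lambda u, reshaped per level
  b <- as.numeric(ev$Lam %*% ev$u)
  blups <- list()
  for (nm in names(dm$levels)) {
    lev <- dm$levels[[nm]]
    m <- matrix(b[lev$cols], nrow = lev$n_groups, ncol = lev$dim,
                byrow = TRUE)
    rownames(m) <- lev$labels
    colnames(m) <- if (lev$dim == 2L) c("intercept", "slope") else "intercept"
    blups[[nm]] <- m
  }

  structure(list(
    coefficients = beta, se = se,
    t_values = beta / se, vcov = vcov_beta,
    vc = list(sigma2 = sigma2,
              tau_watershed = tau$watershed, tau_county = tau$county),
    theta = theta_hat, loglik = loglik, deviance = dev, aic = aic, df = df,
    method = method, converged = converged,
    n_obs = n, n_watersheds = dm$levels$watershed$n_groups,
    n_counties = dm$levels$county$n_groups, n_dropped = dm$n_dropped,
    blups = blups, fitted = dm$y - ev$resid, residuals = ev$resid,
    design = dm,
    y_signature = c(n = n, sum = sum(dm$y), sumsq = sum(dm$y^2))
  ), class = "nested_lmm")
}

#' Exact Gaussian log-likelihood at given variance components
#'
#' Evaluates the marginal log-density of the response under
#' \eqn{V = \sigma^2 I + Z_w (\tau_w \otimes I) Z_w' + Z_c (\tau_c \otimes I) Z_c'}
#' at user-supplied fixed effects, without refitting.  Uses the same
#' determinant/Woodbury identities as the fitting code but accepts arbitrary
#' (valid) components, so it doubles as a likelihood probe for tests and
#' likelihood-ratio machinery.
#'
#' @param dm an `"lmm_design"` or a fitted `"nested_lmm"` (its design is
#'   used).
#' @param sigma2 residual variance (> 0).
#' @param tau_watershed,tau_county per-level covariance matrices (scalars
#'   accepted for intercept-only designs); must be symmetric positive
#'   semi-definite.
#' @param beta fixed-effect vector, in design-column order.
#' @return the log-likelihood (a scalar).
#' @export
loglik_at <- function(dm, sigma2, tau_watershed, tau_county, beta) {
  if (inherits(dm, "nested_lmm")) dm <- dm$design
  stopifnot(inherits(dm, "lmm_design"))
  if (sigma2 <= 0) stop("sigma2 must be positive")
  as_mat <- function(m, d, nm) {
    m <- as.matrix(m)
    if (!all(dim(m) == d)) stop(nm, " must be ", d, "x", d)
    if (max(abs(m - t(m))) > 1e-10) stop(nm, " must be symmetric")
    if (any(eigen(m, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop(nm, " must be positive semi-definite")
    m
  }
  d <- dm$levels$watershed$dim
  tw <- as_mat(tau_watershed, d, "tau_watershed")
  tc <- as_mat(tau_county, d, "tau_county")

  ## relative Cholesky factors (PSD-safe via eigen square root fallback)
  rel_chol <- function(m) {
    out <- tryCatch(t(chol(m / sigma2)), error = function(e) NULL)
    if (!is.null(out)) return(out)
    es <- eigen(m / sigma2, symmetric = TRUE)
    es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow(m)) %*% t(es$vectors)
  }
  theta_like <- list(watershed = rel_chol(tw), county = rel_chol(tc))

  ## assemble Lambda directly from the blocks
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (nm in names(dm$levels)) {
    lev <- dm$levels[[nm]]
    blk <- theta_like[[nm]]
    base <- lev$cols[1L] - 1L
    for (r in seq_len(lev$dim)) for (cc in seq_len(lev$dim)) {
      if (blk[r, cc] != 0) {
        g <- seq_len(lev$n_groups)
        i <- c(i, base + lev$dim * (g - 1L) + r)
        j <- c(j, base + lev$dim * (g - 1L) + cc)
        x <- c(x, rep(blk[r, cc], lev$n_groups))
      }
    }
  }
  q <- ncol(dm$Z)
  Lam <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(q, q))

  r <- dm$y - as.numeric(dm$X %*% beta)
  A <- Matrix::forceSymmetric(
    Matrix::crossprod(Lam, Matrix::crossprod(dm$Z) %*% Lam) +
      Matrix::Diagonal(q))
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  ztr <- as.numeric(Matrix::crossprod(Lam, Matrix::crossprod(dm$Z, r)))
  quad <- (sum(r^2) - sum(ztr * as.numeric(Matrix::solve(ch, ztr)))) / sigma2
  ldV <- length(r) * log(sigma2) +
    as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
  -0.5 * (length(r) * log(2 * pi) + ldV + quad)
}

#' Likelihood-ratio test between two nested model fits
#'
#' @param fit_full,fit_reduced fitted models; the reduced model must be
#'   nested in the full one and fitted to the same rows.  `fit_reduced` may
#'   be an [stats::lm()] fit (pooled ordinary least squares), in which case
#'   its ML log-likelihood from [stats::logLik()] is used — the baseline for
#'   "multilevel model vs. pooled regression" tests.
#' @return a list with `chi2`, `df`, `p_value`, and a `note` flagging the
#'   boundary-variance caveat (the null distribution of a variance
#'   component test is a chi-squared mixture, so the reported p is
#'   conservative).
#' @export
lr_test <- function(fit_full, fit_reduced) {
  get_ll <- function(f, role) {
    if (inherits(f, "nested_lmm")) {
      if (f$method != "ML")
        stop(role, " fit uses REML; likelihood-ratio tests require ML ",
             "(REML criteria are not comparable across fixed-effect sets)")
      list(ll = f$loglik, df = f$df,
           sig = f$y_signature)
    } else if (inherits(f, "lm")) {
      ll <- stats::logLik(f)
      y <- stats::model.response(stats::model.frame(f))
      list(ll = as.numeric(ll), df = attr(ll, "df"),
           sig = c(n = length(y), sum = sum(y), sumsq = sum(y^2)))
    } else stop("unsupported fit object of class ", class(f)[1L])
  }
  a <- get_ll(fit_full, "full")
  b <- get_ll(fit_reduced, "reduced")
  if (a$sig[["n"]] != b$sig[["n"]] ||
      abs(a$sig[["sum"]] - b$sig[["sum"]]) > 1e-6 * (1 + abs(a$sig[["sum"]])) ||
      abs(a$sig[["sumsq"]] - b$sig[["sumsq"]]) > 1e-6 * (1 + a$sig[["sumsq"]]))
    stop("fits do not appear to use identical response rows")
  df <- a$df - b$df
  if (df < 0) stop("full model has fewer parameters than reduced model")
  chi2 <- max(0, 2 * (a$ll - b$ll))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p,
       note = paste("p-value is conservative when the reduced model sets a",
                    "variance component to its boundary value of zero"))
}
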