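trend_classes <- c("ext_sig_decrease", "sig_decrease", "no_change",
                   "sig_increase", "ext_sig_increase")

#' Linear trend of an NPP series with F-test significance grading
#'
#' Fits the least-squares line through an NPP time series using the
#' closed-form slope
#' \deqn{\theta = \frac{n\sum_i i\,y_i - \sum_i i \sum_i y_i}
#'                     {n\sum_i i^2 - (\sum_i i)^2}}
#' where by default the index i runs over observation rank 1..n (the
#' convention for unevenly spaced survey years; set
#' `spacing = "calendar"` to regress on the supplied time values
#' instead).  Significance is the regression F test with (1, n-2) degrees
#' of freedom and the trend is graded into five classes by
#' [classify_trend()].
#'
#' @param values numeric NPP series (>= 2 finite values).
#' @param time_index strictly increasing observation times; default 1..n.
#' @param spacing `"rank"` (regress on 1..n) or `"calendar"` (regress on
#'   `time_index` as given).
#' @return list of class `"trend_result"`: `slope`, `intercept`,
#'   `p_value` (NA when n = 2), `klass`, `n`.
#' @export
fit_trend <- function(values, time_index = seq_along(values),
                      spacing = c("rank", "calendar")) {
  spacing <- match.arg(spacing)
  ok <- is.finite(values)
  values <- values[ok]
  time_index <- time_index[ok]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values")
  if (any(diff(time_index) <= 0))
    stop("degenerate design: time_index must be strictly increasing")
  x <- if (spacing == "rank") seq_len(n) else as.numeric(time_index)

  sx <- sum(x); sy <- sum(values)
  sxx <- sum(x^2); sxy <- sum(x * values)
  denom <- n * sxx - sx^2
  slope <- (n * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / n

  if (n >= 3L) {
    fitted <- intercept + slope * x
    sse <- sum((values - fitted)^2)
    ssr <- sum((fitted - mean(values))^2)
    if (sse <= 0) {
      p <- if (ssr > 0) 0 else 1  # perfect line vs perfectly constant
    } else {
      f <- ssr / (sse / (n - 2))
      p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
    }
  } else {
    p <- NA_real_  # slope defined, significance undefined at n = 2
  }
  klass <- if (is.na(p)) NA_character_ else classify_trend(slope, p)
  structure(list(slope = slope, intercept = intercept, p_value = p,
                 klass = klass, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, digits = 4, ...) {
  cat("NPP trend: slope ", format(x$slope, digits = digits),
      " per step, p = ", format(x$p_value, digits = digits),
      " [", if (is.na(x$klass)) "undefined" else x$klass, "], n = ", x$n,
      "\n", sep = "")
  invisible(x)
}

#' Five-way significance grading of a fitted trend
#'
#' Grades (slope, p) into: extremely significant decrease (slope < 0,
#' p < 0.01), significant decrease (slope < 0, 0.01 <= p < 0.05), no
#' significant change (p >= 0.05), significant increase (slope > 0,
#' 0.01 <= p < 0.05), extremely significant increase (slope > 0,
#' p < 0.01).  Boundaries follow the half-open intervals: p = 0.05 is
#' "no_change", p = 0.01 is the "significant" (not "extremely") class.
#' A zero slope is never graded as change.
#'
#' @param slope fitted slope.
#' @param p_value F-test p-value in [0, 1].
#' @return one of `"ext_sig_decrease"`, `"sig_decrease"`, `"no_change"`,
#'   `"sig_increase"`, `"ext_sig_increase"`.
#' @export
classify_trend <- function(slope, p_value) {
  if (length(slope) != 1L || length(p_value) != 1L)
    stop("classify_trend is scalar; use fit_trend/trend_map for series")
  if (!is.finite(slope) || !is.finite(p_value))
    stop("invalid input: slope and p_value must be finite")
  if (p_value < 0 || p_value > 1) stop("p_value must lie in [0, 1]")
  if (p_value >= 0.05 || slope == 0) return("no_change")
  if (slope < 0) {
    if (p_value < 0.01) "ext_sig_decrease" else "sig_decrease"
  } else {
    if (p_value < 0.01) "ext_sig_increase" else "sig_increase"
  }
}

#' Per-pixel trend map with class-area summary
#'
#' Applies the closed-form trend fit and F grading to every valid pixel of
#' a gridded NPP time series (vectorised across pixels), and summarises
#' the percentage of valid area in each of the five classes.
#'
#' @param stack numeric array rows x cols x years (>= 3 layers).
#' @param mask logical matrix of valid (e.g. grassland) pixels; default
#'   all valid.
#' @param cell_area pixel area in km^2 (scalar; areas are equal so class
#'   percentages are pixel fractions).
#' @param spacing passed to the per-pixel fit; `"rank"` by default.
#' @param time_index observation times of the layers (used when
#'   `spacing = "calendar"`).
#' @return list of class `"trend_map"`: `slope_grid`, `p_grid`,
#'   `class_grid` (character matrix, `NA` outside the mask, sentinel
#'   `"unresolved"` where the fit is undefined), `class_area_pct` (named,
#'   sums to 100 over resolved valid pixels), `n_valid`.
#' @export
trend_map <- function(stack, mask = NULL, cell_area = 1,
                      spacing = c("rank", "calendar"),
                      time_index = seq_len(dim(stack)[3])) {
  spacing <- match.arg(spacing)
  stopifnot(length(dim(stack)) == 3L)
  nT <- dim(stack)[3L]
  if (nT < 3L) stop("need at least 3 layers for a graded trend map")
  nr <- dim(stack)[1L]; nc <- dim(stack)[2L]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(all(dim(mask) == c(nr, nc)))
  if (!any(mask)) stop("empty mask: zero valid pixels")

  Y <- matrix(stack, nr * nc, nT)        # pixels x time
  valid <- as.vector(mask) & rowSums(!is.finite(Y)) == 0L
  x <- if (spacing == "rank") seq_len(nT) else as.numeric(time_index)
  xc <- x - mean(x)
  sxx <- sum(xc^2)

  slope <- p <- rep(NA_real_, nr * nc)
  klass <- rep(NA_character_, nr * nc)
  if (any(valid)) {
    Yv <- Y[valid, , drop = FALSE]
    ybar <- rowMeans(Yv)
    b <- as.numeric(Yv %*% xc) / sxx
    a <- ybar - b * mean(x)
    res <- Yv - outer(a, rep(1, nT)) - outer(b, x)
    sse <- rowSums(res^2)
    ssr <- b^2 * sxx
    fstat <- ssr / (sse / (nT - 2))
    pv <- stats::pf(fstat, 1, nT - 2, lower.tail = FALSE)
    pv[sse <= 1e-300 & ssr > 0] <- 0
    pv[ssr == 0 & sse <= 1e-300] <- 1
    slope[valid] <- b
    p[valid] <- pv
    kv <- character(sum(valid))
    resolved <- is.finite(b) & is.finite(pv)
    kv[!resolved] <- "unresolved"
    bi <- b[resolved]; pi <- pv[resolved]
    k <- ifelse(pi >= 0.05 | bi == 0, "no_change",
         ifelse(bi < 0,
                ifelse(pi < 0.01, "ext_sig_decrease", "sig_decrease"),
                ifelse(pi < 0.01, "ext_sig_increase", "sig_increase")))
    kv[resolved] <- k
    klass[valid] <- kv
  }

  cg <- matrix(klass, nr, nc)
  counts <- table(factor(klass[valid & klass != "unresolved"],
                         levels = trend_classes))
  pct <- 100 * as.numeric(counts) / max(sum(counts), 1L)
  names(pct) <- trend_classes

  structure(list(slope_grid = matrix(slope, nr, nc),
                 p_grid = matrix(p, nr, nc),
                 class_grid = cg,
                 class_area_pct = pct,
                 n_valid = sum(valid),
                 cell_area = cell_area),
            class = "trend_map")
}

#' @export
print.trend_map <- function(x, digits = 2, ...) {
  cat("Trend map over", x$n_valid, "valid pixels (cell area",
      x$cell_area, "km^2)\n")
  cat("Class area percentages:\n")
  print(round(x$class_area_pct, digits))
  invisible(x)
}
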