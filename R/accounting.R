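#' Area-weighted NPP summary
#'
#' Total and mean NPP over a set of cells (grid pixels or panel rows).
#' The total is \eqn{\sum_i v_i a_i} (per-area NPP times cell area, an
#' opaque mass-carbon unit carried through unchanged) and the mean is the
#' area-weighted mean \eqn{\sum v_i a_i / \sum a_i} in gC m^-2.
#'
#' @param values numeric per-area NPP values (gC m^-2); non-finite cells
#'   are excluded together with their area.
#' @param area cell areas in km^2: a scalar (equal-area cells) or a vector
#'   matching `values`.
#' @param year optional label carried into the output.
#' @return list of class `"npp_summary"`: `year`, `total_npp`, `mean_npp`,
#'   `area`.
#' @export
summarize_npp <- function(values, area = 1, year = NA) {
  values <- as.numeric(values)
  if (length(area) == 1L) area <- rep(area, length(values))
  if (length(area) != length(values))
    stop("area must be a scalar or match values in length")
  if (any(!is.finite(area)) || any(area <= 0))
    stop("all cell areas must be positive and finite")
  ok <- is.finite(values)
  total_area <- sum(area[ok])
  if (total_area <= 0) stop("no valid cells")
  total <- sum(values[ok] * area[ok])
  structure(list(year = year, total_npp = total,
                 mean_npp = total / total_area, area = total_area),
            class = "npp_summary")
}

#' @export
print.npp_summary <- function(x, digits = 4, ...) {
  cat("NPP summary", if (!is.na(x$year)) paste0("(", x$year, ")"), ":",
      "total", format(x$total_npp, digits = digits),
      "over", format(x$area, digits = digits), "km^2;",
      "mean", format(x$mean_npp, digits = digits), "gC/m^2\n")
  invisible(x)
}

#' Per-year NPP summaries of a gridded stack
#'
#' @param stack array rows x cols x years.
#' @param years labels for the layers.
#' @param mask logical validity matrix.
#' @param cell_area pixel area, km^2.
#' @return data frame with columns `year`, `total_npp`, `mean_npp`, `area`.
#' @export
summarize_npp_stack <- function(stack, years = seq_len(dim(stack)[3]),
                                mask = NULL, cell_area = 1) {
  stopifnot(length(dim(stack)) == 3L)
  if (is.null(mask)) mask <- matrix(TRUE, dim(stack)[1L], dim(stack)[2L])
  out <- lapply(seq_len(dim(stack)[3L]), function(k) {
    layer <- stack[, , k]
    s <- summarize_npp(layer[mask], area = cell_area, year = years[k])
    data.frame(year = s$year, total_npp = s$total_npp,
               mean_npp = s$mean_npp, area = s$area)
  })
  do.call(rbind, out)
}

#' Percent change between two mean NPP values
#'
#' @param mean_start,mean_end mean NPP at the start and end dates
#'   (gC m^-2); `mean_start` must be positive.
#' @return percent increase, 100 * (end - start) / start.
#' @export
percent_change <- function(mean_start, mean_end) {
  if (any(mean_start <= 0)) stop("mean_start must be positive")
  100 * (mean_end - mean_start) / mean_start
}

#' Average annual growth rate from a total percent change
#'
#' Both conventions are exposed because published summaries differ in
#' which they use: `"arithmetic"` divides the total percent change by the
#' number of years; `"geometric"` is the compound rate
#' \eqn{100((1 + pct/100)^{1/n} - 1)}.
#'
#' @param pct_change total percent change over the period.
#' @param n_years length of the period in years (> 0).
#' @param convention `"arithmetic"` or `"geometric"`.
#' @return percent per year.
#' @export
annual_rate <- function(pct_change, n_years,
                        convention = c("arithmetic", "geometric")) {
  convention <- match.arg(convention)
  if (n_years <= 0) stop("n_years must be positive")
  if (convention == "arithmetic") {
    pct_change / n_years
  } else {
    if (pct_change <= -100) stop("geometric rate undefined at or below -100%")
    100 * ((1 + pct_change / 100)^(1 / n_years) - 1)
  }
}

#' Decompose total NPP change by land-use transition
#'
#' Splits the change in total NPP between two dates into three additive
#' contributions by pixel transition class: retained grassland (G-G,
#' contributes end minus start), conversion into grassland (O-G,
#' credited its full end value) and conversion out of grassland (G-O,
#' debited its full start value).  Non-grassland pixels at both dates
#' contribute nothing.  The identity
#' `delta_retained + delta_in + delta_out = delta_total` holds exactly,
#' where `delta_total` is the difference between total NPP over end-date
#' grassland and total NPP over start-date grassland.
#'
#' @param npp_start,npp_end numeric NPP grids (matrices, gC m^-2).
#' @param landuse_start,landuse_end matrices with codes `"grass"` /
#'   `"other"` (unknown codes are an error listing them).
#' @param cell_area pixel area, km^2.
#' @return list of class `"change_decomposition"`: `delta_total`,
#'   `delta_retained`, `delta_in`, `delta_out` (same mass-carbon unit as
#'   [summarize_npp()] totals), `shares` (each component as percent of the
#'   total change; signs are kept, so shares sum to 100 when
#'   `delta_total` is nonzero), and pixel `counts` per class.
#' @export
decompose_change <- function(npp_start, npp_end, landuse_start, landuse_end,
                             cell_area = 1) {
  dims <- dim(npp_start)
  for (m in list(npp_end, landuse_start, landuse_end)) {
    if (!all(dim(m) == dims)) stop("all grids must share one shape")
  }
  codes <- unique(c(landuse_start, landuse_end))
  unknown <- setdiff(codes, c("grass", "other"))
  if (length(unknown))
    stop("unknown land-use code(s): ", paste(unknown, collapse = ", "))

  gs <- landuse_start == "grass"
  ge <- landuse_end == "grass"
  a <- cell_area
  retained <- sum((npp_end - npp_start)[gs & ge]) * a
  conv_in <- sum(npp_end[!gs & ge]) * a
  conv_out <- -sum(npp_start[gs & !ge]) * a
  total <- retained + conv_in + conv_out

  shares <- if (total != 0) {
    100 * c(retained = retained, converted_in = conv_in,
            converted_out = conv_out) / total
  } else {
    c(retained = NA_real_, converted_in = NA_real_,
      converted_out = NA_real_)
  }
  structure(list(delta_total = total, delta_retained = retained,
                 delta_in = conv_in, delta_out = conv_out,
                 shares = shares,
                 counts = c(retained = sum(gs & ge),
                            converted_in = sum(!gs & ge),
                            converted_out = sum(gs & !ge),
                            never_grass = sum(!gs & !ge))),
            class = "change_decomposition")
}

#' @export
print.change_decomposition <- function(x, digits = 4, ...) {
  cat("NPP change decomposition by land-use transition\n")
  cat("  total change:   ", format(x$delta_total, digits = digits), "\n")
  cat("  retained (G-G): ", format(x$delta_retained, digits = digits),
      if (is.finite(x$shares[["retained"]]))
        paste0(" (", round(x$shares[["retained"]], 1), "%)"), "\n", sep = "")
  cat("  in  (O-G):      ", format(x$delta_in, digits = digits),
      if (is.finite(x$shares[["converted_in"]]))
        paste0(" (", round(x$shares[["converted_in"]], 1), "%)"), "\n", sep = "")
  cat("  out (G-O):      ", format(x$delta_out, digits = digits),
      if (is.finite(x$shares[["converted_out"]]))
        paste0(" (", round(x$shares[["converted_out"]], 1), "%)"), "\n", sep = "")
  invisible(x)
}
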