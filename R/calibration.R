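# Standard-curve calibration, internal-standard lot assignment, correction
# factors and limits of quantification.
#
# The standard series spans 0, 0.1, 0.2, 0.6, 2, 6, 20, 60 and 200 uM; each
# level is mixed 1:1 with the diluted heavy-extract lot and 2.5 ul is
# injected, so on-column amounts run 0.125-250 pmol. Curves are ordinary
# least squares of light peak area on pmol with a free intercept over the
# nonzero levels (the zero level only informs noise). The limit of
# quantification is the amount producing a signal-to-noise ratio of 10.

#' On-column amounts for a standard series
#'
#' pmol on column = concentration (uM) x mix fraction x injection volume
#' (ul); numerically exact because uM x ul = pmol.
#'
#' @param series_conc concentrations in uM (>= 0).
#' @param mix_fraction fraction of the injected solution that is standard
#'   (default 0.5 for 1:1 mixing with the internal-standard lot).
#' @param injection_volume_ul injected volume in ul (default 2.5).
#' @return pmol on column, same length as `series_conc`.
#' @examples
#' on_column_amounts(c(0.1, 200))  # 0.125 and 250 pmol
#' @export
on_column_amounts <- function(series_conc, mix_fraction = 0.5,
                              injection_volume_ul = 2.5) {
  if (any(series_conc < 0)) stop("concentrations must be >= 0")
  stopifnot(mix_fraction > 0, mix_fraction <= 1, injection_volume_ul > 0)
  series_conc * mix_fraction * injection_volume_ul
}

#' Fit a standard curve
#'
#' Ordinary least squares of peak area on on-column amount over the nonzero
#' standards, free intercept, unweighted. The linear range is the widest
#' contiguous span of levels whose back-calculated amounts deviate less than
#' `range_tol` (default 15%) from nominal; the LOQ comes from
#' [loq_from_series()] when S/N values are available.
#'
#' @param points data.frame with columns `pmol`, `area` and optionally
#'   `s2n`; one row per standard level (detected peaks only — use `NA` area
#'   for undetected levels, which are dropped).
#' @param metabolite analyte name carried into the result.
#' @param range_tol back-calculation tolerance defining the linear range.
#' @return an object of class `nad_calcurve` with components `metabolite`,
#'   `slope` (counts.min per pmol), `intercept` (counts.min), `r_squared`,
#'   `linear_range` (pmol, length 2), `loq_pmol`, `loq_flag`, `points`.
#' @seealso [interpolate_amount()], [predict.nad_calcurve()]
#' @export
fit_calibration <- function(points, metabolite = "", range_tol = 0.15) {
  stopifnot(is.data.frame(points), all(c("pmol", "area") %in% names(points)))
  use <- points[points$pmol > 0 & is.finite(points$area), , drop = FALSE]
  use <- use[order(use$pmol), , drop = FALSE]
  if (nrow(use) < 3L)
    stop("need at least 3 nonzero standard points",
         if (nzchar(metabolite)) paste0(" for ", metabolite))
  if (all(use$area == 0))
    stop("all standard areas are zero",
         if (nzchar(metabolite)) paste0(" for ", metabolite))
  fit <- stats::lm(area ~ pmol, data = use)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  sst <- sum((use$area - mean(use$area))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  back <- (use$area - intercept) / slope
  ok <- abs(back / use$pmol - 1) < range_tol
  lr <- c(NA_real_, NA_real_)
  if (any(ok)) {
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    lr <- c(use$pmol[starts[best]], use$pmol[ends[best]])
  }
  loq <- list(loq_pmol = NA_real_, flag = "unavailable")
  if ("s2n" %in% names(use) && any(is.finite(use$s2n)))
    loq <- loq_from_series(use$pmol, use$s2n)
  structure(list(metabolite = metabolite, slope = slope,
                 intercept = intercept, r_squared = r2, linear_range = lr,
                 loq_pmol = loq$loq_pmol, loq_flag = loq$flag, points = use,
                 fit = fit),
            class = "nad_calcurve")
}

#' @export
print.nad_calcurve <- function(x, ...) {
  cat(sprintf("Standard curve%s: area = %.4g x pmol %+.4g  (R2 = %.4f)\n",
              if (nzchar(x$metabolite)) paste0(" [", x$metabolite, "]") else "",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  linear range: %.3g-%.3g pmol over %d levels; LOQ %s pmol (%s)\n",
              x$linear_range[1], x$linear_range[2], nrow(x$points),
              formatC(x$loq_pmol, digits = 3), x$loq_flag))
  invisible(x)
}

#' @export
coef.nad_calcurve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict peak area from amount
#'
#' @param object an `nad_calcurve`.
#' @param pmol amounts in pmol.
#' @param ... unused.
#' @return predicted areas (counts.min).
#' @export
predict.nad_calcurve <- function(object, pmol, ...) {
  object$intercept + object$slope * pmol
}

#' @export
plot.nad_calcurve <- function(x, ...) {
  graphics::plot(x$points$pmol, x$points$area, log = "xy",
                 xlab = "amount on column (pmol)", ylab = "peak area (counts.min)",
                 main = paste("Standard curve", x$metabolite), ...)
  pr <- range(x$points$pmol)
  px <- exp(seq(log(pr[1]), log(pr[2]), length.out = 100))
  graphics::lines(px, pmax(predict(x, px), .Machine$double.xmin))
  invisible(x)
}

#' Back-calculate an amount from a peak area
#'
#' pmol = (area - intercept) / slope. Values outside the curve's linear
#' range are flagged via the `"outside_linear_range"` attribute.
#'
#' @param curve an `nad_calcurve`.
#' @param area peak area(s), >= 0.
#' @return amounts in pmol with attribute `outside_linear_range` (logical).
#' @export
interpolate_amount <- function(curve, area) {
  if (curve$slope <= 0) stop("calibration slope must be positive")
  if (any(area < 0, na.rm = TRUE)) stop("areas must be >= 0")
  pmol <- (area - curve$intercept) / curve$slope
  outside <- !is.na(pmol) & !is.na(curve$linear_range[1]) &
    (pmol < curve$linear_range[1] | pmol > curve$linear_range[2])
  attr(pmol, "outside_linear_range") <- outside
  pmol
}

#' Limit of quantification from a dilution series
#'
#' Log-linear interpolation of amount versus signal-to-noise to the S/N = 10
#' crossing. If a level sits exactly at S/N = 10 that amount is returned.
#' When every level is below 10 the LOQ is an open upper bound
#' (`flag = "above_max"`, `loq_pmol = NA`, `bound` = largest amount); when
#' every level is above 10 the crossing is extrapolated from the two lowest
#' levels and flagged `"extrapolated"`.
#'
#' @param pmol amounts on column.
#' @param s2n signal-to-noise at each amount.
#' @param target the defining S/N (default 10).
#' @return list with `loq_pmol`, `flag` (`"interpolated"`, `"exact"`,
#'   `"extrapolated"` or `"above_max"`) and, for `"above_max"`, `bound`.
#' @export
loq_from_series <- function(pmol, s2n, target = 10) {
  keep <- is.finite(pmol) & is.finite(s2n) & pmol > 0 & s2n > 0
  pmol <- pmol[keep]; s2n <- s2n[keep]
  if (length(pmol) < 2L)
    return(list(loq_pmol = NA_real_, flag = "unavailable"))
  o <- order(pmol)
  pmol <- pmol[o]; s2n <- s2n[o]
  if (any(s2n == target))
    return(list(loq_pmol = pmol[which(s2n == target)[1L]], flag = "exact"))
  if (all(s2n < target))
    return(list(loq_pmol = NA_real_, flag = "above_max", bound = max(pmol)))
  i <- which(s2n > target)[1L]
  if (i == 1L) {  # already above target at the lowest level: extrapolate
    lo <- 1L; hi <- 2L; flag <- "extrapolated"
  } else {
    lo <- i - 1L; hi <- i; flag <- "interpolated"
  }
  lx <- log(pmol[c(lo, hi)])
  ly <- log(s2n[c(lo, hi)])
  loq <- exp(lx[1L] + (log(target) - ly[1L]) * diff(lx) / diff(ly))
  list(loq_pmol = loq, flag = flag)
}

#' Response-factor correction factor between two analytes
#'
#' Mean over standard levels of (target response factor) / (surrogate
#' response factor), response factor = area / pmol. Lets a surrogate heavy
#' peak quantify an analyte with no usable heavy channel: IMP against the
#' heavy-extract NMN peak, NA against heavy (18O) Nam.
#'
#' @param target_area,target_pmol areas and amounts of the target analyte in
#'   the standard injections.
#' @param surrogate_area,surrogate_pmol same for the surrogate.
#' @return dimensionless correction factor (> 0).
#' @export
correction_factor <- function(target_area, target_pmol,
                              surrogate_area, surrogate_pmol) {
  keep <- is.finite(target_area) & is.finite(surrogate_area) &
    target_pmol > 0 & surrogate_pmol > 0
  if (!any(keep)) stop("no usable standard levels shared by target and surrogate")
  rf_t <- target_area[keep] / target_pmol[keep]
  rf_s <- surrogate_area[keep] / surrogate_pmol[keep]
  if (any(rf_s == 0)) stop("surrogate response factor is zero")
  cf <- mean(rf_t / rf_s)
  if (!is.finite(cf) || cf <= 0) stop("correction factor must be positive")
  cf
}
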