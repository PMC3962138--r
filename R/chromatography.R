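# Peak processing for SRM transition traces.
#
# A trace is a time/intensity series for one channel (one metabolite, light
# or heavy isotopologue). Intensities are baseline-corrected arbitrary
# counts, so small negative excursions from detector noise are legal; the
# integration baseline is zero. Times are minutes throughout.

#' Construct a transition trace
#'
#' @param channel_id identifier, conventionally `"<metabolite>.light"` or
#'   `"<metabolite>.heavy"`.
#' @param time_min strictly increasing times in minutes (>= 2 points).
#' @param intensity baseline-corrected intensities (counts), same length.
#' @return a `data.frame` of class `nad_trace` with columns `channel_id`,
#'   `time_min`, `intensity`.
#' @export
transition_trace <- function(channel_id, time_min, intensity) {
  if (length(time_min) != length(intensity))
    stop("time and intensity must have equal length")
  if (length(time_min) < 2L) stop("a trace needs at least 2 points")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(channel_id = channel_id, time_min = time_min,
                       intensity = intensity, stringsAsFactors = FALSE),
            class = c("nad_trace", "data.frame"))
}

#' Robust baseline noise estimate
#'
#' Estimates the baseline noise scale of a trace as 1.4826 x the median
#' absolute deviation of intensities outside the supplied exclusion windows
#' (typically the expected peak regions). For a constant trace the MAD is
#' zero and the configured floor is returned instead; this is also the
#' denominator floor used for signal-to-noise.
#'
#' @param trace a trace (`transition_trace()` or any data.frame with
#'   `time_min`/`intensity`).
#' @param exclusion_windows list of `c(lo, hi)` RT intervals (minutes) to
#'   leave out, e.g. around expected peaks.
#' @param floor positive fallback when the out-of-window trace is constant.
#' @return noise scale in counts (strictly positive).
#' @export
estimate_noise <- function(trace, exclusion_windows = NULL, floor = 1) {
  stopifnot(floor > 0)
  keep <- rep(TRUE, nrow(trace))
  for (w in exclusion_windows)
    keep[trace$time_min >= w[1] & trace$time_min <= w[2]] <- FALSE
  if (!any(keep)) stop("all points fall inside exclusion windows")
  if (sum(keep) < 10L)
    stop("need at least 10 points outside exclusion windows (have ",
         sum(keep), ")")
  m <- stats::mad(trace$intensity[keep])
  if (m <= 0) floor else max(m, floor)
}

#' Detect and integrate peaks in a trace
#'
#' Local maxima of a lightly smoothed copy of the trace (moving average,
#' `smooth_points` wide) that exceed `threshold x noise` seed peaks. Peak
#' bounds extend from the apex to the nearer of the first local minimum and
#' the first point below `bound_frac` (default 2%) of the apex height. The
#' area is the trapezoidal integral of the *raw* trace between the bounds
#' above a zero baseline; the height (used for S/N) is the smoothed maximum
#' within the bounds. Adjacent detections whose claimed regions touch and
#' whose connecting valley stays above half the smaller apex are merged:
#' they are one peak split by a noise wiggle, not two resolved analytes.
#'
#' @param trace a trace.
#' @param noise noise scale in counts; estimated from the whole trace via
#'   [estimate_noise()] when `NULL`.
#' @param threshold detection threshold in noise units (default 3).
#' @param smooth_points moving-average width for detection (default 5).
#' @param bound_frac apex fraction terminating a peak (default 0.02).
#' @return data.frame with one row per peak, sorted by `apex_rt`: columns
#'   `apex_rt`, `left_bound`, `right_bound`, `area`, `height`, `noise`,
#'   `s2n`. Zero rows for a flat trace.
#' @export
detect_and_integrate <- function(trace, noise = NULL, threshold = 3,
                                 smooth_points = 5L, bound_frac = 0.02) {
  t <- trace$time_min
  y <- trace$intensity
  n <- length(y)
  if (is.null(noise)) noise <- estimate_noise(trace)
  s <- moving_average(y, smooth_points)
  empty <- data.frame(apex_rt = numeric(0), left_bound = numeric(0),
                      right_bound = numeric(0), area = numeric(0),
                      height = numeric(0), noise = numeric(0),
                      s2n = numeric(0))
  left_n <- c(-Inf, s[-n])
  right_n <- c(s[-1L], -Inf)
  cand <- which(s > threshold * noise & s >= left_n & s > right_n)
  if (!length(cand)) return(empty)
  cand <- cand[order(s[cand], decreasing = TRUE)]
  claimed <- rep(FALSE, n)
  rows <- vector("list", n)
  for (i in cand) {
    if (claimed[i]) next
    cutoff <- bound_frac * s[i]
    l <- i
    while (l > 1L && s[l - 1L] < s[l]) {
      l <- l - 1L
      if (s[l] <= cutoff) break
    }
    r <- i
    while (r < n && s[r + 1L] < s[r]) {
      r <- r + 1L
      if (s[r] <= cutoff) break
    }
    claimed[l:r] <- TRUE
    rows[[i]] <- data.frame(iapex = i, il = l, ir = r)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[out$ir > out$il, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$iapex), , drop = FALSE]
  # noise can split one peak at a shallow valley on a flank: merge adjacent
  # detections whose claimed regions touch and whose valley stays above half
  # the smaller apex
  repeat {
    if (nrow(out) < 2L) break
    merged <- FALSE
    for (j in seq_len(nrow(out) - 1L)) {
      if (out$il[j + 1L] - out$ir[j] > 1L) next
      valley <- min(s[out$iapex[j]:out$iapex[j + 1L]])
      if (valley <= 0.5 * min(s[out$iapex[j]], s[out$iapex[j + 1L]])) next
      keep <- if (s[out$iapex[j]] >= s[out$iapex[j + 1L]]) j else j + 1L
      out$iapex[j] <- out$iapex[keep]
      out$ir[j] <- out$ir[j + 1L]
      out <- out[-(j + 1L), , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  res <- do.call(rbind, lapply(seq_len(nrow(out)), function(j) {
    l <- out$il[j]; r <- out$ir[j]
    height <- max(s[l:r])
    data.frame(apex_rt = t[out$iapex[j]], left_bound = t[l],
               right_bound = t[r], area = trapz(t[l:r], y[l:r]),
               height = height, noise = noise, s2n = height / noise)
  }))
  res[order(res$apex_rt), , drop = FALSE]
}

#' Select the peak belonging to a metabolite
#'
#' Among peaks whose apex lies within `expected_rt` +/- `window`, returns the
#' one nearest the expected retention time; ties go to the larger area. The
#' window is what rejects crosstalk peaks, which sit at the *source*
#' metabolite's retention time.
#'
#' @param peaks data.frame from [detect_and_integrate()].
#' @param expected_rt expected retention time (minutes).
#' @param window half-width of the acceptance window (minutes, > 0); the
#'   default 0.3 min is just under the closest crosstalk pair in the panel
#'   (cytidine 11.14 vs uridine 11.50 min).
#' @return a one-row data.frame, or `NULL` if no apex falls in the window.
#' @export
select_peak <- function(peaks, expected_rt, window = 0.3) {
  stopifnot(window > 0)
  if (is.null(peaks) || nrow(peaks) == 0L) return(NULL)
  d <- abs(peaks$apex_rt - expected_rt)
  inwin <- which(d <= window)
  if (!length(inwin)) return(NULL)
  dd <- d[inwin]
  best <- inwin[dd == min(dd)]
  if (length(best) > 1L) best <- best[which.max(peaks$area[best])]
  peaks[best, , drop = FALSE]
}

#' Chromatographic capacity factor
#'
#' `k' = (rt - t0) / t0`, the dimensionless retention measure. The void time
#' `t0` is a per-separation configuration value; the default 1.40 min for
#' both separations is inferred from the published (RT, k') pairs.
#'
#' @param rt retention time (minutes), must be >= `t0`.
#' @param t0 void time (minutes, > 0).
#' @return dimensionless capacity factor.
#' @examples
#' capacity_factor(13.64, 1.4)  # NAD+, ~8.7
#' @export
capacity_factor <- function(rt, t0 = 1.4) {
  stopifnot(t0 > 0)
  if (any(rt < t0)) stop("retention time before the void time (rt < t0)")
  (rt - t0) / t0
}

#' Write / read per-injection trace files
#'
#' One CSV per injection, columns `channel_id,time_min,intensity`.
#'
#' @param traces named list of traces (one per channel).
#' @param path CSV file path.
#' @return `write_traces` returns `path` invisibly; `read_traces` a named
#'   list of traces.
#' @export
write_traces <- function(traces, path) {
  dt <- data.table::rbindlist(traces)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  dt <- data.table::fread(path, na.strings = NULL)
  split_df <- split(as.data.frame(dt), dt$channel_id)
  lapply(split_df, function(d)
    transition_trace(d$channel_id[1], d$time_min, d$intensity))
}
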