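# Robustness metrics: replicate precision (RSD), curve quality, capacity
# factors and the crosstalk audit.
#
# RSDs are computed on back-calculated amounts, not raw areas, so they are
# insensitive to ionization suppression — consistent with the ratio-based
# philosophy of the assay. "Method" RSD spans independently prepared
# standard solutions (assay convention: six at 10 uM); "system" RSD spans
# repeat injections of one solution (four).

#' Relative standard deviation
#'
#' Sample (n-1) standard deviation as a percentage of the mean.
#'
#' @param values >= 2 measurements with nonzero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(9, 10, 11))  # 10
#' @export
rsd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("RSD needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  stats::sd(values) / m * 100
}

# Back-calculated amount matrix (runs x metabolites) from assigned areas of
# replicate standard injections.
back_calculated_amounts <- function(assigned, curves) {
  ids <- unique(assigned$injection_id)
  mets <- names(curves)
  out <- matrix(NA_real_, length(ids), length(mets),
                dimnames = list(ids, mets))
  for (met in mets) {
    r <- assigned[assigned$metabolite == met & assigned$isotope == "light", ]
    r <- r[match(ids, r$injection_id), ]
    a <- ifelse(r$found, r$area, NA_real_)
    out[, met] <- as.numeric(interpolate_amount(curves[[met]], ifelse(is.na(a), NA, a)))
  }
  out
}

rsd_over_runs <- function(part, curves, panel, config, n_expected, what) {
  pa <- assign_part(part, panel, noise_floor = config$noise_floor)
  asg <- pa$assigned
  n <- length(unique(asg$injection_id))
  if (n != n_expected)
    stop(what, " RSD expects exactly ", n_expected, " runs, got ", n)
  amounts <- back_calculated_amounts(asg, curves)
  missing <- colnames(amounts)[colSums(is.na(amounts)) > 0]
  if (length(missing))
    stop("metabolite(s) missing from at least one run: ",
         paste(missing, collapse = ", "))
  apply(amounts, 2, rsd)
}

#' Method precision over independent standard preparations
#'
#' RSD of back-calculated amounts over `n_expected` (default 6)
#' independently prepared standard solutions; the replicate count is
#' enforced.
#'
#' @param runs an `nad_dataset_part` of replicate standard injections.
#' @param curves named list of `nad_calcurve`.
#' @param panel an `nad_panel`.
#' @param config a [sim_config()].
#' @param n_expected required run count.
#' @return named per-metabolite RSD (percent).
#' @export
method_rsd <- function(runs, curves, panel, config, n_expected = 6L) {
  rsd_over_runs(runs, curves, panel, config, n_expected, "method")
}

#' System precision over repeat injections
#'
#' RSD of back-calculated amounts over `n_expected` (default 4) injections
#' of one solution: injection-level noise only.
#'
#' @inheritParams method_rsd
#' @return named per-metabolite RSD (percent).
#' @export
system_rsd <- function(runs, curves, panel, config, n_expected = 4L) {
  rsd_over_runs(runs, curves, panel, config, n_expected, "system")
}

#' Crosstalk audit of unselected peaks
#'
#' Any detected-but-unselected peak whose apex lies within `window` of a
#' crosstalk rule's source retention time (for a rule targeting that
#' channel's metabolite) is annotated with the rule; remaining extra peaks
#' are flagged unexplained.
#'
#' @param peaks all-peaks table from [process_injection()] (with `selected`).
#' @param panel an `nad_panel`.
#' @param window RT matching half-window (minutes).
#' @return data.frame of notes: `injection_id`, `channel_id`, `apex_rt`,
#'   `note`. Zero rows when every channel is clean.
#' @export
crosstalk_audit <- function(peaks, panel, window = 0.3) {
  empty <- data.frame(injection_id = character(0), channel_id = character(0),
                      apex_rt = numeric(0), note = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(peaks) || nrow(peaks) == 0L) return(empty)
  extra <- peaks[!peaks$selected, , drop = FALSE]
  if (nrow(extra) == 0L) return(empty)
  notes <- character(nrow(extra))
  for (i in seq_len(nrow(extra))) {
    fd <- crosstalk_feeders(panel, extra$metabolite[i], extra$isotope[i])
    hit <- fd[abs(fd$rt - extra$apex_rt[i]) <= window, , drop = FALSE]
    notes[i] <- if (nrow(hit))
      paste(sprintf("%s (RT %.2f)", hit$note, hit$rt), collapse = "; ")
    else "unexplained extra peak"
  }
  data.frame(injection_id = extra$injection_id,
             channel_id = extra$channel_id, apex_rt = extra$apex_rt,
             note = notes, stringsAsFactors = FALSE)
}

#' Assay QC report
#'
#' One row per quantifiable metabolite mirroring the assay's robustness
#' table: retention time, capacity factor, LOQ, R-squared and the two RSDs.
#'
#' @param calibration an `nad_calibration`.
#' @param panel an `nad_panel`.
#' @param method_rsd,system_rsd named per-metabolite RSD vectors (optional).
#' @param t0 named void times per separation in minutes (defaults 1.40 for
#'   both, inferred from the published (RT, k') pairs).
#' @return data.frame of class `nad_qc`: `metabolite`, `rt`, `k_prime`,
#'   `loq_pmol`, `r2`, `rsd_method_pct`, `rsd_system_pct`.
#' @export
qc_report <- function(calibration, panel, method_rsd = NULL,
                      system_rsd = NULL,
                      t0 = c(alkaline = 1.4, acidic = 1.4)) {
  m <- panel$metabolites[panel$metabolites$quantifiable, ]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    met <- m$name[i]
    curve <- calibration$curves[[met]]
    data.frame(metabolite = met, rt = m$rt_min[i],
               k_prime = capacity_factor(m$rt_min[i], t0[[m$separation[i]]]),
               loq_pmol = if (is.null(curve)) NA_real_ else curve$loq_pmol,
               r2 = if (is.null(curve)) NA_real_ else curve$r_squared,
               rsd_method_pct = if (met %in% names(method_rsd))
                 method_rsd[[met]] else NA_real_,
               rsd_system_pct = if (met %in% names(system_rsd))
                 system_rsd[[met]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("nad_qc", "data.frame"))
}
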