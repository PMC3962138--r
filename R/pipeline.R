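# End-to-end processing: traces -> peaks -> curves/lot -> amounts -> report.

#' Integrate and assign the channels of one injection
#'
#' Estimates per-channel noise (excluding windows around the channel's own
#' retention time and any crosstalk-source RT that can feed it), detects and
#' integrates peaks, and selects each channel's peak by retention-time
#' window. Unselected peaks are kept for the crosstalk audit.
#'
#' @param injection a simulated injection (list with `traces`) or a named
#'   list of traces.
#' @param panel an `nad_panel`.
#' @param rt_window selection half-window in minutes (default 0.3).
#' @param threshold detection threshold in noise units.
#' @param noise_floor floor for the noise estimate.
#' @param injection_id identifier for the output rows.
#' @return list with `assigned` (one row per channel: area/height/s2n of the
#'   selected peak, `found` flag) and `peaks` (every detected peak, with a
#'   `selected` flag).
#' @export
process_injection <- function(injection, panel, rt_window = 0.3,
                              threshold = 3, noise_floor = 1,
                              injection_id = NULL) {
  traces <- if (!is.null(injection$traces)) injection$traces else injection
  if (is.null(injection_id))
    injection_id <- injection$injection_id %||% "inj"
  ch <- sim_channels(panel)
  ch <- ch[ch$channel_id %in% names(traces), , drop = FALSE]
  assigned <- vector("list", nrow(ch))
  allpeaks <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    tr <- traces[[ch$channel_id[i]]]
    met <- ch$metabolite[i]
    rts <- c(ch$rt[i], crosstalk_feeders(panel, met, ch$isotope[i])$rt)
    excl <- lapply(rts, function(r) c(r - rt_window, r + rt_window))
    noise <- tryCatch(estimate_noise(tr, excl, floor = noise_floor),
                      error = function(e) estimate_noise(tr, NULL,
                                                         floor = noise_floor))
    pk <- detect_and_integrate(tr, noise = noise, threshold = threshold)
    sel <- select_peak(pk, ch$rt[i], rt_window)
    if (nrow(pk)) {
      pk$selected <- FALSE
      if (!is.null(sel))
        pk$selected[pk$apex_rt == sel$apex_rt[1]] <- TRUE
      pk <- cbind(injection_id = injection_id, channel_id = ch$channel_id[i],
                  metabolite = met, isotope = ch$isotope[i], pk,
                  stringsAsFactors = FALSE)
      allpeaks[[i]] <- pk
    }
    assigned[[i]] <- data.frame(
      injection_id = injection_id, channel_id = ch$channel_id[i],
      metabolite = met, isotope = ch$isotope[i],
      apex_rt = if (is.null(sel)) NA_real_ else sel$apex_rt,
      area = if (is.null(sel)) NA_real_ else sel$area,
      height = if (is.null(sel)) NA_real_ else sel$height,
      noise = noise,
      s2n = if (is.null(sel)) NA_real_ else sel$s2n,
      found = !is.null(sel), stringsAsFactors = FALSE)
  }
  list(assigned = do.call(rbind, assigned),
       peaks = do.call(rbind, allpeaks[!vapply(allpeaks, is.null, logical(1))]))
}

# Assigned table for a whole dataset part (standards, qc or samples); uses
# the fast-path `areas` tables when the part was simulated without traces.
assign_part <- function(part, panel, rt_window = 0.3, threshold = 3,
                        noise_floor = 1) {
  out <- lapply(part$injections, function(inj) {
    if (!is.null(inj$areas)) return(list(assigned = inj$areas, peaks = NULL))
    process_injection(inj, panel, rt_window, threshold, noise_floor)
  })
  list(assigned = do.call(rbind, lapply(out, `[[`, "assigned")),
       peaks = do.call(rbind, lapply(out, `[[`, "peaks")))
}

#' Build the calibration from processed standard injections
#'
#' Fits one standard curve per quantifiable metabolite from the light
#' channels of the standard series, assigns pmol amounts to the heavy lot
#' ([assign_lot()]) and derives the surrogate correction factors (IMP via
#' the extract NMN peak, NA via heavy Nam).
#'
#' @param standards an `nad_dataset_part` from [simulate_standard_series()]
#'   (or a compatible list with `injections` and `levels_uM`).
#' @param panel an `nad_panel`.
#' @param config a [sim_config()] (bookkeeping: mix fraction, injection
#'   volume, noise floor).
#' @param rt_window,threshold peak processing parameters.
#' @return an object of class `nad_calibration`: list with `curves` (named
#'   list of `nad_calcurve`), `lot` (see [assign_lot()]), `cf` (named
#'   correction factors), `assigned`, `peaks`, `levels_uM`, `pmol_levels`.
#' @export
build_calibration <- function(standards, panel, config, rt_window = 0.3,
                              threshold = 3) {
  levels_uM <- standards$levels_uM %||% config$levels_uM
  pa <- assign_part(standards, panel, rt_window, threshold,
                    noise_floor = config$noise_floor)
  asg <- pa$assigned
  ids <- unique(asg$injection_id)
  if (length(ids) != length(levels_uM))
    stop("standard series has ", length(ids), " injections for ",
         length(levels_uM), " levels")
  pmol <- on_column_amounts(levels_uM, config$mix_fraction,
                            config$injection_volume_ul)
  level_of <- stats::setNames(pmol, ids)
  asg$nominal_pmol <- unname(level_of[asg$injection_id])
  q <- panel$metabolites$name[panel$metabolites$quantifiable]
  curves <- list()
  for (met in q) {
    rows <- asg[asg$metabolite == met & asg$isotope == "light", ]
    pts <- data.frame(pmol = rows$nominal_pmol, area = rows$area,
                      s2n = rows$s2n)
    pts$area[!rows$found] <- NA_real_
    curves[[met]] <- fit_calibration(pts, metabolite = met)
  }
  lot <- assign_lot(asg, curves, panel)
  cf <- list()
  light <- function(met) asg[asg$metabolite == met & asg$isotope == "light" &
                               asg$nominal_pmol > 0, ]
  # response factors are taken from levels where both channels are at or
  # above S/N 10: below the LOQ a level's area ratio is noise-dominated
  quantifiable_pair <- function(a, b) {
    ok <- !is.na(a$s2n) & !is.na(b$s2n) & a$s2n >= 10 & b$s2n >= 10
    if (sum(ok) >= 2L) ok else !is.na(a$area) & !is.na(b$area)
  }
  if (all(c("IMP", "NMN") %in% q)) {
    ti <- light("IMP"); tn <- light("NMN")
    tn <- tn[match(ti$injection_id, tn$injection_id), ]
    ok <- quantifiable_pair(ti, tn)
    cf[["IMP"]] <- correction_factor(ti$area[ok], ti$nominal_pmol[ok],
                                     tn$area[ok], tn$nominal_pmol[ok])
  }
  if (all(c("NA", "Nam") %in% q)) {
    ta <- light("NA")
    hn <- asg[asg$metabolite == "Nam" & asg$isotope == "heavy", ]
    hn <- hn[match(ta$injection_id, hn$injection_id), ]
    nam_pmol <- lot$assigned_pmol[lot$metabolite == "Nam"]
    ok <- quantifiable_pair(ta, hn)
    cf[["NA"]] <- correction_factor(ta$area[ok], ta$nominal_pmol[ok],
                                    hn$area[ok], rep(nam_pmol, sum(ok)))
  }
  structure(list(curves = curves, lot = lot, cf = cf, assigned = asg,
                 peaks = pa$peaks, levels_uM = levels_uM,
                 pmol_levels = pmol),
            class = "nad_calibration")
}

#' @export
print.nad_calibration <- function(x, ...) {
  cat("Calibration over", length(x$levels_uM), "levels (",
      min(x$pmol_levels[x$pmol_levels > 0]), "-", max(x$pmol_levels),
      "pmol ):", length(x$curves), "curves\n")
  cat("Lot:", sum(x$lot$via == "own"), "metabolites assigned directly;",
      sum(x$lot$via != "own"), "via correction factor\n")
  if (length(x$cf))
    cat("Correction factors:",
        paste(sprintf("%s %.3g", names(x$cf), unlist(x$cf)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Assign pmol amounts to the internal-standard lot
#'
#' Interpolates each metabolite's heavy-channel areas (across the standard
#' injections, which all carry the same lot aliquot) on that metabolite's
#' light standard curve; the mean over the technical replicates is the
#' assigned amount, reported with its CV. Analytes routed through a
#' surrogate (IMP, NA) are marked `via = "correction_factor"` instead of
#' raising an error when their heavy peak is absent; a missing heavy peak
#' for any own-channel analyte is an error naming the metabolite.
#'
#' @param assigned assigned-areas table of the standard series (from
#'   [build_calibration()] internals or [process_injection()]).
#' @param curves named list of `nad_calcurve`.
#' @param panel an `nad_panel`.
#' @param min_replicates minimum technical replicates (default 2).
#' @return data.frame of class `nad_lot`: `metabolite`, `assigned_pmol`,
#'   `cv_pct`, `n`, `via`.
#' @export
assign_lot <- function(assigned, curves, panel, min_replicates = 2L) {
  routing <- internal_standard_routing(panel)
  rows <- vector("list", nrow(routing))
  for (i in seq_len(nrow(routing))) {
    met <- routing$metabolite[i]
    if (routing$via[i] == "correction_factor") {
      rows[[i]] <- data.frame(metabolite = met, assigned_pmol = NA_real_,
                              cv_pct = NA_real_, n = 0L,
                              via = paste0("correction_factor:",
                                           routing$surrogate[i]),
                              stringsAsFactors = FALSE)
      next
    }
    hv <- assigned[assigned$metabolite == met & assigned$isotope == "heavy" &
                     assigned$found, ]
    if (nrow(hv) < min_replicates)
      stop("heavy peak missing (", nrow(hv), " replicate(s)) for ", met)
    est <- as.numeric(interpolate_amount(curves[[met]], hv$area))
    rows[[i]] <- data.frame(
      metabolite = met, assigned_pmol = mean(est),
      cv_pct = if (length(est) > 1) stats::sd(est) / mean(est) * 100 else 0,
      n = length(est), via = "own", stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("nad_lot", "data.frame"))
}

#' Quantify analyte amounts in one processed injection
#'
#' Applies the isotope-dilution ratio (own heavy channel) or the
#' surrogate-corrected ratio (IMP via NMN, NA via heavy Nam) to the selected
#' peak areas of one injection.
#'
#' @param assigned assigned-areas table of one injection.
#' @param calibration an `nad_calibration`.
#' @param panel an `nad_panel`.
#' @return data.frame `metabolite`, `raw_pmol`, `flag`
#'   (`ok`/`below_loq`/`via_correction`/`excluded`), `loq_pmol`, `note`.
#' @export
quantify_injection <- function(assigned, calibration, panel) {
  routing <- internal_standard_routing(panel)
  lot <- calibration$lot
  area_of <- function(met, iso) {
    r <- assigned[assigned$metabolite == met & assigned$isotope == iso, ]
    if (nrow(r) == 0L || !r$found[1]) NA_real_ else r$area[1]
  }
  rows <- vector("list", nrow(routing))
  for (i in seq_len(nrow(routing))) {
    met <- routing$metabolite[i]
    sur <- routing$surrogate[i]
    light <- area_of(met, "light")
    heavy <- area_of(sur, "heavy")
    sur_pmol <- lot$assigned_pmol[lot$metabolite == sur]
    curve <- calibration$curves[[met]]
    loq <- curve$loq_pmol
    note <- ""
    if (is.na(heavy) || length(sur_pmol) == 0L || is.na(sur_pmol)) {
      flag <- "excluded"
      pm <- NA_real_
      note <- paste0("internal-standard peak missing (", sur, ")")
    } else if (routing$via[i] == "correction_factor") {
      pm <- corrected_pmol(ifelse(is.na(light), 0, light), heavy, sur_pmol,
                           calibration$cf[[met]])
      flag <- "via_correction"
    } else {
      pm <- isotope_dilution_pmol(ifelse(is.na(light), 0, light), heavy,
                                  sur_pmol)
      flag <- "ok"
    }
    if (!is.na(pm) && !is.na(loq) && pm < loq) flag <- "below_loq"
    if (is.na(light) && flag != "excluded") flag <- "below_loq"
    if (met == "NADP")
      note <- "may include oxidized NADPH; interpret with care"
    if (met == "Nam")
      note <- paste0(note, if (nzchar(note)) "; ",
                     "membrane permeable: losses to supernatants possible")
    rows[[i]] <- data.frame(metabolite = met, raw_pmol = pm, flag = flag,
                            loq_pmol = loq, note = note,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Quantify a set of sample injections to intracellular concentrations
#'
#' Runs peak processing and [quantify_injection()] on every sample
#' injection, then converts amounts to intracellular uM through the
#' sample-prep volume bookkeeping. Below-LOQ analytes carry a concentration
#' bound (the LOQ pushed through the same bookkeeping), not a value.
#'
#' @param samples an `nad_dataset_part` (type `"sample"`) or list of
#'   injections.
#' @param calibration an `nad_calibration`.
#' @param prep a [sample_prep()].
#' @param panel an `nad_panel`.
#' @param config a [sim_config()] (processing parameters).
#' @param rt_window,threshold peak processing parameters.
#' @return data.frame of class `nad_quant`: per injection and metabolite,
#'   `pmol_on_column`, `mol_in_sample`, `conc_uM`, `flag`, `bound_uM`,
#'   `raw_pmol`, `note`.
#' @export
quantify_samples <- function(samples, calibration, prep, panel, config,
                             rt_window = 0.3, threshold = 3) {
  part <- if (!is.null(samples$injections)) samples else
    list(injections = samples)
  pa <- assign_part(part, panel, rt_window, threshold,
                    noise_floor = config$noise_floor)
  asg <- pa$assigned
  out <- lapply(unique(asg$injection_id), function(id) {
    qi <- quantify_injection(asg[asg$injection_id == id, ], calibration,
                             panel)
    qi$injection_id <- id
    qi
  })
  res <- do.call(rbind, out)
  eff_nl <- prep$effective_nl
  quantified <- res$flag %in% c("ok", "via_correction")
  res$pmol_on_column <- ifelse(quantified, res$raw_pmol, NA_real_)
  res$mol_in_sample <- res$pmol_on_column * 1e-12 / prep$analyzed_fraction
  res$conc_uM <- ifelse(quantified,
                        to_concentration(res$raw_pmol, eff_nl), NA_real_)
  res$bound_uM <- ifelse(res$flag == "below_loq",
                         to_concentration(res$loq_pmol, eff_nl), NA_real_)
  res <- res[, c("injection_id", "metabolite", "pmol_on_column",
                 "mol_in_sample", "conc_uM", "flag", "bound_uM", "raw_pmol",
                 "loq_pmol", "note")]
  structure(res, class = c("nad_quant", "data.frame"),
            prep = prep, peaks = pa$peaks, assigned = asg)
}

#' Reporting-style results table
#'
#' Aggregates replicate injections (mean +/- across-sample SD, the default
#' replicate convention), prints concentrations to two significant figures,
#' renders below-LOQ analytes as `"<bound"`, and appends the summary redox
#' ratios: NAD+/NADH to the nearest integer and NAD+/NADP to one decimal.
#' AMP is not in the panel and NADPH is never quantifiable, so neither can
#' appear.
#'
#' @param results an `nad_quant` from [quantify_samples()].
#' @return list of class `nad_report`: `table` (metabolite, mean_uM, sd_uM,
#'   display, flag, note), `ratios` (named: `NAD_NADH`, `NAD_NADP`),
#'   `footnotes`.
#' @export
nad_report <- function(results) {
  agg <- split(as.data.frame(results), results$metabolite)
  rows <- lapply(agg, function(d) {
    conc <- d$conc_uM[!is.na(d$conc_uM)]
    idx <- which(!is.na(d$conc_uM))
    flag <- if (all(d$flag == "below_loq")) "below_loq" else
      if (any(d$flag == "excluded") && !length(conc)) "excluded" else
        d$flag[if (length(idx)) idx[1] else 1L]
    mean_uM <- if (length(conc)) mean(conc) else NA_real_
    sd_uM <- if (length(conc) > 1) stats::sd(conc) else NA_real_
    bound <- suppressWarnings(max(d$bound_uM, na.rm = TRUE))
    display <- if (!is.na(mean_uM)) {
      paste0(signif(mean_uM, 2),
             if (!is.na(sd_uM)) paste0(" ± ", signif(sd_uM, 2)))
    } else if (is.finite(bound)) paste0("<", signif(bound, 2)) else "n.q."
    data.frame(metabolite = d$metabolite[1], mean_uM = mean_uM,
               sd_uM = sd_uM, display = display, flag = flag,
               note = d$note[1], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-replace(tab$mean_uM, is.na(tab$mean_uM), -Inf)), ]
  rownames(tab) <- NULL
  conc_of <- function(met) tab$mean_uM[tab$metabolite == met]
  ratios <- c(NAD_NADH = NA_real_, NAD_NADP = NA_real_)
  if (length(conc_of("NAD")) && length(conc_of("NADH")) &&
      isTRUE(conc_of("NADH") > 0))
    ratios["NAD_NADH"] <- round(conc_of("NAD") / conc_of("NADH"))
  if (length(conc_of("NAD")) && length(conc_of("NADP")) &&
      isTRUE(conc_of("NADP") > 0))
    ratios["NAD_NADP"] <- round(conc_of("NAD") / conc_of("NADP"), 1)
  structure(list(table = tab, ratios = ratios,
                 footnotes = unique(tab$note[nzchar(tab$note)])),
            class = "nad_report")
}

#' @export
print.nad_report <- function(x, ...) {
  cat("Intracellular concentrations (uM):\n")
  w <- max(nchar(x$table$metabolite))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-*s  %s\n", w, x$table$metabolite[i], x$table$display[i]))
  if (!is.na(x$ratios["NAD_NADH"]))
    cat("  NAD+/NADH ", x$ratios[["NAD_NADH"]], "\n")
  if (!is.na(x$ratios["NAD_NADP"]))
    cat("  NAD+/NADP ", x$ratios[["NAD_NADP"]], "\n")
  for (f in x$footnotes) cat("  note:", f, "\n")
  invisible(x)
}
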