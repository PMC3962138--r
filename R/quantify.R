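# Isotope-dilution quantification and extraction-volume bookkeeping.
#
# The central design point of the assay: co-eluting light (12C, experimental)
# and heavy (13C/18O, internal standard) isotopologues experience the same
# ionization suppression, so the light/heavy peak-area ratio times the known
# heavy amount recovers the light amount regardless of matrix effects.
# Volume bookkeeping then converts pmol on column to intracellular molar
# concentration: the dried metabolite pellet is resuspended at 100 ul per
# 3.6 mg of particulate, diluted to OD260 = 14, mixed 1:1 with internal
# standards, and 2.5 ul injected, so the injected material contains a known
# fraction of the total intracellular volume (cell count x per-cell volume).

#' Resuspension volume from dry particulate mass
#'
#' 3.6 mg of cell-derived particulate corresponds to a metabolite pellet
#' resuspended in 100 ul; volumes scale linearly with mass.
#'
#' @param dry_mass_mg dried particulate mass in mg (> 0).
#' @return resuspension volume in ul.
#' @examples
#' resuspension_volume(3.6)  # 100
#' @export
resuspension_volume <- function(dry_mass_mg) {
  if (any(dry_mass_mg <= 0)) stop("dry mass must be > 0")
  dry_mass_mg / 3.6 * 100
}

#' Dilute to the target OD260
#'
#' Samples at or above OD260 = 14 are diluted to 14, multiplying the volume
#' by od260/14. Below-target samples are processed undiluted (there is no
#' concentration step) and flagged with a warning and the
#' `"below_target_od"` attribute.
#'
#' @param volume_ul current volume in ul.
#' @param od260 measured absorbance at 260 nm (> 0).
#' @param target target OD260 (default 14).
#' @return final volume in ul (attribute `below_target_od` set when
#'   `od260 < target`).
#' @export
od_normalized_volume <- function(volume_ul, od260, target = 14) {
  stopifnot(volume_ul > 0, od260 > 0, target > 0)
  if (od260 >= target) {
    out <- volume_ul * od260 / target
    attr(out, "below_target_od") <- FALSE
  } else {
    warning("OD260 (", od260, ") below target (", target,
            "); sample processed without dilution")
    out <- volume_ul
    attr(out, "below_target_od") <- TRUE
  }
  out
}

#' Total intracellular volume of the harvested cells
#'
#' Cell count times the per-cell volume (yeast 70 fl; HeLa-like mammalian
#' cells 2.5 pl), reported in ul.
#'
#' @param cell_count number of cells (>= 0).
#' @param per_cell_volume volume of one cell, in `unit`.
#' @param unit `"fl"` or `"pl"`.
#' @return intracellular volume in ul.
#' @examples
#' intracellular_volume(3e7, 70, "fl")   # 2.1 ul
#' intracellular_volume(4e6, 2.5, "pl")  # 10 ul
#' @export
intracellular_volume <- function(cell_count, per_cell_volume = 70,
                                 unit = c("fl", "pl")) {
  unit <- match.arg(unit)
  stopifnot(cell_count >= 0, per_cell_volume >= 0)
  scale <- c(fl = 1e-9, pl = 1e-6)[[unit]]
  cell_count * per_cell_volume * scale
}

#' Effective analyzed intracellular volume
#'
#' The injected material contains `injection_volume x mix_fraction` of the
#' final extract; that analyzed fraction of the intracellular volume is the
#' volume that divides mol on column to give intracellular concentration.
#'
#' @param intracellular_ul total intracellular volume (ul).
#' @param final_volume_ul final extract volume after OD normalization (ul).
#' @param injection_volume_ul injected volume (default 2.5 ul).
#' @param mix_fraction extract fraction of the injected solution
#'   (default 0.5).
#' @return effective analyzed volume in nl.
#' @examples
#' effective_analyzed_volume(2.1, 100)  # 26.25 nl
#' @export
effective_analyzed_volume <- function(intracellular_ul, final_volume_ul,
                                      injection_volume_ul = 2.5,
                                      mix_fraction = 0.5) {
  stopifnot(final_volume_ul > 0, intracellular_ul >= 0)
  frac <- injection_volume_ul * mix_fraction / final_volume_ul
  if (frac > 1) stop("analyzed volume exceeds the final extract volume")
  frac * intracellular_ul * 1000
}

#' Isotope-dilution amount from a light/heavy area ratio
#'
#' pmol = light_area / heavy_area x heavy_pmol. Because suppression
#' multiplies both co-eluting isotopologue areas identically, it cancels in
#' the ratio. A missing or zero heavy area makes the analyte unquantifiable
#' in that injection: `NA` is returned rather than a number.
#'
#' @param light_area light (12C) peak area.
#' @param heavy_area heavy internal-standard peak area.
#' @param heavy_pmol known heavy amount on column (> 0).
#' @return amount in pmol, or `NA` when the heavy peak is absent.
#' @export
isotope_dilution_pmol <- function(light_area, heavy_area, heavy_pmol) {
  if (any(heavy_pmol <= 0, na.rm = TRUE))
    stop("heavy internal-standard amount must be > 0")
  out <- light_area / heavy_area * heavy_pmol
  out[!is.finite(heavy_area) | heavy_area <= 0] <- NA_real_
  out
}

#' Surrogate-corrected amount
#'
#' For analytes without a usable heavy channel, a surrogate heavy peak and a
#' response-factor correction factor stand in:
#' pmol = (light_area / surrogate_heavy_area) x surrogate_pmol / cf.
#' With cf = 1 this reduces exactly to [isotope_dilution_pmol()].
#'
#' @param light_area_target light area of the target analyte.
#' @param heavy_area_surrogate heavy area of the surrogate.
#' @param surrogate_pmol known heavy amount of the surrogate (> 0).
#' @param cf correction factor from [correction_factor()] (> 0).
#' @return amount in pmol, or `NA` when the surrogate heavy peak is absent.
#' @export
corrected_pmol <- function(light_area_target, heavy_area_surrogate,
                           surrogate_pmol, cf) {
  if (any(cf <= 0)) stop("correction factor must be > 0")
  isotope_dilution_pmol(light_area_target, heavy_area_surrogate,
                        surrogate_pmol) / cf
}

#' Convert an on-column amount to intracellular concentration
#'
#' pmol divided by the effective analyzed volume; 1 pmol in 1 nl is 1 mM,
#' so uM = pmol / nl x 1000 (e.g. 1 pmol / 26 nl ~ 38.5 uM).
#'
#' @param pmol_on_column amount in pmol.
#' @param effective_volume_nl effective analyzed intracellular volume (nl,
#'   > 0).
#' @return concentration in uM.
#' @export
to_concentration <- function(pmol_on_column, effective_volume_nl) {
  stopifnot(effective_volume_nl > 0)
  pmol_on_column / effective_volume_nl * 1000
}

#' Sample-preparation bookkeeping
#'
#' Bundles the prep metadata and derives every volume the pipeline needs:
#' resuspension volume from the dry mass, final volume from the OD260
#' normalization, intracellular volume from the cell count, the analyzed
#' fraction and the effective analyzed volume.
#'
#' @param cell_count harvested cells.
#' @param per_cell_volume single-cell volume in `volume_unit` (yeast 70 fl,
#'   HeLa 2.5 pl).
#' @param volume_unit `"fl"` or `"pl"`.
#' @param dry_mass_mg dried particulate mass (mg).
#' @param od260 measured OD260 of the resuspension.
#' @param mix_fraction extract fraction of the injected solution.
#' @param injection_volume_ul injected volume (ul).
#' @return an object of class `nad_prep` (a list of inputs plus
#'   `resuspension_ul`, `final_ul`, `intracellular_ul`, `analyzed_fraction`,
#'   `effective_nl`).
#' @examples
#' sample_prep(3e7, 70, "fl", dry_mass_mg = 3.6, od260 = 14)
#' @export
sample_prep <- function(cell_count, per_cell_volume = 70,
                        volume_unit = c("fl", "pl"), dry_mass_mg = 3.6,
                        od260 = 14, mix_fraction = 0.5,
                        injection_volume_ul = 2.5) {
  volume_unit <- match.arg(volume_unit)
  stopifnot(mix_fraction > 0, mix_fraction <= 1, injection_volume_ul > 0)
  resus <- resuspension_volume(dry_mass_mg)
  final_ul <- suppressWarnings(od_normalized_volume(resus, od260))
  ic <- intracellular_volume(cell_count, per_cell_volume, volume_unit)
  eff <- effective_analyzed_volume(ic, as.numeric(final_ul),
                                   injection_volume_ul, mix_fraction)
  structure(list(cell_count = cell_count, per_cell_volume = per_cell_volume,
                 volume_unit = volume_unit, dry_mass_mg = dry_mass_mg,
                 od260 = od260, mix_fraction = mix_fraction,
                 injection_volume_ul = injection_volume_ul,
                 resuspension_ul = resus, final_ul = as.numeric(final_ul),
                 below_target_od = isTRUE(attr(final_ul, "below_target_od")),
                 intracellular_ul = ic,
                 analyzed_fraction = injection_volume_ul * mix_fraction /
                   as.numeric(final_ul),
                 effective_nl = eff),
            class = "nad_prep")
}

#' @export
print.nad_prep <- function(x, ...) {
  cat(sprintf(paste0(
    "Sample prep: %.3g cells x %.3g %s -> intracellular %.3g ul\n",
    "  resuspension %.3g ul (%.3g mg), final %.3g ul (OD260 %.3g%s)\n",
    "  analyzed fraction %.3g%% -> effective volume %.4g nl\n"),
    x$cell_count, x$per_cell_volume, x$volume_unit, x$intracellular_ul,
    x$resuspension_ul, x$dry_mass_mg, x$final_ul, x$od260,
    if (x$below_target_od) ", below target: not diluted" else "",
    100 * x$analyzed_fraction, x$effective_nl))
  invisible(x)
}
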