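# Synthetic SRM run generator.
#
# Emulates the assay's raw data: per-channel traces with Gaussian peaks at
# the registry retention times, multiplicative ionization suppression shared
# between the light and heavy isotopologue channels of a metabolite,
# on-source fragmentation crosstalk (source signal appearing in the target
# channel at the SOURCE retention time, the source retaining 1 - fraction),
# isotopologue channel bleed (the natural +1/+2 Da isotope peak of a light
# source adding into a neighbour channel, again at the source RT), and
# mean-zero Gaussian baseline noise on baseline-corrected traces.
#
# Default response factors are derived from the assay's published
# sensitivities: rf = 10 x sigma_b x sigma_peak x sqrt(2*pi) / LOQ at the
# reference noise (sigma_b = 50 counts) and peak width (0.05 min), so that
# the designed S/N = 10 crossing of each channel sits at its published LOQ
# and the LOQ ordering across metabolites is reproduced.

# Published per-metabolite LOQs (pmol) used to scale default response
# factors; NADPH has no published LOQ and gets a mid-range default.
DESIGN_LOQ <- c(
  Nam = 0.6, "NA" = 2.5, Cytidine = 0.01, Uridine = 3.1, NR = 0.01,
  NAR = 0.1, Inosine = 0.03, CMP = 0.09, UMP = 0.06, NMN = 1, NAMN = 0.06,
  IMP = 0.1, ADP = 0.03, ATP = 1, ADPr = 0.02, NAD = 0.19, NAAD = 0.02,
  NADH = 0.19, NADP = 0.06, NADPH = 0.19)

REF_BASELINE_SIGMA <- 50
REF_PEAK_SIGMA <- 0.05

#' Default simulator response factors
#'
#' counts.min per pmol for each channel, scaled so the designed S/N = 10
#' crossing at reference noise sits at the assay's published LOQ.
#'
#' @return named numeric vector.
#' @export
default_response_factors <- function() {
  10 * REF_BASELINE_SIGMA * REF_PEAK_SIGMA * sqrt(2 * pi) / DESIGN_LOQ
}

#' Designed limit of quantification of a simulator configuration
#'
#' Closed-form S/N = 10 crossing: the amount whose noise-free peak height
#' (area / (sigma * sqrt(2*pi))) equals 10 x the baseline noise sigma. This
#' is the ground truth against which the empirical LOQ estimator is judged.
#'
#' @param config a [sim_config()].
#' @return named vector of pmol amounts (Inf when noise-free).
#' @export
designed_loq <- function(config) {
  10 * config$baseline_sigma * config$peak_sigma * sqrt(2 * pi) /
    config$response_factors
}

#' Simulator configuration
#'
#' @param seed integer seed; every stochastic simulator entry point derives
#'   its stream from it.
#' @param peak_sigma Gaussian peak width sigma in minutes.
#' @param baseline_sigma baseline noise sigma in counts (0 = noise-free).
#' @param dt trace sampling interval in minutes.
#' @param pad minutes of baseline kept either side of the peaks of a
#'   channel (the simulated acquisition window).
#' @param noise_floor floor for noise estimation on noise-free traces.
#' @param response_factors named counts.min-per-pmol vector.
#' @param heavy_rf_ratio heavy/light response-factor ratio (1: isotopologues
#'   ionize identically).
#' @param lot_pmol named on-column pmol of each 13C-extract metabolite in
#'   the standard lot aliquot (default 5 pmol; IMP 0, its extract peak being
#'   too small to use).
#' @param o18_spike_uM concentration of the 18O Nam/NR spike in the injected
#'   solution (1.5 uM).
#' @param levels_uM the standard series concentrations.
#' @param mix_fraction,injection_volume_ul mixing and injection bookkeeping.
#' @param suppression_range range of the per-injection shared suppression
#'   factor drawn for experimental samples (standards are clean solutions
#'   and get 1).
#' @param suppression optional fixed suppression: scalar or named
#'   per-metabolite vector, overriding the random draw.
#' @param prep_cv,injection_cv replicate model: coefficient of variation of
#'   independent sample preparations and of repeat injections (response
#'   drift, multiplying all areas of an injection jointly).
#' @param crosstalk logical: apply the panel's crosstalk map.
#' @param crosstalk_fractions optional named overrides, names
#'   `"source>target"`, replacing the panel's default fractions.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, peak_sigma = 0.05, baseline_sigma = 50,
                       dt = 0.01, pad = 1.2, noise_floor = 1,
                       response_factors = default_response_factors(),
                       heavy_rf_ratio = 1, lot_pmol = NULL,
                       o18_spike_uM = 1.5,
                       levels_uM = c(0, 0.1, 0.2, 0.6, 2, 6, 20, 60, 200),
                       mix_fraction = 0.5, injection_volume_ul = 2.5,
                       suppression_range = c(0.3, 1), suppression = NULL,
                       prep_cv = 0.05, injection_cv = 0.02,
                       crosstalk = TRUE, crosstalk_fractions = NULL) {
  structure(list(seed = as.integer(seed), peak_sigma = peak_sigma,
                 baseline_sigma = baseline_sigma, dt = dt, pad = pad,
                 noise_floor = noise_floor,
                 response_factors = response_factors,
                 heavy_rf_ratio = heavy_rf_ratio, lot_pmol = lot_pmol,
                 o18_spike_uM = o18_spike_uM, levels_uM = levels_uM,
                 mix_fraction = mix_fraction,
                 injection_volume_ul = injection_volume_ul,
                 suppression_range = suppression_range,
                 suppression = suppression, prep_cv = prep_cv,
                 injection_cv = injection_cv, crosstalk = crosstalk,
                 crosstalk_fractions = crosstalk_fractions),
            class = "sim_config")
}

#' Internal-standard routing
#'
#' Which heavy channel quantifies each analyte: the 18O vitamins for Nam and
#' NR; heavy Nam as surrogate (with a correction factor) for NA, which has
#' no carbohydrate to label; the 13C-extract NMN peak as surrogate for IMP,
#' whose extract peak is too small; each analyte's own 13C channel
#' otherwise.
#'
#' @param panel an `nad_panel`.
#' @return data.frame with columns `metabolite`, `standard_set`,
#'   `surrogate` (equal to `metabolite` for own-channel analytes) and `via`
#'   (`"own"` or `"correction_factor"`).
#' @export
internal_standard_routing <- function(panel) {
  m <- panel$metabolites
  q <- m$name[m$quantifiable]
  r <- data.frame(metabolite = q, standard_set = "C13_extract",
                  surrogate = q, via = "own", stringsAsFactors = FALSE)
  r$standard_set[r$metabolite %in% c("Nam", "NR", "NA")] <- "O18_vitamins"
  r$surrogate[r$metabolite == "NA"] <- "Nam"
  r$via[r$metabolite == "NA"] <- "correction_factor"
  r$surrogate[r$metabolite == "IMP"] <- "NMN"
  r$via[r$metabolite == "IMP"] <- "correction_factor"
  r
}

# Channels actually acquired: a light channel per panel metabolite, a heavy
# channel per metabolite that carries an internal standard (13C extract for
# alkaline analytes incl. non-reported NADPH, 18O for Nam and NR). The IMP
# heavy channel is acquired even though the lot amount is ~0.
sim_channels <- function(panel) {
  m <- panel$metabolites
  light <- data.frame(channel_id = paste0(m$name, ".light"),
                      metabolite = m$name, isotope = "light",
                      rt = m$rt_min, separation = m$separation,
                      stringsAsFactors = FALSE)
  hv <- panel$heavy
  hv <- hv[!(hv$metabolite %in% c("Nam", "NR") & hv$standard_set == "C13_extract"), ]
  hm <- m[match(hv$metabolite, m$name), ]
  heavy <- data.frame(channel_id = paste0(hv$metabolite, ".heavy"),
                      metabolite = hv$metabolite, isotope = "heavy",
                      rt = hm$rt_min, separation = hm$separation,
                      stringsAsFactors = FALSE)
  rbind(light, heavy)
}

#' On-column heavy amounts of the internal-standard lot
#'
#' @param panel an `nad_panel`.
#' @param config a [sim_config()].
#' @return named pmol vector over metabolites with a heavy channel.
#' @export
lot_pmol_on_column <- function(panel, config) {
  ch <- sim_channels(panel)
  mets <- ch$metabolite[ch$isotope == "heavy"]
  out <- stats::setNames(rep(5, length(mets)), mets)
  out["IMP"] <- 0
  o18 <- intersect(c("Nam", "NR"), mets)
  out[o18] <- config$o18_spike_uM * config$injection_volume_ul
  if (!is.null(config$lot_pmol))
    out[names(config$lot_pmol)] <- config$lot_pmol
  out
}

# Effective crosstalk rules under a config: panel defaults with optional
# per-rule fraction overrides; empty when crosstalk is disabled.
effective_crosstalk <- function(panel, config) {
  xt <- panel$crosstalk
  if (!is.null(config$crosstalk_fractions)) {
    key <- paste0(xt$source, ">", xt$target)
    hit <- key %in% names(config$crosstalk_fractions)
    xt$fraction[hit] <- unname(config$crosstalk_fractions[key[hit]])
  }
  if (!config$crosstalk) xt$fraction[] <- 0
  xt
}

#' Simulate one injection
#'
#' Generates every acquired channel of one injection as a trace (or, with
#' `traces = FALSE`, as an analytic peak-area table — the fast path used for
#' large Monte-Carlo studies) plus a ground-truth record.
#'
#' The acquisition window of each channel always spans its own retention
#' time and every crosstalk source RT that can feed it, padded by
#' `config$pad` minutes, independent of whether crosstalk is enabled — so a
#' given seed produces identical baseline noise with crosstalk on or off.
#'
#' @param panel an `nad_panel`.
#' @param config a [sim_config()].
#' @param light_pmol named pmol vector of light analytes on column (missing
#'   names = 0).
#' @param heavy_pmol named pmol vector for heavy channels; defaults to
#'   [lot_pmol_on_column()].
#' @param suppression scalar or named per-metabolite factor in (0, 1],
#'   applied identically to the light and heavy channels of a metabolite.
#' @param injection_factor multiplicative response drift applied to every
#'   area in the injection.
#' @param injection_id identifier written into the truth record.
#' @param traces emit time/intensity traces (`TRUE`) or the area-level fast
#'   path (`FALSE`).
#' @return list with `injection_id`, `traces` (named list, or `NULL`),
#'   `areas` (fast-path table, or `NULL`) and `truth` (data.frame
#'   `injection_id, metabolite, channel, true_pmol, pre_noise_area`).
#' @export
simulate_injection <- function(panel, config, light_pmol,
                               heavy_pmol = lot_pmol_on_column(panel, config),
                               suppression = 1, injection_factor = 1,
                               injection_id = "inj", traces = TRUE) {
  ch <- sim_channels(panel)
  unknown <- setdiff(names(light_pmol), panel$metabolites$name)
  if (length(unknown))
    stop("not in the registry: ", paste(unknown, collapse = ", "))
  rf <- config$response_factors
  miss <- setdiff(ch$metabolite, names(rf))
  if (length(miss))
    stop("no response factor for: ", paste(miss, collapse = ", "))
  supp <- if (length(suppression) == 1L && is.null(names(suppression)))
    stats::setNames(rep(suppression, nrow(ch)), ch$metabolite)[!duplicated(ch$metabolite)]
  else suppression
  sfac <- function(met) if (met %in% names(supp)) supp[[met]] else 1
  lp <- function(met) if (met %in% names(light_pmol)) light_pmol[[met]] else 0
  hp <- function(met) if (met %in% names(heavy_pmol)) heavy_pmol[[met]] else 0

  # pre-crosstalk areas per channel
  ch$pmol <- ifelse(ch$isotope == "light",
                    vapply(ch$metabolite, lp, 0),
                    vapply(ch$metabolite, hp, 0))
  ch$supp <- vapply(ch$metabolite, sfac, 0)
  ch$area0 <- ch$pmol * rf[ch$metabolite] * ch$supp * injection_factor *
    ifelse(ch$isotope == "heavy", config$heavy_rf_ratio, 1)

  xt <- effective_crosstalk(panel, config)
  frag <- xt[xt$mechanism == "on_source_fragmentation", , drop = FALSE]
  bleed <- xt[xt$mechanism == "isotopologue_bleed", , drop = FALSE]

  key <- paste(ch$metabolite, ch$isotope)
  a0 <- stats::setNames(ch$area0, key)
  retained <- a0
  extras <- list()  # per channel key: data.frame(rt, area)
  add_extra <- function(k, rt, area) {
    extras[[k]] <<- rbind(extras[[k]], data.frame(rt = rt, area = area))
  }
  rt_of <- stats::setNames(panel$metabolites$rt_min, panel$metabolites$name)
  for (i in seq_len(nrow(frag))) {
    src <- frag$source[i]; tgt <- frag$target[i]; f <- frag$fraction[i]
    for (iso in c("light", "heavy")) {
      ks <- paste(src, iso); kt <- paste(tgt, iso)
      if (!ks %in% key) next
      moved <- f * a0[[ks]]
      retained[[ks]] <- retained[[ks]] - moved
      if (kt %in% key && moved > 0) add_extra(kt, rt_of[[src]], moved)
    }
  }
  # bleed copies the source channel's entire light content — its retained
  # own peak and any fragmentation-derived peaks — so e.g. the NA channel
  # picks up peaks at NR's and NMN's RTs via the bleed of on-source Nam
  for (i in seq_len(nrow(bleed))) {
    src <- bleed$source[i]; tgt <- bleed$target[i]; f <- bleed$fraction[i]
    ks <- paste(src, "light"); kt <- paste(tgt, "light")
    if (!(ks %in% key && kt %in% key)) next
    if (retained[[ks]] > 0) add_extra(kt, rt_of[[src]], f * retained[[ks]])
    ex <- extras[[ks]]
    if (!is.null(ex))
      for (j in seq_len(nrow(ex)))
        if (ex$area[j] > 0) add_extra(kt, ex$rt[j], f * ex$area[j])
  }
  ch$area <- unname(retained[key])

  # which source RTs can ever feed each channel (crosstalk on or off):
  # fixes the acquisition window, hence the noise stream, per channel
  feeders <- function(met, iso) crosstalk_feeders(panel, met, iso)$rt

  truth <- data.frame(injection_id = injection_id, metabolite = ch$metabolite,
                      channel = ch$isotope, true_pmol = ch$pmol,
                      pre_noise_area = ch$area, stringsAsFactors = FALSE)

  if (!traces) {
    sig <- config$baseline_sigma *
      sqrt(config$dt * 6 * config$peak_sigma)  # trapezoid noise over ~6 sigma
    obs <- ch$area + if (config$baseline_sigma > 0)
      stats::rnorm(nrow(ch), 0, sig) else 0
    height <- ch$area / (config$peak_sigma * sqrt(2 * pi))
    noise <- max(config$baseline_sigma, config$noise_floor)
    areas <- data.frame(injection_id = injection_id,
                        channel_id = ch$channel_id,
                        metabolite = ch$metabolite, isotope = ch$isotope,
                        apex_rt = ch$rt, area = obs,
                        height = height, noise = noise,
                        s2n = height / noise, found = ch$area > 0,
                        stringsAsFactors = FALSE)
    return(list(injection_id = injection_id, traces = NULL, areas = areas,
                truth = truth))
  }

  out <- vector("list", nrow(ch))
  names(out) <- ch$channel_id
  for (i in seq_len(nrow(ch))) {
    rts <- c(ch$rt[i], feeders(ch$metabolite[i], ch$isotope[i]))
    lo <- max(0, min(rts) - config$pad)
    hi <- min(RUN_LENGTH[[ch$separation[i]]], max(rts) + config$pad)
    t <- seq(lo, hi, by = config$dt)
    y <- gauss_peak(t, ch$rt[i], ch$area[i], config$peak_sigma)
    ex <- extras[[key[i]]]
    if (!is.null(ex))
      for (j in seq_len(nrow(ex)))
        y <- y + gauss_peak(t, ex$rt[j], ex$area[j], config$peak_sigma)
    if (config$baseline_sigma > 0)
      y <- y + stats::rnorm(length(t), 0, config$baseline_sigma)
    out[[i]] <- transition_trace(ch$channel_id[i], t, y)
  }
  list(injection_id = injection_id, traces = out, areas = NULL, truth = truth)
}

gauss_peak <- function(t, rt, area, sigma) {
  if (area == 0) return(numeric(length(t)))
  area / (sigma * sqrt(2 * pi)) * exp(-(t - rt)^2 / (2 * sigma^2))
}

#' Simulate the standard series
#'
#' One injection per level of the series (default 0, 0.1, 0.2, 0.6, 2, 6,
#' 20, 60, 200 uM), each containing every quantifiable metabolite at the
#' level's on-column amount, mixed 1:1 with the internal-standard lot.
#' Standard solutions are clean matrices: suppression is 1.
#'
#' @param panel an `nad_panel`.
#' @param config a [sim_config()]; `config$seed` fixes the noise stream.
#' @param traces trace or fast-path output (see [simulate_injection()]).
#' @return list of class `nad_dataset_part`: `injections`, `levels_uM`,
#'   `truth` (bound truth records), `type = "standard"`.
#' @export
simulate_standard_series <- function(panel, config, traces = TRUE) {
  set.seed(config$seed)
  q <- panel$metabolites$name[panel$metabolites$quantifiable]
  heavy <- lot_pmol_on_column(panel, config)
  inj <- vector("list", length(config$levels_uM))
  for (i in seq_along(config$levels_uM)) {
    pm <- on_column_amounts(config$levels_uM[i], config$mix_fraction,
                            config$injection_volume_ul)
    inj[[i]] <- simulate_injection(
      panel, config, stats::setNames(rep(pm, length(q)), q), heavy,
      suppression = 1, injection_id = sprintf("std_%02d", i), traces = traces)
  }
  structure(list(injections = inj, levels_uM = config$levels_uM,
                 truth = do.call(rbind, lapply(inj, `[[`, "truth")),
                 type = "standard"),
            class = "nad_dataset_part")
}

#' Simulate precision-QC injection sets
#'
#' `n_method` independently prepared standard solutions at `conc_uM`
#' (per-metabolite preparation error with CV `prep_cv`), plus `n_system`
#' repeat injections of one solution (injection-level response drift with CV
#' `injection_cv` only). All are mixed with the lot like any standard.
#'
#' @param panel,config as elsewhere.
#' @param n_method,n_system replicate counts (assay defaults 6 and 4).
#' @param conc_uM solution concentration (assay default 10 uM).
#' @param traces trace or fast-path output.
#' @return list with `method` and `system` parts (`nad_dataset_part`s) and
#'   the designed CVs.
#' @export
simulate_qc_runs <- function(panel, config, n_method = 6L, n_system = 4L,
                             conc_uM = 10, traces = TRUE) {
  set.seed(config$seed + 1L)
  q <- panel$metabolites$name[panel$metabolites$quantifiable]
  heavy <- lot_pmol_on_column(panel, config)
  base_pm <- on_column_amounts(conc_uM, config$mix_fraction,
                               config$injection_volume_ul)
  make <- function(idx, prefix, prep_factors, inj_cv) {
    lp <- stats::setNames(base_pm * prep_factors, q)
    fac <- if (inj_cv > 0) 1 + stats::rnorm(1, 0, inj_cv) else 1
    simulate_injection(panel, config, lp, heavy, suppression = 1,
                       injection_factor = max(fac, 0.1),
                       injection_id = sprintf("%s_%02d", prefix, idx),
                       traces = traces)
  }
  method <- lapply(seq_len(n_method), function(i) {
    pf <- if (config$prep_cv > 0)
      pmax(1 + stats::rnorm(length(q), 0, config$prep_cv), 0.1)
    else rep(1, length(q))
    make(i, "method", pf, config$injection_cv)
  })
  pf_sys <- if (config$prep_cv > 0)
    pmax(1 + stats::rnorm(length(q), 0, config$prep_cv), 0.1)
  else rep(1, length(q))
  system <- lapply(seq_len(n_system), function(i)
    make(i, "system", pf_sys, config$injection_cv))
  part <- function(x, type) structure(
    list(injections = x, truth = do.call(rbind, lapply(x, `[[`, "truth")),
         type = type), class = "nad_dataset_part")
  list(method = part(method, "qc_method"), system = part(system, "qc_system"),
       designed_method_cv = sqrt(config$prep_cv^2 + config$injection_cv^2) * 100,
       designed_system_cv = config$injection_cv * 100)
}

#' Published cell-line concentrations used as the demo truth
#'
#' The measured NAD+ metabolome of a glioma cell line (uM); analytes
#' reported only as below-LOQ bounds enter the demo truth as 0.
#'
#' @return named numeric vector (uM).
#' @export
demo_concentrations <- function() {
  c(ATP = 1010, ADP = 890, UMP = 370, NAD = 260, Inosine = 250,
    Uridine = 210, CMP = 170, IMP = 98, NADP = 57, Nam = 39,
    Cytidine = 6.7, NADH = 6.7, ADPr = 6.7, NMN = 1.3,
    "NA" = 0, NR = 0, NAMN = 0, NAAD = 0, NAR = 0)
}

#' Simulate an experimental sample set
#'
#' Per replicate: preparation noise perturbs the true concentrations
#' (CV `prep_cv`), a shared suppression factor is drawn once per injection
#' (uniform over `suppression_range`, applied identically to light and heavy
#' channels), and an injection-level response drift (CV `injection_cv`)
#' multiplies all areas. The truth record carries each replicate's actual
#' on-column amounts.
#'
#' @param panel,config as elsewhere.
#' @param prep a [sample_prep()] describing the cells and volumes.
#' @param truth_conc_uM named true intracellular concentrations (uM);
#'   default [demo_concentrations()].
#' @param replicates number of sample replicates (>= 1).
#' @param traces trace or fast-path output.
#' @return `nad_dataset_part` with `injections`, `truth`, `truth_conc_uM`,
#'   `prep`, `type = "sample"`.
#' @export
simulate_experiment <- function(panel, config, prep,
                                truth_conc_uM = demo_concentrations(),
                                replicates = 3L, traces = TRUE) {
  stopifnot(replicates >= 1)
  set.seed(config$seed + 2L)
  heavy <- lot_pmol_on_column(panel, config)
  inj <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    conc <- truth_conc_uM
    if (config$prep_cv > 0)
      conc <- conc * pmax(1 + stats::rnorm(length(conc), 0, config$prep_cv), 0)
    lp <- conc * prep$effective_nl / 1000  # uM x ul-equivalent = pmol
    supp <- if (!is.null(config$suppression)) config$suppression
      else stats::runif(1, config$suppression_range[1], config$suppression_range[2])
    fac <- if (config$injection_cv > 0)
      max(1 + stats::rnorm(1, 0, config$injection_cv), 0.1) else 1
    inj[[r]] <- simulate_injection(panel, config, lp, heavy,
                                   suppression = supp, injection_factor = fac,
                                   injection_id = sprintf("sample_%02d", r),
                                   traces = traces)
  }
  structure(list(injections = inj,
                 truth = do.call(rbind, lapply(inj, `[[`, "truth")),
                 truth_conc_uM = truth_conc_uM, prep = prep, type = "sample"),
            class = "nad_dataset_part")
}
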