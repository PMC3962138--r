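# Shared fixtures: the built-in panel and lazily cached calibrations so the
# expensive standard-series simulations run once per suite.

PANEL <- load_registry()

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# noise-free configuration: deterministic areas, unit suppression (unless
# overridden)
config_noise_free <- function(seed = 1L, suppression = 1, ...) {
  sim_config(seed = seed, baseline_sigma = 0, prep_cv = 0, injection_cv = 0,
             suppression = suppression, ...)
}

calib_noise_free <- function() {
  cached("calib_nf", {
    cfg <- config_noise_free()
    std <- simulate_standard_series(PANEL, cfg)
    build_calibration(std, PANEL, cfg)
  })
}

# noise-free with the crosstalk map disabled end to end
calib_noise_free_clean <- function() {
  cached("calib_nf_clean", {
    cfg <- config_noise_free(crosstalk = FALSE)
    std <- simulate_standard_series(PANEL, cfg)
    build_calibration(std, PANEL, cfg)
  })
}

calib_default_noise <- function() {
  cached("calib_dn", {
    cfg <- sim_config(seed = 7L)
    std <- simulate_standard_series(PANEL, cfg)
    build_calibration(std, PANEL, cfg)
  })
}

demo_prep <- function() sample_prep(2e7, 2.5, "pl")

# designed LOQs at the reference noise level (the default configuration)
ref_loq <- function() designed_loq(sim_config())

# concentrations putting every quantifiable analyte at `mult` x its designed
# LOQ on column (for recovery studies)
conc_at_loq_multiple <- function(prep, mult = 20) {
  q <- PANEL$metabolites$name[PANEL$metabolites$quantifiable]
  pm <- ref_loq()[q] * mult
  pm / (prep$effective_nl / 1000)
}

# empirical LOQ from a dedicated dilution series bracketing the designed
# S/N = 10 crossing, averaged over replicate injections per level
measure_loq <- function(met, config, levels = c(0.5, 0.75, 1, 1.5, 2),
                        nrep = 3L) {
  amounts <- unname(ref_loq()[met]) * levels
  set.seed(config$seed)
  s2n <- vapply(amounts, function(a) {
    reps <- vapply(seq_len(nrep), function(r) {
      inj <- simulate_injection(PANEL, config,
                                stats::setNames(a, met),
                                heavy_pmol = numeric(0))
      one <- list(traces = inj$traces[paste0(met, ".light")])
      pr <- process_injection(one, PANEL)
      pr$assigned$s2n[1]
    }, 0)
    mean(reps, na.rm = TRUE)
  }, 0)
  loq_from_series(amounts, s2n)
}
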