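test_that("extraction volume bookkeeping reproduces the worked examples", {
  expect_equal(resuspension_volume(3.6), 100)
  expect_equal(resuspension_volume(7.2), 200)
  expect_error(resuspension_volume(0), "> 0")

  expect_equal(as.numeric(od_normalized_volume(100, 14)), 100)
  expect_equal(as.numeric(od_normalized_volume(100, 28)), 200)
  expect_warning(v <- od_normalized_volume(100, 10), "below target")
  expect_equal(as.numeric(v), 100)
  expect_true(attr(v, "below_target_od"))

  expect_equal(intracellular_volume(3e7, 70, "fl"), 2.1)
  expect_equal(intracellular_volume(0, 70, "fl"), 0)
  expect_equal(intracellular_volume(4e6, 2.5, "pl"), 10)

  expect_equal(effective_analyzed_volume(2.1, 100), 26.25)
  expect_equal(signif(effective_analyzed_volume(2.1, 100), 2), 26)
  # injecting the whole extract analyzes the whole intracellular volume
  expect_equal(effective_analyzed_volume(2.1, 2.5, 2.5, 1), 2100)
  # doubling the final volume halves the effective volume
  expect_equal(effective_analyzed_volume(2.1, 200),
               effective_analyzed_volume(2.1, 100) / 2)
  expect_error(effective_analyzed_volume(2.1, 1, 2.5, 1), "exceeds")
})

test_that("isotope-dilution ratios are exact and suppression-invariant", {
  expect_equal(isotope_dilution_pmol(100, 100, 5), 5)
  expect_equal(isotope_dilution_pmol(200, 100, 5), 10)
  s <- 0.37  # any joint suppression factor cancels
  expect_equal(isotope_dilution_pmol(200 * s, 100 * s, 5),
               isotope_dilution_pmol(200, 100, 5))
  expect_true(is.na(isotope_dilution_pmol(100, 0, 5)))
  expect_error(isotope_dilution_pmol(100, 100, 0), "> 0")
  # cf = 1 reduces the corrected form to plain isotope dilution
  expect_equal(corrected_pmol(200, 100, 5, 1), isotope_dilution_pmol(200, 100, 5))
  expect_equal(corrected_pmol(200, 100, 5, 2), 5)
  expect_error(corrected_pmol(200, 100, 5, 0), "> 0")
})

test_that("concentration conversion has the right unit algebra", {
  expect_equal(to_concentration(0, 26), 0)
  expect_equal(to_concentration(1, 1000), 1)       # 1 pmol in 1 ul = 1 uM
  expect_equal(to_concentration(1, 26), 1000 / 26) # ~38.5 uM
  expect_equal(round(to_concentration(6.76, 26)), 260)
})

test_that("prep bookkeeping is invariant to the declared per-cell unit", {
  a <- sample_prep(2e7, 2.5, "pl")
  b <- sample_prep(2e7, 2500, "fl")
  expect_equal(a$effective_nl, b$effective_nl)
  expect_equal(a$intracellular_ul, 50)
  expect_equal(a$analyzed_fraction, 0.0125)
})

test_that("surrogate-corrected analytes recover simulator truth within 5%", {
  calib <- calib_default_noise()
  prep <- demo_prep()
  conc <- conc_at_loq_multiple(prep, 20)
  errs <- c(IMP = 0, "NA" = 0)
  nseeds <- 8L
  for (k in seq_len(nseeds)) {
    cfg_k <- sim_config(seed = 100L + k)
    smp <- simulate_experiment(PANEL, cfg_k, prep, conc, replicates = 1L)
    res <- quantify_samples(smp, calib, prep, PANEL, cfg_k)
    tr <- smp$truth[smp$truth$channel == "light", ]
    for (met in names(errs)) {
      est <- res$raw_pmol[res$metabolite == met]
      tru <- tr$true_pmol[tr$metabolite == met]
      errs[met] <- errs[met] + est / tru / nseeds
    }
  }
  expect_lt(abs(errs[["IMP"]] - 1), 0.05)
  expect_lt(abs(errs[["NA"]] - 1), 0.05)
})

test_that("results table applies the reporting conventions", {
  cfg <- config_noise_free()
  calib <- calib_noise_free()
  prep <- demo_prep()
  smp <- simulate_experiment(PANEL, cfg, prep, replicates = 1L)
  res <- quantify_samples(smp, calib, prep, PANEL, cfg)
  rep <- nad_report(res)
  # published-style summary ratios from the demo concentrations
  expect_equal(unname(rep$ratios["NAD_NADH"]), 39)
  expect_equal(unname(rep$ratios["NAD_NADP"]), 4.6)
  # below-LOQ analytes render as "<bound", with a bound not a value
  tab <- rep$table
  na_row <- tab[tab$metabolite == "NA", ]
  expect_true(is.na(na_row$mean_uM))
  expect_match(na_row$display, "^<")
  # AMP and NADPH can never appear
  expect_false(any(c("AMP", "NADPH") %in% tab$metabolite))
  # NADP carries its interpretation caveat
  expect_match(tab$note[tab$metabolite == "NADP"], "NADPH")
})
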