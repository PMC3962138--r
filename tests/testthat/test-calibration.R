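test_that("standard-series bookkeeping spans 0.125-250 pmol", {
  series <- c(0, 0.1, 0.2, 0.6, 2, 6, 20, 60, 200)
  pm <- on_column_amounts(series)
  expect_equal(pm[1], 0)
  expect_equal(min(pm[pm > 0]), 0.125)
  expect_equal(max(pm), 250)
  expect_error(on_column_amounts(-1), ">= 0")
})

test_that("noiseless lines are fitted exactly", {
  pts <- data.frame(pmol = c(0.125, 0.25, 2.5, 25, 250),
                    area = 100 * c(0.125, 0.25, 2.5, 25, 250))
  cv <- fit_calibration(pts, "x")
  expect_equal(cv$slope, 100)
  expect_equal(cv$intercept, 0, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$linear_range, c(0.125, 250))
  expect_error(fit_calibration(pts[1:2, ]), "at least 3")
  expect_error(fit_calibration(transform(pts, area = 0)), "zero")
})

test_that("fitted coefficients match a closed-form normal-equations oracle", {
  set.seed(21)
  pmol <- c(0.125, 0.25, 0.75, 2.5, 7.5, 25, 75, 250)
  area <- 40 * pmol + 3 + rnorm(length(pmol), 0, 5)
  cv <- fit_calibration(data.frame(pmol = pmol, area = area))
  # independent oracle: normal equations solved by hand
  n <- length(pmol)
  sxx <- sum(pmol^2) - sum(pmol)^2 / n
  sxy <- sum(pmol * area) - sum(pmol) * sum(area) / n
  slope <- sxy / sxx
  intercept <- mean(area) - slope * mean(pmol)
  expect_equal(cv$slope, slope, tolerance = 1e-9)
  expect_equal(cv$intercept, intercept, tolerance = 1e-9)
})

test_that("interpolation inverts the curve and reproduces the 5 pmol example", {
  # exact line through the standard areas: the area midway between the 2 uM
  # and 6 uM standards (2.5 and 7.5 pmol on column) back-calculates to 5 pmol
  pmol <- on_column_amounts(c(0.1, 0.2, 0.6, 2, 6, 20, 60, 200))
  cv <- fit_calibration(data.frame(pmol = pmol, area = 80 * pmol))
  mid <- mean(predict(cv, c(2.5, 7.5)))
  expect_equal(as.numeric(interpolate_amount(cv, mid)), 5, tolerance = 1e-9)
  # a standard's own area returns its own amount
  expect_equal(as.numeric(interpolate_amount(cv, predict(cv, 2.5))), 2.5,
               tolerance = 1e-9)
  # forward-model then invert is the identity
  expect_equal(as.numeric(interpolate_amount(cv, predict(cv, 42))), 42,
               tolerance = 1e-9)
  out <- interpolate_amount(cv, predict(cv, 400))
  expect_true(attr(out, "outside_linear_range"))
  expect_error(interpolate_amount(cv, -1), ">= 0")
})

test_that("LOQ interpolation handles exact, bracketed and degenerate series", {
  pm <- c(0.5, 1, 2, 4)
  expect_equal(loq_from_series(pm, c(5, 10, 20, 40))$loq_pmol, 1)
  expect_equal(loq_from_series(pm, c(5, 10, 20, 40))$flag, "exact")
  br <- loq_from_series(pm, c(4, 8, 16, 32))
  expect_equal(br$flag, "interpolated")
  # S/N proportional to amount: crossing at amount where s2n = 10
  expect_equal(br$loq_pmol, 10 / 8, tolerance = 1e-9)
  low <- loq_from_series(pm, c(1, 2, 4, 8))
  expect_equal(low$flag, "above_max")
  expect_equal(low$bound, 4)
  hi <- loq_from_series(pm, c(50, 100, 200, 400))
  expect_equal(hi$flag, "extrapolated")
  expect_equal(hi$loq_pmol, 0.1, tolerance = 1e-9)
})

test_that("empirical LOQ lands within 15% of the designed S/N=10 crossing", {
  loq_true <- ref_loq()
  for (met in c("NAD", "NMN")) {
    est <- measure_loq(met, sim_config(seed = 3L))
    expect_lt(abs(est$loq_pmol / loq_true[[met]] - 1), 0.15, label = met)
  }
  # the coarse 9-level curve gives the right order of magnitude only
  calib <- calib_default_noise()
  for (met in c("NAD", "NMN", "ATP")) {
    est <- calib$curves[[met]]$loq_pmol
    expect_lt(abs(log(est / loq_true[[met]])), log(1.5), label = met)
  }
})

test_that("default-noise curves reproduce the published linearity behaviour", {
  calib <- calib_default_noise()
  # low-LOQ analytes are linear across the whole series
  for (met in c("NAD", "ADPr", "NAAD", "Cytidine")) {
    expect_equal(calib$curves[[met]]$linear_range, c(0.125, 250),
                 info = met)
    expect_gt(calib$curves[[met]]$r_squared, 0.99)
  }
  # back-calculation recovers every nominal amount in range within 15%
  cv <- calib$curves$NAD
  back <- as.numeric(interpolate_amount(cv, cv$points$area))
  expect_lt(max(abs(back / cv$points$pmol - 1)), 0.15)
})

test_that("lot assignment recovers the designed heavy amounts", {
  calib <- calib_default_noise()
  lot <- calib$lot
  own <- lot[lot$via == "own", ]
  truth <- lot_pmol_on_column(PANEL, sim_config(seed = 7L))
  expect_lt(max(abs(own$assigned_pmol / truth[own$metabolite] - 1)), 0.03)
  expect_true(all(own$n == 9))
  # IMP's extract peak is too small: routed via NMN, no error
  expect_match(lot$via[lot$metabolite == "IMP"], "correction_factor:NMN")
  expect_match(lot$via[lot$metabolite == "NA"], "correction_factor:Nam")
  # identical replicate areas give zero CV
  asg <- calib$assigned
  idx <- asg$metabolite == "NAD" & asg$isotope == "heavy"
  asg$area[idx] <- mean(asg$area[idx])
  lot2 <- assign_lot(asg, calib$curves, PANEL)
  expect_equal(lot2$cv_pct[lot2$metabolite == "NAD"], 0)
})

test_that("correction factors equal designed response-factor ratios", {
  expect_equal(correction_factor(c(100, 200), c(1, 2), c(100, 200), c(1, 2)), 1)
  expect_equal(correction_factor(c(200, 400), c(1, 2), c(100, 200), c(1, 2)), 2)
  expect_error(correction_factor(1, 1, 0, 1), "zero")
  # simulator: cf(IMP via NMN) is the designed response ratio; NMN's light
  # response in standards is scaled by what on-source fragmentation leaves
  # behind (1 - its fragmentation fraction)
  calib <- calib_default_noise()
  rf <- default_response_factors()
  xt <- PANEL$crosstalk
  keep_nmn <- 1 - sum(xt$fraction[xt$source == "NMN" &
                                    xt$mechanism == "on_source_fragmentation"])
  expect_lt(abs(calib$cf$IMP / (rf[["IMP"]] / (keep_nmn * rf[["NMN"]])) - 1),
            0.02)
  expect_lt(abs(calib$cf$`NA` / (rf[["NA"]] / rf[["Nam"]]) - 1), 0.02)
})

test_that("assign_lot errors when an own-channel heavy peak is missing", {
  calib <- calib_default_noise()
  asg <- calib$assigned
  asg$found[asg$metabolite == "NAD" & asg$isotope == "heavy"] <- FALSE
  expect_error(assign_lot(asg, calib$curves, PANEL), "NAD")
})
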