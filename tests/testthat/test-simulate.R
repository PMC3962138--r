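test_that("noise-free channels carry exactly the designed signal", {
  cfg <- config_noise_free()
  # everything zero: flat zero traces
  inj <- simulate_injection(PANEL, cfg, c(NAD = 0),
                            heavy_pmol = c(NAD = 0), injection_id = "z")
  expect_true(all(vapply(inj$traces, function(tr) all(tr$intensity == 0),
                         TRUE)))
  # single analyte: integrated area = pmol x response factor (analytic)
  rf <- default_response_factors()
  inj <- simulate_injection(PANEL, cfg, c(NAD = 10),
                            heavy_pmol = c(NAD = 5))
  a_light <- detect_and_integrate(inj$traces[["NAD.light"]], noise = 1)$area
  expect_lt(abs(a_light / (10 * rf[["NAD"]]) - 1), 0.01)
  a_heavy <- detect_and_integrate(inj$traces[["NAD.heavy"]], noise = 1)$area
  expect_lt(abs(a_heavy / (5 * rf[["NAD"]]) - 1), 0.01)
  expect_error(simulate_injection(PANEL, cfg, c(bogus = 1)), "registry")
})

test_that("fragmentation moves signal to the source RT and conserves area", {
  cfg <- config_noise_free(
    crosstalk_fractions = c("NR>Nam" = 0.2, "NMN>Nam" = 0, "Nam>NA" = 0))
  rf <- default_response_factors()
  inj <- simulate_injection(PANEL, cfg, c(NR = 2), heavy_pmol = c(Nam = 0, NR = 0))
  nam <- detect_and_integrate(inj$traces[["Nam.light"]], noise = 1)
  expect_equal(nrow(nam), 1L)
  expect_lt(abs(nam$apex_rt - 8.98), 0.02)       # NR's RT, not Nam's
  expect_lt(abs(nam$area / (0.2 * 2 * rf[["NR"]]) - 1), 0.01)
  # source retains 1 - fraction
  nr <- detect_and_integrate(inj$traces[["NR.light"]], noise = 1)
  expect_lt(abs(nr$area / (0.8 * 2 * rf[["NR"]]) - 1), 0.01)
  # truth records the retained pre-noise area
  t_nr <- inj$truth[inj$truth$metabolite == "NR" & inj$truth$channel == "light", ]
  expect_equal(t_nr$pre_noise_area, 0.8 * 2 * rf[["NR"]])
})

test_that("bleed copies the source channel content, including fragments", {
  cfg <- config_noise_free(
    crosstalk_fractions = c("NR>Nam" = 0.2, "NMN>Nam" = 0,
                            "Nam>NA" = 0.1, "NAR>NA" = 0, "NAMN>NA" = 0))
  rf <- default_response_factors()
  inj <- simulate_injection(PANEL, cfg, c(NR = 2, Nam = 1),
                            heavy_pmol = c(Nam = 0, NR = 0))
  na_pk <- detect_and_integrate(inj$traces[["NA.light"]], noise = 1)
  expect_equal(nrow(na_pk), 2L)  # Nam's own peak bleed + NR-fragment bleed
  at_nam <- na_pk[which.min(abs(na_pk$apex_rt - 9.82)), ]
  at_nr <- na_pk[which.min(abs(na_pk$apex_rt - 8.98)), ]
  expect_lt(abs(at_nam$area / (0.1 * 1 * rf[["Nam"]]) - 1), 0.01)
  expect_lt(abs(at_nr$area / (0.1 * 0.2 * 2 * rf[["NR"]]) - 1), 0.01)
})

test_that("suppression multiplies light and heavy channels identically", {
  cfg <- config_noise_free()
  base <- simulate_injection(PANEL, cfg, c(NAD = 10), heavy_pmol = c(NAD = 5))
  supp <- simulate_injection(PANEL, cfg, c(NAD = 10), heavy_pmol = c(NAD = 5),
                             suppression = 0.4)
  ratio_l <- max(supp$traces[["NAD.light"]]$intensity) /
    max(base$traces[["NAD.light"]]$intensity)
  ratio_h <- max(supp$traces[["NAD.heavy"]]$intensity) /
    max(base$traces[["NAD.heavy"]]$intensity)
  expect_equal(ratio_l, 0.4, tolerance = 1e-12)
  expect_equal(ratio_h, ratio_l, tolerance = 1e-12)
})

test_that("the standard series has the designed structure", {
  cfg <- config_noise_free()
  std <- simulate_standard_series(PANEL, cfg)
  expect_length(std$injections, 9L)
  # zero level: no light signal, heavy lot still present
  tr0 <- std$injections[[1]]$truth
  expect_true(all(tr0$true_pmol[tr0$channel == "light"] == 0))
  expect_true(any(tr0$true_pmol[tr0$channel == "heavy"] > 0))
  # top level: 250 pmol on column in the truth record
  tr9 <- std$injections[[9]]$truth
  expect_equal(unique(tr9$true_pmol[tr9$channel == "light" &
                                      tr9$metabolite == "NAD"]), 250)
  # 18O spike: 1.5 uM in the 2.5 ul injection
  expect_equal(tr9$true_pmol[tr9$metabolite == "Nam" & tr9$channel == "heavy"],
               3.75)
})

test_that("simulation is deterministic in config + seed", {
  cfg <- sim_config(seed = 99L)
  a <- simulate_standard_series(PANEL, cfg)
  b <- simulate_standard_series(PANEL, cfg)
  expect_identical(a, b)
  c_ <- simulate_standard_series(PANEL, sim_config(seed = 100L))
  expect_false(identical(a$injections[[2]]$traces[["NAD.light"]]$intensity,
                         c_$injections[[2]]$traces[["NAD.light"]]$intensity))
})

test_that("experiments carry per-replicate truth and stable concentrations", {
  cfg <- sim_config(seed = 17L)
  prep <- demo_prep()
  smp <- simulate_experiment(PANEL, cfg, prep, replicates = 3L)
  expect_length(smp$injections, 3L)
  expect_setequal(unique(smp$truth$injection_id),
                  c("sample_01", "sample_02", "sample_03"))
  # seed change: different noise, same designed truth concentrations
  smp2 <- simulate_experiment(PANEL, sim_config(seed = 18L), prep)
  expect_identical(smp$truth_conc_uM, smp2$truth_conc_uM)
})

test_that("the area-level fast path agrees with trace integration", {
  cfg <- sim_config(seed = 23L)
  prep <- demo_prep()
  conc <- conc_at_loq_multiple(prep, 50)
  full <- simulate_experiment(PANEL, cfg, prep, conc, 1L, traces = TRUE)
  fast <- simulate_experiment(PANEL, cfg, prep, conc, 1L, traces = FALSE)
  pa <- process_injection(full$injections[[1]], PANEL)$assigned
  fa <- fast$injections[[1]]$areas
  m <- merge(pa[pa$found, c("channel_id", "area")],
             fa[fa$found, c("channel_id", "area")], by = "channel_id")
  expect_gt(nrow(m), 25)
  expect_lt(stats::median(abs(m$area.x / m$area.y - 1)), 0.02)
})
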