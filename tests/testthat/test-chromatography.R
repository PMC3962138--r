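gauss_trace <- function(rt, area, sigma = 0.05, lo = 0, hi = 4, dt = 0.005,
                        id = "x.light") {
  t <- seq(lo, hi, by = dt)
  y <- 0 * t
  for (i in seq_along(rt))
    y <- y + area[i] / (sigma * sqrt(2 * pi)) *
      exp(-(t - rt[i])^2 / (2 * sigma^2))
  transition_trace(id, t, y)
}

test_that("noise estimation is robust and honours exclusion windows", {
  t <- seq(0, 10, by = 0.01)
  flat <- transition_trace("x", t, rep(0, length(t)))
  expect_equal(estimate_noise(flat, floor = 2.5), 2.5)
  set.seed(11)
  for (sigma in c(5, 50)) {
    tr <- transition_trace("x", seq_len(1000) * 0.01, rnorm(1000, 0, sigma))
    expect_lt(abs(estimate_noise(tr) / sigma - 1), 0.15)
  }
  # a peak inflates the estimate unless excluded
  tr <- transition_trace("x", t, rnorm(length(t), 0, 5) +
                           1e4 * exp(-(t - 5)^2 / (2 * 0.05^2)))
  excl <- estimate_noise(tr, list(c(4.5, 5.5)))
  expect_lte(excl, estimate_noise(tr))
  expect_lt(abs(excl / 5 - 1), 0.2)
  expect_error(estimate_noise(tr, list(c(-1, 11))), "exclusion")
})

test_that("a noise-free Gaussian integrates to its analytic area", {
  A <- 1234; sigma <- 0.05
  pk <- detect_and_integrate(gauss_trace(2, A, sigma), noise = 1)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$area / A - 1), 0.01)
  expect_lt(abs(pk$apex_rt - 2), 0.01)
  expect_true(pk$left_bound < pk$apex_rt && pk$apex_rt < pk$right_bound)
  expect_equal(pk$s2n, pk$height / pk$noise)
})

test_that("two resolved Gaussians are found and match a quadrature oracle", {
  areas <- c(800, 300); rts <- c(1, 3); sigma <- 0.05
  tr <- gauss_trace(rts, areas, sigma)
  # independent oracle: fine-grid quadrature of each analytic component
  oracle <- vapply(seq_along(rts), function(i) {
    tt <- seq(rts[i] - 5 * sigma, rts[i] + 5 * sigma, length.out = 20001)
    yy <- areas[i] / (sigma * sqrt(2 * pi)) *
      exp(-(tt - rts[i])^2 / (2 * sigma^2))
    sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
  }, 0)
  pk <- detect_and_integrate(tr, noise = 1)
  expect_equal(nrow(pk), 2L)
  expect_lt(max(abs(pk$area / oracle - 1)), 0.01)
})

test_that("flat traces yield no peaks", {
  t <- seq(0, 2, by = 0.01)
  expect_equal(nrow(detect_and_integrate(
    transition_trace("x", t, rep(0, length(t))), noise = 1)), 0L)
})

test_that("areas are stable under time-grid refinement", {
  a1 <- detect_and_integrate(gauss_trace(2, 1000, dt = 0.01), noise = 1)$area
  a2 <- detect_and_integrate(gauss_trace(2, 1000, dt = 0.001), noise = 1)$area
  expect_lt(abs(a1 / a2 - 1), 0.005)
})

test_that("peak selection by RT window rejects crosstalk peaks", {
  # cytidine isotope-bleed peak at 11.14 min must not be picked for uridine
  tr <- gauss_trace(c(11.14, 11.5), c(5000, 800), lo = 10, hi = 13)
  pk <- detect_and_integrate(tr, noise = 1)
  sel <- select_peak(pk, expected_rt = 11.5, window = 0.3)
  expect_lt(abs(sel$apex_rt - 11.5), 0.02)
  # never returns a peak outside the window
  expect_null(select_peak(pk, expected_rt = 12.5, window = 0.3))
  expect_null(select_peak(pk[0, ], 11.5, 0.3))
  # equidistant tie goes to the larger area
  tie <- data.frame(apex_rt = c(10.8, 11.2), left_bound = c(10.7, 11.1),
                    right_bound = c(10.9, 11.3), area = c(10, 400),
                    height = c(5, 200), noise = 1, s2n = c(5, 200))
  expect_equal(select_peak(tie, 11.0, 0.3)$area, 400)
})

test_that("capacity factors reproduce the published retention table", {
  expect_equal(capacity_factor(1.4, 1.4), 0)
  expect_equal(capacity_factor(4.2, 1.4), 2)         # NAMN row
  t0 <- 4.2 / (1 + 2)                                 # void time from NAMN
  expect_equal(round(capacity_factor(13.64, t0), 1), 8.7)  # NAD+ row
  expect_error(capacity_factor(1.0, 1.4), "void")
  expect_error(capacity_factor(1, 0))
})

test_that("traces round-trip through per-injection CSV files", {
  f <- withr::local_tempfile(fileext = ".csv")
  trs <- list("a.light" = gauss_trace(1, 100, id = "a.light"),
              "b.heavy" = gauss_trace(2, 50, id = "b.heavy"))
  write_traces(trs, f)
  back <- read_traces(f)
  expect_setequal(names(back), names(trs))
  expect_equal(back[["a.light"]]$intensity, trs[["a.light"]]$intensity)
})

test_that("trace construction validates its inputs", {
  expect_error(transition_trace("x", 1:3, 1:2), "equal length")
  expect_error(transition_trace("x", 1, 1), "2 points")
  expect_error(transition_trace("x", c(1, 1, 2), c(0, 0, 0)), "increasing")
})
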