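test_that("FRET value is the FRET/EGFP ratio and guards the denominator", {
  expect_equal(fret_value(1000, 1000), 1.0)
  expect_equal(fret_value(1960, 1000), 1.96)
  expect_equal(fret_value(c(100, 300), c(200, 200)), c(0.5, 1.5))
  expect_error(fret_value(500, 0), "EGFP")
  expect_error(fret_value(500, -10), "EGFP")
})

test_that("ratio-to-occupancy subtracts the offset and flags the range", {
  th <- ratio_to_theta(c(1.46, 1.96, 2.46))
  expect_equal(as.vector(th), c(0, 0.5, 1.0), ignore_attr = TRUE)
  expect_equal(attr(th, "flagged"), c(TRUE, FALSE, TRUE))
  expect_true(is.na(ratio_to_theta(2.6)[1]))   # beyond the range entirely
  expect_equal(ratio_to_theta(2.6, mode = "clip"), 1 - 1e-6)
  expect_equal(ratio_to_theta(1.0, mode = "clip"), 1e-6)
})

test_that("occupancy-to-ATP inverts the Hill equation", {
  cal <- hill_calibration()
  expect_equal(theta_to_atp(0.5, cal), 0.84699)
  # theta = 0.9 -> K_A * 9^(1/n), evaluated directly as the oracle
  expect_equal(theta_to_atp(0.9, cal), 0.84699 * 9^(1 / 3.1234))
  expect_equal(round(theta_to_atp(0.9, cal), 2), 1.71)
  expect_lt(theta_to_atp(1e-12, cal), 1e-3)
  expect_error(theta_to_atp(0, cal), "undefined")
  expect_error(theta_to_atp(1.2, cal), "undefined")
  expect_true(is.na(theta_to_atp(NA_real_, cal)))
})

test_that("ATP-to-occupancy is the exact forward Hill curve", {
  cal <- hill_calibration()
  expect_equal(atp_to_theta(cal$K_A, cal), 0.5)
  expect_equal(atp_to_theta(0, cal), 0)
  expect_error(atp_to_theta(-1, cal), ">= 0")
})

test_that("occupancy/ATP conversions are mutual inverses on (0,1)", {
  cal <- hill_calibration()
  theta <- seq(0.01, 0.99, length.out = 41)
  expect_equal(atp_to_theta(theta_to_atp(theta, cal), cal), theta,
               tolerance = 1e-12)
  atp <- 10^seq(-2, 1.2, length.out = 41)
  expect_equal(theta_to_atp(atp_to_theta(atp, cal), cal), atp,
               tolerance = 1e-10)
})

test_that("the sensor ratio is strictly increasing in ATP", {
  cal <- hill_calibration()
  r <- fret_ratio_from_atp(seq(0.01, 10, length.out = 200), cal)
  expect_true(all(diff(r) > 0))
})

test_that("the log-linearized regression recovers generating parameters", {
  # noiseless forward-model data, reported sensor parameters
  tit <- gen_calibration_titration(hill_calibration())
  cal <- fit_hill(tit)
  expect_equal(cal$n, 3.1234, tolerance = 1e-8)
  expect_equal(cal$K_A, 0.84699, tolerance = 1e-8)
  expect_equal(cal$diagnostics$points_used, 12L)
  # a 1:1 binding curve yields n = 1
  tit1 <- gen_calibration_titration(hill_calibration(n = 1, K_A = 0.5))
  expect_equal(fit_hill(tit1)$n, 1, tolerance = 1e-8)
})

test_that("saturated titration points are excluded and counted", {
  tit <- gen_calibration_titration(concentrations = c(0.2, 0.5, 1, 2, 5))
  tit <- rbind(tit, data.frame(atp_mM = c(100, 1e-5),
                               fret_ratio = c(2.47, 1.45)))
  cal <- fit_hill(tit)
  expect_equal(cal$diagnostics$points_excluded, 2L)
  expect_equal(cal$n, 3.1234, tolerance = 1e-6)
  expect_error(fit_hill(data.frame(atp_mM = c(1, 2), fret_ratio = c(1.8, 1.9))),
               "insufficient")
})

test_that("the fit is unbiased under measurement noise", {
  # Monte-Carlo oracle on a titration inside the sensor's dynamic range
  # (occupancy 0.02-0.98): the mean of many noisy refits stays within 2% of
  # truth. Ladders reaching deep saturation instead incur a selection bias
  # from the occupancy-range exclusion rule (see the methods vignette).
  conc <- 10^seq(log10(0.25), log10(2.6), length.out = 12)
  est <- vapply(1:400, function(i) {
    tit <- gen_calibration_titration(concentrations = conc,
                                     noise_sd = 0.01, seed = 1000 + i)
    cal <- fit_hill(tit)
    c(cal$n, cal$K_A)
  }, c(0, 0))
  expect_equal(mean(est[1, ]), 3.1234, tolerance = 0.02)
  expect_equal(mean(est[2, ]), 0.84699, tolerance = 0.02)
})

test_that("calibrations round-trip through JSON", {
  tmp <- tempfile(fileext = ".json")
  cal <- fit_hill(gen_calibration_titration())
  write_calibration(cal, tmp)
  cal2 <- read_calibration(tmp)
  expect_equal(cal2$n, cal$n)
  expect_equal(cal2$K_A, cal$K_A)
  expect_equal(cal2$diagnostics$points_used, cal$diagnostics$points_used)
})
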