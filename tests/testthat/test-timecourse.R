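make_stream <- function(df, window = NULL) {
  attr(df, "acquisition_window") <- window %||% range(df$time_s)
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gating retains the top-MFI events above the floor", {
  # 10 listed events; brute-force filter as the oracle
  ev <- make_stream(data.frame(
    time_s = 1:10,
    egfp = c(500, 1200, 1500, 2000, 2500, 3000, 900, 4000, 1100, 5000),
    fret = c(600, 1300, 1400, 2600, 2200, 3100, 950, 3900, 1050, 4800)),
    c(0, 10))
  g <- gate_events(ev, mfi_floor = 1000, top_fraction = 0.5)
  keep <- ev$egfp > 1000 & ev$fret > 1000
  qe <- quantile(ev$egfp[keep], 0.5, names = FALSE)
  qf <- quantile(ev$fret[keep], 0.5, names = FALSE)
  oracle <- ev[keep & ev$egfp >= qe & ev$fret >= qf, ]
  expect_equal(g$time_s, oracle$time_s)
})

test_that("top_fraction = 1 reduces the gate to the MFI floor", {
  ev <- make_stream(data.frame(time_s = 1:6,
                               egfp = c(500, 1500, 2000, 800, 3000, 1200),
                               fret = c(700, 1400, 2100, 900, 2900, 1300)))
  g <- gate_events(ev, top_fraction = 1)
  expect_equal(g$time_s, c(2, 3, 5, 6))
})

test_that("an all-dim stream gates to empty with a warning", {
  ev <- make_stream(data.frame(time_s = 1:5, egfp = rep(500, 5),
                               fret = rep(400, 5)))
  expect_warning(g <- gate_events(ev), "empty gate")
  expect_equal(nrow(g), 0L)
})

test_that("gating is idempotent for identical parameters", {
  scn <- scenario_spec("quiescent", seed = 5)
  ev <- gen_event_stream(scn, 2000, 300)
  g1 <- gate_events(ev, 1000, 0.45)
  g2 <- gate_events(g1, 1000, 0.45)
  expect_identical(g1, g2)
})

test_that("the smoother reproduces constants and straight lines", {
  set.seed(1)
  t <- sort(runif(200, 0, 100))
  const <- make_stream(data.frame(time_s = t, egfp = 2000,
                                  fret = 2000 * 1.9), c(0, 100))
  tr <- smooth_ratio_trace(const)
  expect_equal(tr$ratio, rep(1.9, nrow(tr)), tolerance = 1e-8)
  lin <- make_stream(data.frame(time_s = t, egfp = 2000,
                                fret = 2000 * (1.5 + 0.004 * t)), c(0, 100))
  tr2 <- smooth_ratio_trace(lin)
  expect_equal(tr2$ratio, 1.5 + 0.004 * tr2$time_s, tolerance = 1e-6)
})

test_that("the smoother is translation-equivariant in the ratio", {
  scn <- scenario_spec("quiescent", seed = 9)
  ev <- gate_events(gen_event_stream(scn, 3000, 300))
  tr <- smooth_ratio_trace(ev)
  shifted <- ev
  shifted$fret <- shifted$fret + 0.25 * shifted$egfp   # ratio + 0.25
  tr2 <- smooth_ratio_trace(shifted)
  expect_equal(tr2$ratio, tr$ratio + 0.25, tolerance = 1e-6)
})

test_that("too few events is an error", {
  ev <- make_stream(data.frame(time_s = 1:10, egfp = 2000, fret = 3800))
  expect_error(smooth_ratio_trace(ev), "insufficient")
})

test_that("ratio curves convert pointwise to ATP", {
  grid <- 0:100
  flat <- make_stream(data.frame(time_s = grid, ratio = 1.96), c(0, 100))
  atp <- trace_to_atp(flat)
  expect_equal(atp$atp_mM, rep(0.84699, 101), tolerance = 1e-9)
  # a curve at the offset converts to the clip floor, essentially 0 mM
  base <- make_stream(data.frame(time_s = grid, ratio = 1.46), c(0, 100))
  expect_lt(max(trace_to_atp(base)$atp_mM), 0.02)
  # monotone ratio -> monotone ATP
  mono <- make_stream(data.frame(time_s = grid,
                                 ratio = seq(2.2, 1.6, length.out = 101)),
                      c(0, 100))
  expect_true(all(diff(trace_to_atp(mono)$atp_mM) < 0))
})

test_that("baseline correction anchors the control to the treated baseline", {
  grid <- 0:60
  mk <- function(x) {
    d <- data.frame(time_s = grid, atp_mM = x)
    attr(d, "correction_factor") <- 1
    d
  }
  ctl <- mk(1.0 - 0.002 * grid)
  trt <- mk(0.5 - 0.003 * grid)
  corr <- baseline_correct(ctl, trt)
  expect_equal(attr(corr, "correction_factor"), 0.5)
  expect_equal(corr$atp_mM, ctl$atp_mM * 0.5)
  expect_identical(corr$atp_mM[1], trt$atp_mM[1])
  same <- baseline_correct(ctl, ctl)
  expect_equal(attr(same, "correction_factor"), 1)
  expect_equal(same$atp_mM, ctl$atp_mM)
  expect_error(baseline_correct(mk(c(0, rep(1, 60))), trt), "undefined")
})

test_that("window means match closed forms and brute-force averages", {
  grid <- seq(0, 100, by = 1)
  const <- data.frame(time_s = grid, atp_mM = 0.7)
  expect_equal(window_mean(const, 10, 40), 0.7)
  lin <- data.frame(time_s = grid, atp_mM = 0.2 + 0.01 * grid)
  # linear a + bt over [T - d, T]: mean = a + b (T - d/2)
  expect_equal(window_mean(lin, 90, 100), 0.2 + 0.01 * 95)
  set.seed(4)
  arb <- data.frame(time_s = grid, atp_mM = runif(101))
  expect_equal(window_mean(arb, 0, 100), mean(arb$atp_mM))
  expect_error(window_mean(arb, 200, 300), "empty window")
})

test_that("the density grid covers the event cloud", {
  scn <- scenario_spec("quiescent", seed = 21)
  ev <- gate_events(gen_event_stream(scn, 2000, 300))
  dg <- density_grid(ev, n = 32)
  expect_equal(dim(dg$z), c(32L, 32L))
  expect_true(all(dg$z >= 0))
})
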