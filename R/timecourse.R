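# From gated event streams to smoothed, baseline-corrected ATP traces.

stream_window <- function(stream, default = NULL) {
  w <- attr(stream, "acquisition_window")
  if (is.null(w)) w <- default %||% range(stream$time_s)
  w
}

#' Read / write an event stream as CSV
#'
#' Event CSVs carry one row per cell event with columns `time_s`, `egfp`,
#' `fret`.
#'
#' @param path CSV path.
#' @param window Optional acquisition window `c(t0, t1)`; defaults to the
#'   observed time range.
#' @return `read_event_stream` returns the event data frame.
#' @export
read_event_stream <- function(path, window = NULL) {
  x <- utils::read.csv(path)
  need <- c("time_s", "egfp", "fret")
  if (!all(need %in% names(x)))
    stopf("event CSV must have columns %s", paste(need, collapse = ", "))
  if (any(x$egfp < 0) || any(x$fret < 0))
    stopf("negative fluorescence intensities in event stream")
  attr(x, "acquisition_window") <- window %||% range(x$time_s)
  attr(x, "gate_label") <- "ungated"
  x
}

#' @rdname read_event_stream
#' @param stream Event data frame.
#' @export
write_event_stream <- function(stream, path) {
  utils::write.csv(stream[, c("time_s", "egfp", "fret")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Gate events on intensity floor and top-MFI fraction
#'
#' Keeps events whose EGFP and FRET intensities both exceed the MFI floor
#' and both lie in the top `top_fraction` of their channel's post-floor
#' distribution (linear-interpolation quantiles, channel-wise). This removes
#' autofluorescence-dominated events before ratio analysis. The gate
#' parameters are recorded on the returned stream; re-applying the same gate
#' to an already-gated stream is a no-op.
#'
#' @param stream Event data frame (`time_s`, `egfp`, `fret`).
#' @param mfi_floor Intensity floor applied to both channels (default 1000).
#' @param top_fraction Fraction of the post-floor distribution retained,
#'   in (0, 1\]; the study design uses the top 40-50 percent (default 0.45).
#' @return The gated stream (possibly empty, with a warning).
#' @export
gate_events <- function(stream, mfi_floor = 1000, top_fraction = 0.45) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stopf("'top_fraction' must lie in (0, 1]")
  params <- list(mfi_floor = mfi_floor, top_fraction = top_fraction)
  if (identical(attr(stream, "gate_params"), params)) return(stream)
  keep <- stream$egfp > mfi_floor & stream$fret > mfi_floor
  sub <- stream[keep, , drop = FALSE]
  if (nrow(sub) > 0L && top_fraction < 1) {
    qe <- stats::quantile(sub$egfp, 1 - top_fraction, names = FALSE)
    qf <- stats::quantile(sub$fret, 1 - top_fraction, names = FALSE)
    sub <- sub[sub$egfp >= qe & sub$fret >= qf, , drop = FALSE]
  }
  if (nrow(sub) == 0L)
    warning("empty gate: no events above the MFI floor / quantile cut")
  attr(sub, "acquisition_window") <- stream_window(stream)
  attr(sub, "gate_label") <- sprintf("MFI>%g & top %g%%", mfi_floor,
                                     100 * top_fraction)
  attr(sub, "gate_params") <- params
  sub
}

#' Smooth the per-event FRET/EGFP ratio against time
#'
#' Fits a generalized additive model `ratio ~ s(time)` (penalized regression
#' spline, smoothness chosen automatically by the default GCV criterion of
#' [mgcv::gam()]) to the gated events, and evaluates the fit on a uniform
#' time grid over the acquisition window.
#'
#' @param stream Gated event data frame (needs >= 20 events).
#' @param grid_dt Grid resolution in seconds (default 1).
#' @return Data frame `time_s`, `ratio` with attribute `smoother_meta`
#'   (basis and effective degrees of freedom) and the acquisition window.
#' @export
smooth_ratio_trace <- function(stream, grid_dt = 1) {
  if (nrow(stream) < 20L)
    stopf("insufficient data: need >= 20 gated events, got %d", nrow(stream))
  d <- data.frame(time_s = stream$time_s,
                  ratio = fret_value(stream$fret, stream$egfp))
  fit <- mgcv::gam(ratio ~ s(time_s), data = d)
  w <- stream_window(stream)
  grid <- seq(w[1L], w[2L], by = grid_dt)
  out <- data.frame(time_s = grid,
                    ratio = as.vector(stats::predict(fit,
                      newdata = data.frame(time_s = grid))))
  attr(out, "acquisition_window") <- w
  attr(out, "smoother_meta") <- list(basis = "thin-plate regression spline",
                                     effective_df = sum(fit$edf))
  out
}

#' Convert a fitted ratio curve to an ATP trace
#'
#' Applies [ratio_to_theta()] (clip mode, since a fitted curve may brush the
#' sensor's range limits) and [theta_to_atp()] pointwise on the grid.
#'
#' @param curve Output of [smooth_ratio_trace()].
#' @param calib A [hill_calibration()].
#' @return Data frame `time_s`, `atp_mM` with `correction_factor` attribute
#'   (1 until baseline correction) and the smoother metadata.
#' @export
trace_to_atp <- function(curve, calib = hill_calibration()) {
  theta <- ratio_to_theta(curve$ratio, calib, mode = "clip")
  out <- data.frame(time_s = curve$time_s,
                    atp_mM = theta_to_atp(theta, calib))
  attr(out, "acquisition_window") <- stream_window(curve)
  attr(out, "smoother_meta") <- attr(curve, "smoother_meta")
  attr(out, "correction_factor") <- 1
  out
}

trace_at_zero <- function(trace) {
  trace$atp_mM[which.min(abs(trace$time_s))]
}

#' Baseline-correct a control ATP trace against a treated trace
#'
#' Multiplies the whole control trace by
#' `treated(0) / control(0)` (fitted values at the grid point nearest 0 s),
#' so both arms share the same baseline; the factor is recorded in the
#' `correction_factor` attribute. The treated trace is not modified.
#'
#' @param control,treated ATP traces from [trace_to_atp()].
#' @return The corrected control trace.
#' @export
baseline_correct <- function(control, treated) {
  c0 <- trace_at_zero(control)
  t0 <- trace_at_zero(treated)
  if (!is.finite(c0) || c0 == 0)
    stopf("undefined correction: control trace is 0 at t = 0")
  factor <- t0 / c0
  out <- control
  out$atp_mM <- control$atp_mM * factor
  attr(out, "correction_factor") <- factor
  out
}

#' Mean ATP concentration over a time window
#'
#' Mean of the trace's grid values inside the closed window
#' `[t_start, t_end]` (e.g. the last 1-2 minutes of an acquisition).
#'
#' @param trace ATP trace.
#' @param t_start,t_end Window bounds in seconds.
#' @return Mean ATP in mM.
#' @export
window_mean <- function(trace, t_start, t_end) {
  sel <- trace$time_s >= t_start & trace$time_s <= t_end
  if (!any(sel)) stopf("empty window: no grid points in [%g, %g]",
                       t_start, t_end)
  mean(trace$atp_mM[sel])
}

#' 2-D kernel density grid of an event stream
#'
#' Density of (time, FRET/EGFP ratio) on a regular grid — the plain-data
#' equivalent of the pseudocolor plots used to display event clouds.
#' Bandwidths follow the normal reference rule.
#'
#' @param stream Event data frame.
#' @param n Grid points per axis.
#' @return List with vectors `x` (time), `y` (ratio) and matrix `z`.
#' @export
density_grid <- function(stream, n = 64) {
  MASS::kde2d(stream$time_s, fret_value(stream$fret, stream$egfp), n = n)
}
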