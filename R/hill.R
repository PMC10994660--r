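#' Hill calibration of a ratiometric FRET ATP biosensor
#'
#' The GO-ATeam2-type sensor reports ATP through the ratio of FRET to EGFP
#' fluorescence. Sensor occupancy follows the Hill equation
#' \deqn{\theta = [L]^n / (K_A^n + [L]^n)}
#' where \eqn{[L]} is the ATP concentration (mM), \eqn{K_A} the
#' half-saturation concentration and \eqn{n} the Hill coefficient, and the
#' measured ratio is \eqn{\theta} plus a fixed instrument offset. The offset
#' is treated as an instrument constant (default 1.46) and is not refit.
#'
#' @param n Hill coefficient (> 0). Default is the reported sensor value.
#' @param K_A Half-saturation ATP concentration in mM (> 0).
#' @param offset FRET-ratio offset added to the occupancy (default 1.46).
#' @param diagnostics Optional list of fit diagnostics (`r_squared`,
#'   `points_used`, `points_excluded`).
#' @return An object of class `hill_calibration`.
#' @examples
#' cal <- hill_calibration()
#' theta_to_atp(0.5, cal)  # half-saturation: returns K_A
#' @export
hill_calibration <- function(n = 3.1234, K_A = 0.84699, offset = 1.46,
                             diagnostics = NULL) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stopf("Hill coefficient 'n' must be a single positive number")
  if (!is.numeric(K_A) || length(K_A) != 1L || !is.finite(K_A) || K_A <= 0)
    stopf("'K_A' must be a single positive number (mM)")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    stopf("'offset' must be a single finite number")
  structure(list(n = n, K_A = K_A, offset = offset,
                 diagnostics = diagnostics),
            class = "hill_calibration")
}

#' @export
print.hill_calibration <- function(x, ...) {
  cat("Hill calibration: n =", format(x$n), ", K_A =", format(x$K_A),
      "mM, offset =", format(x$offset), "\n")
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("  fit: R^2 = %.6f, %d points used, %d excluded\n",
                d$r_squared, d$points_used, d$points_excluded))
  }
  invisible(x)
}

#' FRET value of an event
#'
#' Ratio of FRET to EGFP fluorescence intensities of a single event.
#'
#' @param fret_fluor FRET-channel intensity (vectorized).
#' @param egfp_fluor EGFP-channel intensity; must be strictly positive.
#' @return `fret_fluor / egfp_fluor`.
#' @export
fret_value <- function(fret_fluor, egfp_fluor) {
  if (any(!is.finite(egfp_fluor)) || any(egfp_fluor <= 0))
    stopf("invalid event: EGFP fluorescence must be > 0")
  fret_fluor / egfp_fluor
}

#' Sensor occupancy from a FRET ratio
#'
#' Subtracts the calibration offset from the ratio. Occupancies outside the
#' open interval (0, 1) are outside the sensor's dynamic range: in `"flag"`
#' mode, boundary values are kept and marked in the `"flagged"` attribute and
#' values beyond \[0, 1\] become `NA`; in `"clip"` mode, values are clipped to
#' \[1e-6, 1 - 1e-6\] (noisy single events routinely exceed the range, so the
#' clipped conversion is what the time-course pipeline uses).
#'
#' @param ratio FRET/EGFP ratio (vectorized).
#' @param calib A [hill_calibration()].
#' @param mode `"flag"` (default) or `"clip"`.
#' @return Numeric occupancy vector; in flag mode it carries a logical
#'   `"flagged"` attribute marking out-of-range inputs.
#' @export
ratio_to_theta <- function(ratio, calib = hill_calibration(),
                           mode = c("flag", "clip")) {
  mode <- match.arg(mode)
  theta <- ratio - calib$offset
  if (mode == "clip") return(pmin(pmax(theta, 1e-6), 1 - 1e-6))
  flagged <- !is.na(theta) & (theta <= 0 | theta >= 1)
  theta[!is.na(theta) & (theta < 0 | theta > 1)] <- NA_real_
  attr(theta, "flagged") <- flagged
  theta
}

#' ATP concentration from sensor occupancy
#'
#' Inverts the Hill equation: \eqn{[L] = K_A (\theta/(1-\theta))^{1/n}}.
#' Occupancy must lie strictly inside (0, 1); `NA`s propagate.
#'
#' @param theta Occupancy in (0, 1).
#' @param calib A [hill_calibration()].
#' @return ATP concentration in mM.
#' @export
theta_to_atp <- function(theta, calib = hill_calibration()) {
  bad <- !is.na(theta) & (theta <= 0 | theta >= 1)
  if (any(bad))
    stopf("undefined concentration: occupancy must lie strictly in (0, 1)")
  calib$K_A * (theta / (1 - theta))^(1 / calib$n)
}

#' Sensor occupancy at a given ATP concentration
#'
#' Forward Hill equation; exact inverse of [theta_to_atp()] on (0, 1).
#'
#' @param atp ATP concentration in mM (>= 0).
#' @param calib A [hill_calibration()].
#' @return Occupancy in \[0, 1).
#' @export
atp_to_theta <- function(atp, calib = hill_calibration()) {
  if (any(!is.finite(atp)) || any(atp < 0))
    stopf("ATP concentration must be finite and >= 0")
  atp^calib$n / (calib$K_A^calib$n + atp^calib$n)
}

#' Forward sensor model: FRET ratio at a given ATP concentration
#'
#' @param atp ATP concentration in mM (>= 0).
#' @param calib A [hill_calibration()].
#' @return FRET/EGFP ratio `offset + theta(atp)`.
#' @export
fret_ratio_from_atp <- function(atp, calib = hill_calibration()) {
  calib$offset + atp_to_theta(atp, calib)
}

#' Fit the Hill calibration from a titration
#'
#' Log-linearizes the Hill equation,
#' \deqn{\log(\theta/(1-\theta)) = n \log[L] - n \log K_A,}
#' and fits it by ordinary least squares (natural logarithms; the slope and
#' therefore `n` are base-invariant). The occupancy is the measured ratio
#' minus the fixed offset; points whose occupancy falls outside (0, 1) —
#' saturated or sub-baseline readings — are excluded and counted in the
#' diagnostics.
#'
#' @param titration Data frame whose first two columns are ATP concentration
#'   (mM) and FRET ratio (columns `atp_mM` and `fret_ratio` if named).
#' @param offset Instrument ratio offset (default 1.46); subtracted, not
#'   refit.
#' @return A [hill_calibration()] with fitted `n` and `K_A` and diagnostics.
#' @export
fit_hill <- function(titration, offset = 1.46) {
  if (!is.data.frame(titration) || ncol(titration) < 2L)
    stopf("'titration' must be a data frame with ATP and FRET-ratio columns")
  atp <- if ("atp_mM" %in% names(titration)) titration$atp_mM else titration[[1L]]
  ratio <- if ("fret_ratio" %in% names(titration)) titration$fret_ratio else titration[[2L]]
  theta <- ratio - offset
  usable <- is.finite(atp) & atp > 0 & is.finite(theta) & theta > 0 & theta < 1
  if (sum(usable) < 3L)
    stopf("insufficient data: need >= 3 titration points with occupancy in (0, 1), got %d",
          sum(usable))
  y <- log(theta[usable] / (1 - theta[usable]))
  x <- log(atp[usable])
  fit <- stats::lm(y ~ x)
  n <- unname(stats::coef(fit)[2L])
  if (!is.finite(n) || n <= 0)
    stopf("Hill regression produced a non-positive slope (n = %g)", n)
  K_A <- exp(-unname(stats::coef(fit)[1L]) / n)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  hill_calibration(n = n, K_A = K_A, offset = offset,
                   diagnostics = list(r_squared = r2,
                                      points_used = sum(usable),
                                      points_excluded = sum(!usable)))
}

#' Write / read a Hill calibration as JSON
#'
#' @param calib A [hill_calibration()].
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a [hill_calibration()].
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(list(n = calib$n, K_A = calib$K_A,
                            offset = calib$offset,
                            diagnostics = calib$diagnostics),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hill_calibration(n = x$n, K_A = x$K_A, offset = x$offset,
                   diagnostics = x$diagnostics)
}
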