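# Amplifier frequency-response calibration. EEG amplifiers attenuate slow
# and fast sinusoids differently; feeding known analog sinusoids through each
# device and comparing recorded to generated amplitude yields an empirical
# gain ("amplitude reduction rate") per frequency, interpolated by a cubic
# spline and applied to power spectra as 1/rate(f)^2.

#' Calibration frequency grid
#'
#' The sweep protocol probes 0.05 Hz, every 0.1 Hz from 0.1-2 Hz, every 1 Hz
#' from 2-20 Hz and every 10 Hz from 10-100 Hz (the last two segments
#' overlap; the union is used).
#'
#' @return Sorted numeric vector of sweep frequencies in Hz.
#' @export
calibration_grid <- function() {
  sort(unique(c(0.05, seq(0.1, 2, by = 0.1), 2:20, seq(10, 100, by = 10))))
}

#' Generated sinusoid amplitudes used in the sweep protocol
#' @return Numeric vector, microvolts.
#' @export
calibration_amplitudes <- function() c(40, 355)

#' Estimate the amplitude of a sinusoidal component
#'
#' Least-squares fit of `a*cos + b*sin` (plus an intercept) at a known
#' frequency; the fitted peak amplitude is `sqrt(a^2 + b^2)`. A least-squares
#' fit is used rather than an FFT peak read so that calibration frequencies
#' falling between FFT bins are estimated without leakage bias.
#'
#' @param signal Numeric sample vector.
#' @param fs Sampling rate, Hz.
#' @param frequency Target frequency, Hz.
#' @return Estimated peak amplitude, in the units of `signal`.
#' @export
measure_amplitude <- function(signal, fs, frequency) {
  assert_that(frequency > 0 && frequency < fs / 2,
              "frequency must lie in (0, fs/2)")
  dur <- length(signal) / fs
  need <- max(10 / frequency, if (frequency < 2.5) 4 else 0)
  assert_that(dur >= need - 1e-9,
              sprintf("signal too short: %.2f s given, %.2f s required at %g Hz",
                      dur, need, frequency),
              class = "sleepspectra_precondition_error")
  t <- (seq_along(signal) - 1) / fs
  X <- cbind(1, cos(2 * pi * frequency * t), sin(2 * pi * frequency * t))
  beta <- unname(lm.fit(X, signal)$coefficients)
  sqrt(beta[2]^2 + beta[3]^2)
}

#' Build a calibration sweep record
#'
#' @param device_id Device identifier.
#' @param entries Tibble with columns `frequency_hz`, `generated_uv`
#'   (generated analog amplitude, microvolts), `fs`, and a list-column
#'   `signal` of recorded sample vectors.
#' @return A `calibration_sweep` object.
#' @export
new_calibration_sweep <- function(device_id, entries) {
  need <- c("frequency_hz", "generated_uv", "fs", "signal")
  assert_that(all(need %in% names(entries)),
              sprintf("sweep entries need columns: %s", paste(need, collapse = ", ")))
  assert_that(all(entries$generated_uv > 0), "generated amplitudes must be positive")
  structure(list(device_id = device_id, entries = tibble::as_tibble(entries)),
            class = "calibration_sweep")
}

#' Estimate per-frequency amplitude reduction rates from a sweep
#'
#' For each probed frequency the rate is the measured/generated amplitude
#' ratio, averaged over the amplitude runs (40 and 355 microvolts in the
#' standard protocol). A single run per frequency is accepted with a warning.
#'
#' @param sweep A [new_calibration_sweep()] object.
#' @return Tibble with columns `frequency_hz` and `rate`.
#' @export
estimate_reduction_rate <- function(sweep) {
  stopifnot(inherits(sweep, "calibration_sweep"))
  e <- sweep$entries
  e$run_rate <- purrr::pmap_dbl(
    list(e$signal, e$fs, e$frequency_hz, e$generated_uv),
    function(sig, fs, f, amp) measure_amplitude(sig, fs, f) / amp
  )
  n_runs <- table(e$frequency_hz)
  if (any(n_runs < 2)) {
    warn(sprintf("single amplitude run at %d frequenc(ies); rates not averaged",
                 sum(n_runs < 2)))
  }
  rates <- dplyr::summarise(dplyr::group_by(e, .data$frequency_hz),
                            rate = mean(.data$run_rate), .groups = "drop")
  bad <- rates$frequency_hz[rates$rate <= 0 | rates$rate > 2]
  assert_that(length(bad) == 0,
              sprintf("implausible reduction rate (<=0 or >2) at %s Hz",
                      paste(bad, collapse = ", ")),
              class = "sleepspectra_validation_error")
  rates
}

#' Build a calibration curve by spline interpolation
#'
#' Natural cubic spline through the measured (frequency, rate) points; exact
#' at the measured grid, smooth in between. The curve must stay positive on
#' the 1-40 Hz analysis range.
#'
#' @param rates Tibble with columns `frequency_hz` and `rate` (e.g. from
#'   [estimate_reduction_rate()]).
#' @param device_id Device identifier attached to the curve.
#' @return A `calibration_curve` object: callable via [rate_at()].
#' @export
build_curve <- function(rates, device_id = "unknown") {
  assert_that(all(c("frequency_hz", "rate") %in% names(rates)),
              "`rates` needs columns frequency_hz and rate")
  assert_that(nrow(rates) >= 2, "at least two grid points are required",
              class = "sleepspectra_validation_error")
  assert_that(!is.unsorted(rates$frequency_hz, strictly = TRUE),
              "frequency grid must be strictly increasing",
              class = "sleepspectra_validation_error")
  f <- splinefun(rates$frequency_hz, rates$rate, method = "natural")
  probe <- freq_bins()
  assert_that(all(f(probe) > 0),
              "interpolated rate is non-positive somewhere on 1-40 Hz",
              class = "sleepspectra_validation_error")
  structure(list(device_id = device_id,
                 grid = tibble::as_tibble(rates),
                 interpolator = f),
            class = "calibration_curve")
}

#' Evaluate a calibration curve
#'
#' @param curve A `calibration_curve`.
#' @param frequency_hz Frequencies at which to evaluate the rate.
#' @return Numeric vector of amplitude reduction rates.
#' @export
rate_at <- function(curve, frequency_hz) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$interpolator(frequency_hz)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> device %s: %d grid points (%g-%g Hz)\n",
              x$device_id, nrow(x$grid), min(x$grid$frequency_hz),
              max(x$grid$frequency_hz)))
  invisible(x)
}

#' Correct a power spectrum for device frequency response
#'
#' Divides each PSD bin by the squared amplitude reduction rate at that
#' frequency (power scales with amplitude squared).
#'
#' @param psd Data frame with columns `bin_hz` and `psd` (plus any others,
#'   preserved), or a bare numeric vector aligned with [freq_bins()].
#' @param curve A `calibration_curve`.
#' @return Same shape as `psd` with corrected power.
#' @export
correct_psd <- function(psd, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.numeric(psd) && is.null(dim(psd))) {
    assert_that(length(psd) == length(freq_bins()),
                "vector psd must be on the 157-bin grid")
    return(psd / rate_at(curve, freq_bins())^2)
  }
  assert_that(all(c("bin_hz", "psd") %in% names(psd)),
              "`psd` needs columns bin_hz and psd")
  psd$psd <- psd$psd / rate_at(curve, psd$bin_hz)^2
  psd
}

#' Apply a device frequency response to a power spectrum
#'
#' The analytic forward model inverted by [correct_psd()]: multiplies power
#' by the squared reduction rate. Useful for simulation and round-trip tests.
#'
#' @inheritParams correct_psd
#' @return Same shape as `psd` with the response applied.
#' @export
apply_response <- function(psd, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.numeric(psd) && is.null(dim(psd))) {
    return(psd * rate_at(curve, freq_bins())^2)
  }
  psd$psd <- psd$psd * rate_at(curve, psd$bin_hz)^2
  psd
}

#' Read / write calibration curve files
#'
#' On-disk dialect: CSV with columns `device_id`, `frequency_hz`, `rate`.
#' `read_curves()` returns a named list of `calibration_curve` objects, one
#' per device.
#'
#' @param curves A named list of `calibration_curve` objects.
#' @param path CSV path.
#' @return `read_curves()`: named list of curves; `write_curves()`: `path`.
#' @export
write_curves <- function(curves, path) {
  tbl <- purrr::map_dfr(curves, function(cv) {
    dplyr::mutate(cv$grid, device_id = cv$device_id, .before = 1)
  })
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           device_id = readr::col_character(),
                           frequency_hz = readr::col_double(),
                           rate = readr::col_double()
                         ))
  split(tbl, tbl$device_id) |>
    purrr::imap(function(g, dev) build_curve(g[c("frequency_hz", "rate")], dev))
}
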