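# State-specific spectral estimation: 4 s Hann-tapered windows with 2 s
# overlap averaged over all artifact-free windows of the requested sleep
# state, expressed as relative log10 power on the 1-40 Hz grid.

#' Plan artifact-free analysis windows
#'
#' Selects the maximal set of 4 s analysis windows at 2 s steps lying wholly
#' inside maximal runs of contiguous artifact-free 4 s segments of epochs of
#' the requested state. `NREM` pools NREM2 and SWS epochs; windows never span
#' a stage change, an epoch boundary or an artifacted segment.
#'
#' @param hypnogram Tibble from [read_hypnogram()].
#' @param mask Tibble from [read_artifact_mask()]; five 4 s segments per
#'   epoch. A mask shorter than the hypnogram is an error.
#' @param state `"NREM"` or `"REM"`.
#' @return Tibble with one row per window: `epoch`, `start_s` (offset from
#'   recording start, seconds). Zero rows when no eligible window exists.
#' @export
plan_windows <- function(hypnogram, mask, state = c("NREM", "REM")) {
  state <- match.arg(state)
  wanted <- states_for(state)
  n_seg_needed <- nrow(hypnogram) * SEGMENTS_PER_EPOCH
  assert_that(nrow(mask) >= n_seg_needed,
              sprintf("mask has %d segments; %d needed to cover the hypnogram",
                      nrow(mask), n_seg_needed),
              class = "sleepspectra_validation_error")

  out <- vector("list", nrow(hypnogram))
  for (i in seq_len(nrow(hypnogram))) {
    if (!(hypnogram$stage[i] %in% wanted)) next
    seg_idx <- (i - 1) * SEGMENTS_PER_EPOCH + seq_len(SEGMENTS_PER_EPOCH)
    clean <- !mask$artifact[seg_idx]
    # maximal runs of contiguous clean segments within this epoch
    r <- rle(clean)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    wins <- list()
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      run_start_s <- (i - 1) * EPOCH_S + (starts[k] - 1) * SEGMENT_S
      run_len_s <- r$lengths[k] * SEGMENT_S
      offs <- seq(0, run_len_s - SEGMENT_S, by = SEGMENT_S / 2)
      wins[[length(wins) + 1]] <- run_start_s + offs
    }
    if (length(wins) > 0) {
      out[[i]] <- tibble::tibble(epoch = i, start_s = unlist(wins))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(epoch = integer(), start_s = numeric())
  }
  res
}

hann_window <- function(n) {
  # periodic Hann taper
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

#' Compute the averaged power spectral density for planned windows
#'
#' For every channel, each planned 4 s window is mean-detrended, Hann
#' tapered and Fourier transformed; one-sided periodogram densities are
#' averaged over windows and restricted to the 1-40 Hz grid (0.25 Hz bins,
#' the native resolution of a 4 s window). If a calibration curve is given,
#' power is divided by the squared amplitude reduction rate per bin.
#'
#' @param recording A [new_recording()] object; `fs * 4` must be a whole
#'   number of samples.
#' @param plan Window plan from [plan_windows()]; must be non-empty.
#' @param curve Optional `calibration_curve` for device-response correction.
#' @param channels Channels to analyse (default: all in the recording).
#' @return Tibble with columns `electrode`, `bin_hz`, `psd`.
#' @export
compute_psd <- function(recording, plan, curve = NULL, channels = NULL) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  nwin <- round(fs * SEGMENT_S)
  assert_that(abs(fs * SEGMENT_S - nwin) < 1e-9,
              "fs times the 4 s window length must be an integer sample count")
  assert_that(nrow(plan) > 0,
              sprintf("empty window plan for subject %s: no artifact-free windows",
                      recording$subject_id),
              class = "sleepspectra_processing_error")
  channels <- channels %||% recording$channels
  missing <- setdiff(channels, recording$channels)
  assert_that(length(missing) == 0,
              sprintf("channel(s) not in recording: %s", paste(missing, collapse = ", ")),
              class = "sleepspectra_lookup_error")

  starts <- round(plan$start_s * fs) + 1
  assert_that(max(starts) + nwin - 1 <= nrow(recording$data),
              "window plan extends past the end of the recording")
  w <- hann_window(nwin)
  scale <- 2 / (fs * sum(w^2))            # one-sided density normalization
  grid <- freq_bins()
  k_idx <- grid * SEGMENT_S + 1           # FFT bins of the 1-40 Hz grid (DC at 1)

  res <- purrr::map_dfr(channels, function(ch) {
    x <- recording$data[, ch]
    # samples x windows matrix of detrended, tapered windows
    M <- vapply(starts, function(s) {
      seg <- x[s:(s + nwin - 1)]
      (seg - mean(seg)) * w
    }, numeric(nwin))
    P <- abs(stats::mvfft(M))^2 * scale
    psd <- rowMeans(P[k_idx, , drop = FALSE])
    tibble::tibble(electrode = ch, bin_hz = grid, psd = psd)
  })
  if (!is.null(curve)) res <- correct_psd(res, curve)
  res
}

#' Relative log10 power on the 1-40 Hz grid
#'
#' Divides each bin's (calibration-corrected) power by the summed 1-40 Hz
#' power of the same electrode, then takes the base-10 logarithm. Zero bins
#' are floored at `eps` (as a relative-power value) with a warning, since
#' the logarithm of zero is undefined.
#'
#' @param psd Tibble with columns `electrode`, `bin_hz`, `psd`, or a bare
#'   numeric vector on the grid.
#' @param eps Relative-power floor for zero bins.
#' @return Same shape with `psd` replaced by `value` (relative log10 power).
#'   The antilogs of each electrode's values sum to 1 (up to flooring).
#' @export
relative_log_power <- function(psd, eps = 1e-12) {
  logrel <- function(p) {
    assert_that(any(p > 0), "relative power undefined: all bins are zero",
                class = "sleepspectra_processing_error")
    rel <- p / sum(p)
    if (any(rel <= 0)) {
      warn(sprintf("%d zero power bin(s) floored at %g before log", sum(rel <= 0), eps))
      rel[rel <= 0] <- eps
    }
    log10(rel)
  }
  if (is.numeric(psd) && is.null(dim(psd))) return(logrel(psd))
  assert_that(all(c("electrode", "bin_hz", "psd") %in% names(psd)),
              "`psd` needs columns electrode, bin_hz, psd")
  psd |>
    dplyr::group_by(.data$electrode) |>
    dplyr::mutate(value = logrel(.data$psd)) |>
    dplyr::ungroup() |>
    dplyr::select(-"psd")
}

#' Per-subject spectra from raw polysomnography
#'
#' Convenience composition: plan windows for each requested state, compute
#' calibrated PSDs and convert to relative log power, returning the long
#' spectra-table rows for one recording.
#'
#' @inheritParams compute_psd
#' @param hypnogram,mask Scored stage and artifact files for this recording.
#' @param states States to compute (default both).
#' @return Long spectra tibble (`subject_id`, `state`, `electrode`,
#'   `bin_hz`, `value`).
#' @export
subject_spectra <- function(recording, hypnogram, mask, curve = NULL,
                            states = c("NREM", "REM"), channels = NULL) {
  purrr::map_dfr(states, function(st) {
    plan <- plan_windows(hypnogram, mask, st)
    psd <- compute_psd(recording, plan, curve = curve, channels = channels)
    rel <- relative_log_power(psd)
    dplyr::mutate(rel, subject_id = recording$subject_id, state = st,
                  .before = 1)
  })
}

#' Re-reference a recording to mathematically linked mastoids
#'
#' Subtracts the average of the A1 and A2 channels from every other channel.
#' Input recordings are normally assumed to be re-referenced already; this
#' helper covers raw files that still carry the mastoid channels.
#'
#' @param recording A recording containing channels `A1` and `A2`.
#' @return A recording without the mastoid channels, re-referenced.
#' @export
reref_linked_mastoids <- function(recording) {
  stopifnot(inherits(recording, "psg_recording"))
  assert_that(all(c("A1", "A2") %in% recording$channels),
              "recording lacks A1/A2 mastoid channels",
              class = "sleepspectra_lookup_error")
  ref <- (recording$data[, "A1"] + recording$data[, "A2"]) / 2
  keep <- setdiff(recording$channels, c("A1", "A2"))
  new_recording(recording$data[, keep, drop = FALSE] - ref,
                fs = recording$fs, channels = keep,
                subject_id = recording$subject_id,
                device_id = recording$device_id)
}

#' Sleep macrostructure summary
#'
#' Tallies minutes per stage (20 s epochs, 1/3 minute each) and percentages
#' of total sleep time (NREM1 + NREM2 + SWS + REM). With zero sleep the
#' percentages are undefined and returned as `NA`.
#'
#' @param hypnogram Tibble from [read_hypnogram()].
#' @return Tibble with one row per stage (`stage`, `minutes`, `pct_tst`) and
#'   attribute `total_sleep_min`.
#' @export
macrostructure <- function(hypnogram) {
  assert_that(nrow(hypnogram) > 0, "empty hypnogram")
  tally <- hypnogram |>
    dplyr::count(stage = factor(.data$stage, levels = stage_codes()),
                 .drop = FALSE, name = "epochs") |>
    dplyr::mutate(stage = as.character(.data$stage),
                  minutes = .data$epochs / 3)
  tst <- sum(tally$minutes[tally$stage %in% sleep_stages()])
  tally$pct_tst <- ifelse(
    tally$stage %in% sleep_stages(),
    if (tst > 0) 100 * tally$minutes / tst else NA_real_,
    NA_real_
  )
  out <- dplyr::select(tally, "stage", "minutes", "pct_tst")
  attr(out, "total_sleep_min") <- tst
  out
}
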