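# Shared grids, montages and small helpers.

#' The analysis frequency grid
#'
#' All spectra and correlation maps in this package live on a fixed grid of
#' 0.25 Hz bins spanning 1.00-40.00 Hz inclusive (157 bins). Bin values label
#' bin centres; a 4 s analysis window at any sampling rate yields exactly this
#' native resolution.
#'
#' @return Numeric vector of 157 bin centre frequencies in Hz.
#' @export
#' @examples
#' length(freq_bins()) # 157
freq_bins <- function() {
  seq(1, 40, by = 0.25)
}

#' Electrode montages
#'
#' `montage_1020()` returns the 18-channel 10-20 recording montage used
#' throughout; `montage_12ch()` returns the 12-channel subset retained for the
#' permutation correction (the temporal arc F7, F8, T3, T4, T5, T6 is
#' excluded because those electrodes lack neighbours on one side, which makes
#' them poor candidates for neighbour imputation).
#'
#' @return Character vector of electrode labels in montage order.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8", "C3", "C4", "Cz",
    "P3", "P4", "T3", "T4", "T5", "T6", "O1", "O2")
}

#' @rdname montage_1020
#' @export
montage_12ch <- function() {
  c("Fp1", "Fp2", "F3", "F4", "Fz", "C3", "C4", "Cz", "P3", "P4", "O1", "O2")
}

#' Sleep stage codes
#'
#' Canonical stage labels: one per 20 s scoring epoch. `NREM` analyses pool
#' NREM2 and SWS; REM analyses use REM epochs only.
#'
#' @return Character vector of the recognised stage codes.
#' @export
stage_codes <- function() {
  c("WAKE", "NREM1", "NREM2", "SWS", "REM", "MOVEMENT")
}

# Stages counted as sleep for macrostructure percentages.
sleep_stages <- function() c("NREM1", "NREM2", "SWS", "REM")

# Epoch / segment geometry: 20 s epochs, 4 s artifact segments, 5 per epoch.
EPOCH_S <- 20
SEGMENT_S <- 4
SEGMENTS_PER_EPOCH <- EPOCH_S / SEGMENT_S

states_for <- function(state) {
  switch(match.arg(state, c("NREM", "REM")),
    NREM = c("NREM2", "SWS"),
    REM = "REM"
  )
}

# Validate that x is one of the canonical analysis states.
check_state <- function(state) {
  match.arg(state, c("NREM", "REM"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg, class = "sleepspectra_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
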