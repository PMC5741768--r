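# Synthetic cohorts with known ground truth. Spectra are generated directly
# in relative log-power space: each subject x electrode x bin value is a
# smooth Gaussian field (exponentially decaying correlation across
# electrodes and frequency bins) plus an age loading and, at planted cells,
# a loading on the subject's age-independent latent trait with a chosen
# partial correlation rho. Values are then renormalized so antilogs sum to
# one per electrode, as real relative spectra do.

#' Specify a synthetic cohort
#'
#' Defaults mirror the study conditions this package targets: 68 females
#' and 83 males aged 17-69, an 18-channel 10-20 montage with a small
#' electrode-failure pattern, and three female-only planted effects at
#' `rho = 0.45` (REM delta/theta negative frontally, REM beta positive
#' anteriorly, NREM alpha/sigma positive posteriorly/midline) with nulls in
#' males everywhere.
#'
#' @param n_female,n_male Group sizes (each at least 5).
#' @param age_range Uniform age range in years.
#' @param electrodes Montage to generate.
#' @param effects Tibble of planted effects: `state`, `f_lo`, `f_hi` (Hz,
#'   inside 1-40), `sex`, `rho` (|rho| < 1) and a list-column `electrodes`.
#'   `NULL` plants nothing (global null).
#' @param states States to generate spectra for.
#' @param age_r_trait Correlation of the trait with standardized age.
#' @param age_power_gain Maximum |correlation| of a bin with age (loading
#'   ramps linearly from negative at 1 Hz to positive at 40 Hz, so slow
#'   power falls and fast power rises with age).
#' @param smooth_elec Electrode-correlation decay length (index distance in
#'   montage order, exponential kernel).
#' @param smooth_freq Frequency-correlation decay length in Hz.
#' @param noise_sd Between-subject SD of relative log power, log10 units.
#' @param res_mean,res_sd Location/scale mapping the standardized trait to
#'   the RES scale.
#' @param missing_pattern Named integer vector: how many subjects lose each
#'   electrode (both states), emulating recording failures. `NULL` disables.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_female = 68, n_male = 83, age_range = c(17, 69),
                        electrodes = montage_1020(),
                        effects = default_effects(),
                        states = c("NREM", "REM"),
                        age_r_trait = -0.3, age_power_gain = 0.25,
                        smooth_elec = 1.5, smooth_freq = 2,
                        noise_sd = 0.15, res_mean = 21, res_sd = 6,
                        missing_pattern = default_missing_pattern()) {
  assert_that(n_female >= 5 && n_male >= 5, "need at least 5 subjects per sex",
              class = "sleepspectra_validation_error")
  if (!is.null(effects) && nrow(effects) > 0) {
    assert_that(all(abs(effects$rho) < 1), "|rho| must be < 1",
                class = "sleepspectra_validation_error")
    assert_that(all(effects$f_lo >= 1 & effects$f_hi <= 40 &
                      effects$f_lo <= effects$f_hi),
                "effect bands must lie within 1-40 Hz",
                class = "sleepspectra_validation_error")
    assert_that(all(unlist(effects$electrodes) %in% electrodes),
                "effect electrodes must belong to the montage",
                class = "sleepspectra_validation_error")
  }
  structure(
    list(n_female = n_female, n_male = n_male, age_range = age_range,
         electrodes = electrodes, effects = effects, states = states,
         age_r_trait = age_r_trait, age_power_gain = age_power_gain,
         smooth_elec = smooth_elec, smooth_freq = smooth_freq,
         noise_sd = noise_sd, res_mean = res_mean, res_sd = res_sd,
         missing_pattern = missing_pattern),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_effects <- function() {
  tibble::tibble(
    state = c("REM", "REM", "NREM"),
    f_lo = c(2.25, 12.25, 10.25),
    f_hi = c(5.25, 19.5, 14),
    sex = c("F", "F", "F"),
    rho = c(-0.45, 0.45, 0.45),
    electrodes = list(
      c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8", "C3", "C4", "Cz", "P3", "P4"),
      c("Fp1", "Fp2", "F3", "F4", "Fz", "C3", "C4", "Cz", "P3", "P4", "O1", "O2"),
      c("C3", "C4", "Cz", "P3", "P4", "T5", "O1", "O2")
    )
  )
}

#' @rdname cohort_spec
#' @export
default_missing_pattern <- function() {
  c(Fp1 = 10, Fp2 = 3, F4 = 2, F8 = 2, F7 = 2, T5 = 2,
    F3 = 1, T3 = 1, C3 = 1, O2 = 1, T6 = 1)
}

# baseline relative log-power shape per state: 1/f decay plus a sigma bump
# in NREM and a mild beta shoulder in REM
baseline_shape <- function(state, grid) {
  w <- switch(state,
    NREM = grid^-2.5 + 0.015 * exp(-(grid - 13.5)^2 / 2),
    REM = grid^-2 + 0.004 * exp(-(grid - 18)^2 / 18)
  )
  log10(w / sum(w))
}

exp_corr_chol <- function(k, decay) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  C <- exp(-d / decay)
  chol_ok <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(chol_ok)) {
    abort("implied smoothness covariance is not positive definite",
          class = "sleepspectra_validation_error")
  }
  t(chol_ok)  # lower triangular
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort bit-exactly.
#' @return A list of class `synth_cohort`: `spectra` (long tibble over the
#'   requested states, electrode failures absent), `subjects`, `res`, and
#'   `ground_truth` (planted effect table plus per-subject latent trait and
#'   age).
#' @export
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_female + spec$n_male
  ids <- sprintf("s%03d", seq_len(n))
  sex <- c(rep("F", spec$n_female), rep("M", spec$n_male))
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  zA <- as.vector(scale(age))

  a_t <- spec$age_r_trait
  eT <- rnorm(n)
  trait <- a_t * zA + sqrt(1 - a_t^2) * eT
  res_val <- spec$res_mean + spec$res_sd * trait
  raven_raw <- round(pmin(pmax(res_val, 0), 36))

  grid <- freq_bins()
  nb <- length(grid)
  elec <- spec$electrodes
  ne <- length(elec)
  Le <- exp_corr_chol(ne, spec$smooth_elec)
  Lf <- exp_corr_chol(nb, spec$smooth_freq / 0.25)  # decay in bins

  # per-bin age loading: negative at 1 Hz, positive at 40 Hz
  gamma <- spec$age_power_gain * (grid - mean(range(grid))) / diff(range(grid)) * 2

  eff <- spec$effects
  rho_for <- function(state) {
    R <- matrix(0, ne, nb, dimnames = list(elec, NULL))
    if (is.null(eff) || nrow(eff) == 0) return(list(F = R, M = R))
    out <- list(F = R, M = R)
    for (i in seq_len(nrow(eff))) {
      if (eff$state[i] != state) next
      cols <- which(grid >= eff$f_lo[i] & grid <= eff$f_hi[i])
      rows <- match(eff$electrodes[[i]], elec)
      out[[eff$sex[i]]][rows, cols] <- out[[eff$sex[i]]][rows, cols] + eff$rho[i]
    }
    if (any(abs(out$F) >= 1) || any(abs(out$M) >= 1)) {
      abort("overlapping effects imply |rho| >= 1 at some cell",
            class = "sleepspectra_validation_error")
    }
    out
  }

  spectra <- purrr::map_dfr(spec$states, function(st) {
    mu <- baseline_shape(st, grid)
    # first-order weights of the closure normalizer log10(sum(10^v)); noise
    # projected orthogonal to them so renormalization leaves planted partial
    # correlations intact instead of attenuating them
    w <- 10^mu / sum(10^mu)
    rho <- rho_for(st)
    vals <- matrix(0, n, ne * nb)
    for (i in seq_len(n)) {
      eta <- Le %*% matrix(rnorm(ne * nb), ne, nb) %*% t(Lf)
      eta <- eta - (eta %*% w) %*% t(w) / sum(w^2)
      Rm <- rho[[sex[i]]]
      S <- sweep(sqrt(1 - Rm^2) * eta + Rm * eT[i], 2, gamma * zA[i], "+")
      V <- sweep(spec$noise_sd * S, 2, mu, "+")
      # renormalize per electrode so antilogs sum to 1
      V <- V - log10(rowSums(10^V))
      vals[i, ] <- as.vector(V)   # electrode varies fastest
    }
    tibble::tibble(
      subject_id = rep(ids, times = ne * nb),
      state = st,
      electrode = rep(rep(elec, times = nb), each = n),
      bin_hz = rep(grid, each = n * ne),
      value = as.vector(vals)
    )
  })

  # electrode failures: drop those subject x electrode series in both states
  lost <- tibble::tibble(subject_id = character(), electrode = character())
  mp <- spec$missing_pattern
  if (!is.null(mp) && length(mp) > 0) {
    mp <- mp[names(mp) %in% elec]
    lost <- purrr::imap_dfr(as.list(mp), function(k, ch) {
      tibble::tibble(subject_id = sample(ids, k), electrode = ch)
    })
    spectra <- dplyr::anti_join(spectra, lost,
                                by = c("subject_id", "electrode"))
  }

  subjects <- tibble::tibble(
    subject_id = ids, sex = sex, age = age,
    raven_raw = raven_raw, cft_raw = NA_real_, device_id = "synth01"
  )
  res <- tibble::tibble(subject_id = ids, res = res_val,
                        provenance = "APM_only")
  structure(
    list(spectra = spectra, subjects = subjects, res = res,
         ground_truth = list(effects = eff, lost_electrodes = lost,
                             trait = tibble::tibble(subject_id = ids,
                                                    trait = trait,
                                                    latent = eT, age = age),
                             seed = seed)),
    class = "synth_cohort"
  )
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d subjects (%d F / %d M), %s spectra, %d planted effect(s)\n",
              nrow(x$subjects), sum(x$subjects$sex == "F"),
              sum(x$subjects$sex == "M"),
              paste(unique(x$spectra$state), collapse = "+"),
              if (is.null(x$ground_truth$effects)) 0L
              else nrow(x$ground_truth$effects)))
  invisible(x)
}

# ---- raw-signal fixtures -----------------------------------------------------

# 1/f ("pink") noise via spectral shaping of white noise
pink_noise <- function(n, fs) {
  white <- rnorm(n)
  W <- fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n                  # symmetric two-sided grid
  shape <- 1 / sqrt(pmax(f, fs / n))
  shape[1] <- 0
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate a raw-signal fixture with known spectral content
#'
#' Builds a single- or multi-channel recording whose epochs follow
#' `stage_plan`, adding the listed sinusoids only during epochs of their
#' state (NREM pools NREM2/SWS) on top of pink noise, together with the
#' matching hypnogram and artifact mask.
#'
#' @param stage_plan Character vector of stage codes, one per 20 s epoch.
#' @param components Tibble with columns `frequency`, `amplitude` (uV) and
#'   `state` (`"NREM"` or `"REM"`); `NULL` for noise only.
#' @param fs Sampling rate (>= 100 Hz; components must stay below fs/2).
#' @param channels Channel labels for the recording (same signal plus
#'   independent noise per channel).
#' @param noise_uv Pink-noise RMS amplitude in microvolts.
#' @param artifact_segments Integer indices of 4 s segments to flag as
#'   artifacts in the mask.
#' @param seed Integer seed.
#' @return List with `recording`, `hypnogram`, `mask`.
#' @export
generate_signal_fixture <- function(stage_plan, components = NULL, fs = 250,
                                    channels = "C3", noise_uv = 5,
                                    artifact_segments = integer(0), seed = 1) {
  assert_that(fs >= 100, "fs must be at least 100 Hz")
  assert_that(all(stage_plan %in% stage_codes()), "unknown stage code in plan")
  if (!is.null(components) && nrow(components) > 0) {
    assert_that(all(components$frequency < fs / 2),
                "component frequency at or above Nyquist",
                class = "sleepspectra_validation_error")
  }
  set.seed(seed)
  n_epoch <- length(stage_plan)
  n <- n_epoch * EPOCH_S * fs
  t <- (0:(n - 1)) / fs
  epoch_of <- floor(t / EPOCH_S) + 1
  data <- matrix(0, n, length(channels))
  for (j in seq_along(channels)) {
    x <- noise_uv * pink_noise(n, fs)
    if (!is.null(components) && nrow(components) > 0) {
      for (i in seq_len(nrow(components))) {
        in_state <- stage_plan[epoch_of] %in% states_for(components$state[i])
        x <- x + ifelse(in_state,
                        components$amplitude[i] *
                          sin(2 * pi * components$frequency[i] * t), 0)
      }
    }
    data[, j] <- x
  }
  rec <- new_recording(data, fs = fs, channels = channels,
                       subject_id = "fixture", device_id = "synth01")
  hyp <- tibble::tibble(epoch = seq_len(n_epoch), stage = stage_plan)
  n_seg <- n_epoch * SEGMENTS_PER_EPOCH
  mask <- tibble::tibble(segment = seq_len(n_seg),
                         artifact = seq_len(n_seg) %in% artifact_segments)
  list(recording = rec, hypnogram = hyp, mask = mask)
}

# ---- calibration fixtures ----------------------------------------------------

#' Analytic device gain functions
#'
#' `gain_identity()` is a flat unit response; `gain_highpass(cutoff)` the
#' magnitude response of a first-order analog high-pass filter,
#' `|H(f)| = 1 / sqrt(1 + (cutoff/f)^2)`.
#'
#' @param cutoff Cutoff frequency in Hz.
#' @return A function mapping frequency (Hz) to gain.
#' @export
gain_identity <- function() function(f) rep(1, length(f))

#' @rdname gain_identity
#' @export
gain_highpass <- function(cutoff) {
  force(cutoff)
  function(f) 1 / sqrt(1 + (cutoff / f)^2)
}

#' Apply a gain curve to a signal in the frequency domain
#'
#' Multiplies the signal's Fourier coefficients by `gain(f)` (zero-phase),
#' the forward model of a device's magnitude response. Used to fabricate
#' device-colored signals for calibration round trips.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param gain Function frequency -> gain (see [gain_highpass()]).
#' @return Filtered signal.
#' @export
filter_by_gain <- function(x, fs, gain) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f_folded <- pmin(f, fs - f)            # two-sided spectrum symmetry
  g <- gain(pmax(f_folded, 1e-12))
  g[1] <- 0                              # kill DC; high-pass devices have none
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

#' Generate a synthetic calibration sweep through a known device response
#'
#' Plays the standard sweep protocol — both generated amplitudes at every
#' [calibration_grid()] frequency — through an analytic gain function, with
#' additive white measurement noise, and returns both the sweep and the
#' ground-truth rates.
#'
#' @param gain Gain function (see [gain_highpass()]).
#' @param device_id Device label.
#' @param fs Sampling rate of the recorded sweeps.
#' @param noise_uv SD of additive recording noise in microvolts.
#' @param grid_freqs Probed frequencies.
#' @param amplitudes Generated amplitudes in microvolts.
#' @param seed Integer seed.
#' @return List with `sweep` (a `calibration_sweep`) and `truth` (tibble
#'   `frequency_hz`, `rate`).
#' @export
generate_calibration_sweep <- function(gain = gain_identity(),
                                       device_id = "synth01", fs = 250,
                                       noise_uv = 0.05,
                                       grid_freqs = calibration_grid(),
                                       amplitudes = calibration_amplitudes(),
                                       seed = 1) {
  set.seed(seed)
  entries <- tidyr::expand_grid(frequency_hz = grid_freqs,
                                generated_uv = amplitudes)
  entries$fs <- fs
  entries$signal <- purrr::map2(
    entries$frequency_hz, entries$generated_uv,
    function(f, amp) {
      dur <- max(4, ceiling(10 / f))
      t <- (0:(dur * fs - 1)) / fs
      amp * gain(f) * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
        rnorm(length(t), sd = noise_uv)
    }
  )
  list(sweep = new_calibration_sweep(device_id, entries),
       truth = tibble::tibble(frequency_hz = grid_freqs,
                              rate = gain(grid_freqs)))
}
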