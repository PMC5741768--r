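# Window planning, PSD estimation and relative log power.

clean_mask <- function(n_epochs) {
  tibble::tibble(segment = 1:(n_epochs * 5), artifact = FALSE)
}

test_that("window counts match hand enumeration on simple epochs", {
  hyp <- tibble::tibble(epoch = 1, stage = "NREM2")
  plan <- plan_windows(hyp, clean_mask(1), "NREM")
  expect_equal(plan$start_s, seq(0, 16, by = 2))  # 9 windows

  # middle 4 s segment artifacted: two 8 s runs of 3 windows each
  mask <- clean_mask(1)
  mask$artifact[3] <- TRUE
  plan2 <- plan_windows(hyp, mask, "NREM")
  expect_equal(plan2$start_s, c(0, 2, 4, 12, 14, 16))

  # all-REM hypnogram queried for NREM gives an explicit empty plan
  hyp_rem <- tibble::tibble(epoch = 1:3, stage = "REM")
  expect_equal(nrow(plan_windows(hyp_rem, clean_mask(3), "NREM")), 0)

  # NREM pools NREM2 and SWS but windows never cross the epoch boundary
  hyp_mix <- tibble::tibble(epoch = 1:2, stage = c("NREM2", "SWS"))
  plan3 <- plan_windows(hyp_mix, clean_mask(2), "NREM")
  expect_equal(nrow(plan3), 18)
  expect_false(18 %in% plan3$start_s)
})

test_that("window planner equals the brute-force enumerator on random masks", {
  set.seed(101)
  stages <- stage_codes()
  for (i in 1:1000) {
    n_ep <- sample(2:6, 1)
    hyp <- tibble::tibble(epoch = 1:n_ep,
                          stage = sample(stages, n_ep, replace = TRUE))
    mask <- tibble::tibble(segment = 1:(n_ep * 5),
                           artifact = runif(n_ep * 5) < 0.3)
    st <- sample(c("NREM", "REM"), 1)
    expect_identical(plan_windows(hyp, mask, st)$start_s,
                     oracle_windows(hyp, mask, st))
  }
})

test_that("a 10 Hz sinusoid lands exactly on the 10.00 Hz bin", {
  fs <- 250
  hyp <- tibble::tibble(epoch = 1:3, stage = "NREM2")
  t <- (0:(3 * 20 * fs - 1)) / fs
  rec <- new_recording(matrix(30 * sin(2 * pi * 10 * t), ncol = 1),
                       fs = fs, channels = "Cz")
  psd <- compute_psd(rec, plan_windows(hyp, clean_mask(3), "NREM"))
  expect_equal(psd$bin_hz[which.max(psd$psd)], 10)
  inband <- sum(psd$psd[abs(psd$bin_hz - 10) <= 0.5])
  expect_gt(inband / sum(psd$psd), 0.99)

  # zero signal -> all-zero PSD; averaging identical windows is the identity
  rec0 <- new_recording(matrix(0, 20 * fs, 1), fs = fs, channels = "Cz")
  p0 <- compute_psd(rec0, plan_windows(hyp[1, ], clean_mask(1), "NREM"))
  expect_true(all(p0$psd == 0))

  one <- compute_psd(rec, plan_windows(hyp[1, ], clean_mask(1), "NREM"))
  expect_equal(psd$psd, one$psd, tolerance = 1e-9)

  expect_error(compute_psd(rec, plan_windows(hyp, clean_mask(3), "REM")),
               class = "sleepspectra_processing_error")
})

test_that("integrated PSD density recovers band-limited signal variance", {
  set.seed(7)
  fs <- 250
  n_ep <- 15
  x <- filter_by_gain(rnorm(n_ep * 20 * fs, sd = 15), fs,
                      function(f) as.numeric(f >= 1.25 & f <= 39.75))
  rec <- new_recording(matrix(x, ncol = 1), fs = fs, channels = "C3")
  hyp <- tibble::tibble(epoch = 1:n_ep, stage = "NREM2")
  psd <- compute_psd(rec, plan_windows(hyp, clean_mask(n_ep), "NREM"))
  expect_equal(sum(psd$psd) * 0.25, var(x), tolerance = 0.02)
})

test_that("relative log power normalizes, floors zeros, ignores scale", {
  flat <- relative_log_power(rep(3.7, 157))
  expect_equal(flat, rep(log10(1 / 157), 157), tolerance = 1e-12)

  p <- runif(157, 0.5, 4)
  v <- relative_log_power(p)
  expect_equal(sum(10^v), 1, tolerance = 1e-9)
  expect_equal(relative_log_power(2 * p), v, tolerance = 1e-12)

  pz <- p; pz[40] <- 0
  expect_warning(vz <- relative_log_power(pz), "floored")
  expect_equal(vz[40], log10(1e-12))
  expect_error(suppressWarnings(relative_log_power(rep(0, 157))),
               class = "sleepspectra_processing_error")
})

test_that("relative spectra are invariant to signal gain end to end", {
  fix <- generate_signal_fixture(rep("NREM2", 4),
                                 tibble::tibble(frequency = 12, amplitude = 20,
                                                state = "NREM"),
                                 seed = 5)
  sp1 <- subject_spectra(fix$recording, fix$hypnogram, fix$mask,
                         states = "NREM")
  rec2 <- fix$recording
  rec2$data <- rec2$data * 7.3
  sp2 <- subject_spectra(rec2, fix$hypnogram, fix$mask, states = "NREM")
  expect_equal(sp1$value, sp2$value, tolerance = 1e-9)
})

test_that("linked-mastoid re-referencing subtracts the A1/A2 mean", {
  x <- matrix(rnorm(400 * 3), ncol = 3)
  rec <- new_recording(x, fs = 100, channels = c("C3", "A1", "A2"))
  rr <- reref_linked_mastoids(rec)
  expect_equal(rr$channels, "C3")
  expect_equal(rr$data[, 1], x[, 1] - (x[, 2] + x[, 3]) / 2)
  expect_error(reref_linked_mastoids(new_recording(x, 100, c("C3", "C4", "Cz"))),
               class = "sleepspectra_lookup_error")
})

test_that("macrostructure tallies minutes and percentages of sleep time", {
  hyp <- tibble::tibble(epoch = 1:60,
                        stage = rep(c("NREM2", "REM"), each = 30))
  ms <- macrostructure(hyp)
  expect_equal(ms$minutes[ms$stage == "NREM2"], 10)
  expect_equal(ms$pct_tst[ms$stage == "REM"], 50)
  expect_equal(sum(ms$pct_tst, na.rm = TRUE), 100, tolerance = 1e-6)
  expect_equal(attr(ms, "total_sleep_min"), 20)

  wake <- macrostructure(tibble::tibble(epoch = 1:5, stage = "WAKE"))
  expect_true(all(is.na(wake$pct_tst)))
  expect_equal(attr(wake, "total_sleep_min"), 0)

  # mixed toy hypnogram vs hand tally
  mix <- tibble::tibble(epoch = 1:9,
                        stage = c("WAKE", "NREM1", "NREM2", "NREM2", "SWS",
                                  "REM", "REM", "REM", "MOVEMENT"))
  m2 <- macrostructure(mix)
  expect_equal(m2$minutes[match(c("WAKE", "NREM2", "REM"), m2$stage)],
               c(1, 2, 3) / 3)
  expect_equal(m2$pct_tst[m2$stage == "REM"], 100 * 3 / 7, tolerance = 1e-9)
})

test_that("state-specific components appear only in their state's spectrum", {
  fix <- generate_signal_fixture(
    rep(c("NREM2", "REM"), each = 4),
    tibble::tibble(frequency = 10, amplitude = 30, state = "NREM"),
    noise_uv = 2, seed = 31
  )
  nrem <- compute_psd(fix$recording,
                      plan_windows(fix$hypnogram, fix$mask, "NREM"))
  rem <- compute_psd(fix$recording,
                     plan_windows(fix$hypnogram, fix$mask, "REM"))
  expect_equal(nrem$bin_hz[which.max(nrem$psd)], 10)
  ratio <- nrem$psd[nrem$bin_hz == 10] / rem$psd[rem$bin_hz == 10]
  expect_gt(ratio, 50)
})
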