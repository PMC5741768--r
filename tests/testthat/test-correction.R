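# Rueger areas, channel imputation and the permutation max-statistic test.

test_that("area finding matches the brute-force oracle on toy grids", {
  # significant cells on bins 5-9 (1 Hz grid offsets) on two electrodes
  sig <- matrix(FALSE, 3, 20)
  sig[1, 5:9] <- TRUE
  sig[2, c(5, 7, 9)] <- TRUE
  cm <- pattern_corrmap(sig)
  areas <- find_ruger_areas(cm)
  orc <- oracle_ruger(cm)
  expect_equal(nrow(areas), 1)
  expect_equal(length(orc), 1)
  expect_equal(areas$n_bins, 5)
  expect_equal(areas$first_hz, orc[[1]]$first_hz)
  expect_equal(areas$n_sig, orc[[1]]$n_sig)
  expect_equal(areas$frac_half, orc[[1]]$frac_half, tolerance = 1e-12)
  expect_equal(areas$decision, orc[[1]]$decision)

  # single-electrode areas are discarded
  sig1 <- matrix(FALSE, 3, 20); sig1[2, 2:10] <- TRUE
  expect_equal(nrow(find_ruger_areas(pattern_corrmap(sig1))), 0)

  # sub-1 Hz (3-bin) areas are discarded
  sig2 <- matrix(FALSE, 3, 20); sig2[1:2, 6:8] <- TRUE
  expect_equal(nrow(find_ruger_areas(pattern_corrmap(sig2))), 0)

  # missing cells (NA p) are tolerated
  cm$p[c(3, 17)] <- NA
  expect_no_error(find_ruger_areas(cm))
})

test_that("area finding equals exhaustive enumeration (all 3x4 patterns plus random 3x8)", {
  bad <- NULL
  # every significance pattern of a 3-electrode x 4-bin grid
  for (code in 0:(2^12 - 1)) {
    sig <- matrix(bitwAnd(bitwShiftR(code, 0:11), 1L) == 1L, nrow = 3)
    bad <- bad %||% check_vs_oracle(sig, paste0("3x4#", code))
  }
  expect_null(bad)
  # seeded random patterns on the wider 3x8 grid
  set.seed(404)
  for (i in 1:4096) {
    sig <- matrix(runif(24) < runif(1, 0.1, 0.7), nrow = 3)
    bad <- bad %||% check_vs_oracle(sig, paste0("3x8#", i))
  }
  expect_null(bad)
})

test_that("decision thresholds use exact fractions at the boundary", {
  expect_true(decide_ruger(0.5, 0))
  expect_false(decide_ruger(0.4999, 0.333))      # 0.333 < 1/3
  expect_true(decide_ruger(0, 1 / 3))
  expect_error(decide_ruger(1.2, 0))
})

test_that("max-association cell breaks ties toward low frequency and montage", {
  sig <- matrix(FALSE, 3, 12)
  sig[1:2, 3:8] <- TRUE
  cm <- pattern_corrmap(sig)
  cm$r[cm$p < 0.05] <- 0.5            # all-tied |r|
  a <- find_ruger_areas(cm)
  expect_equal(a$max_bin_hz, min(cm$bin_hz[cm$p < 0.05]))
  expect_equal(a$max_electrode, "Fp1")
})

test_that("channel imputation follows the midline and neighbour rules", {
  co <- generate_cohort(cohort_spec(n_female = 6, n_male = 6, states = "REM",
                                    missing_pattern = NULL, effects = NULL),
                        seed = 61)
  sp <- co$spectra

  # no missing channels: identity on the 12-channel restriction
  expect_equal(impute_channels(sp),
               dplyr::arrange(sp[sp$electrode %in% montage_12ch(), ],
                              subject_id, state,
                              match(electrode, montage_12ch()), bin_hz))

  # missing Fz := mean(F3, F4) bin-wise
  drop_fz <- sp[!(sp$subject_id == "s001" & sp$electrode == "Fz"), ]
  imp <- impute_channels(drop_fz)
  got <- imp$value[imp$subject_id == "s001" & imp$electrode == "Fz"]
  f3 <- sp$value[sp$subject_id == "s001" & sp$electrode == "F3"]
  f4 <- sp$value[sp$subject_id == "s001" & sp$electrode == "F4"]
  expect_equal(got, (f3 + f4) / 2, tolerance = 1e-12)

  # missing O2 := mean of configured neighbours O1, P4
  drop_o2 <- sp[!(sp$subject_id == "s002" & sp$electrode == "O2"), ]
  imp2 <- impute_channels(drop_o2)
  got2 <- imp2$value[imp2$subject_id == "s002" & imp2$electrode == "O2"]
  o1 <- sp$value[sp$subject_id == "s002" & sp$electrode == "O1"]
  p4 <- sp$value[sp$subject_id == "s002" & sp$electrode == "P4"]
  expect_equal(got2, (o1 + p4) / 2, tolerance = 1e-12)

  # no available neighbour at all -> error naming the subject: with a target
  # of only Fp1 and O1 (not adjacent), a subject missing Fp1 has no donor
  iso <- sp[sp$electrode %in% c("O1", "Fp1"), ]
  iso <- iso[!(iso$subject_id == "s003" & iso$electrode == "Fp1"), ]
  err <- expect_error(impute_channels(iso, target = c("Fp1", "O1")),
                      class = "sleepspectra_validation_error")
  expect_match(conditionMessage(err), "s003")
})

test_that("perfect correlation hits the permutation p floor; seeds reproduce", {
  spec <- cohort_spec(n_female = 30, n_male = 5, states = "REM",
                      electrodes = montage_12ch(), effects = NULL,
                      missing_pattern = NULL)
  co <- generate_cohort(spec, seed = 71)
  # make the trait equal one cell's residualized values: |r| = 1 there
  cellv <- co$spectra$value[co$spectra$electrode == "Cz" &
                              co$spectra$bin_hz == 20]
  res2 <- co$res
  fidx <- match(co$subjects$subject_id[co$subjects$sex == "F"],
                co$res$subject_id)
  ages <- co$subjects$age
  res2$res <- 0
  res2$res[fidx] <- cellv[fidx] -
    ages[fidx] * 0  # raw equality; residualization is applied inside
  n_perm <- 400
  pr <- permutation_correct(co$spectra, res2, co$subjects, "F", "REM",
                            n_perm = n_perm, family = "bin", seed = 5)
  cz <- pr$table[pr$table$electrode == "Cz" & pr$table$bin_hz == 20, ]
  expect_equal(cz$r, 1, tolerance = 1e-9)
  expect_equal(cz$p_corrected, 1 / (n_perm + 1))

  pr2 <- permutation_correct(co$spectra, res2, co$subjects, "F", "REM",
                             n_perm = n_perm, family = "bin", seed = 5)
  expect_identical(pr$table$p_corrected, pr2$table$p_corrected)
  pr3 <- permutation_correct(co$spectra, res2, co$subjects, "F", "REM",
                             n_perm = n_perm, family = "bin", seed = 6)
  expect_false(identical(pr$table$p_corrected, pr3$table$p_corrected))
})

test_that("permutation p-values respect floors, monotonicity and family size", {
  spec <- cohort_spec(n_female = 24, n_male = 5, states = "REM",
                      electrodes = montage_12ch(), effects = NULL,
                      missing_pattern = NULL)
  co <- generate_cohort(spec, seed = 81)
  n_perm <- 300
  bin_fam <- permutation_correct(co$spectra, co$res, co$subjects, "F", "REM",
                                 n_perm = n_perm, family = "bin", seed = 9)
  grid_fam <- permutation_correct(co$spectra, co$res, co$subjects, "F", "REM",
                                  n_perm = n_perm, family = "grid", seed = 9)
  tb <- bin_fam$table; tg <- grid_fam$table
  expect_true(all(tb$p_corrected >= 1 / (n_perm + 1)))
  expect_true(all(tb$p_corrected >= tb$p_uncorrected - 1e-12))
  # larger family -> never less strict
  expect_true(all(tg$p_corrected >= tb$p_corrected - 1e-12))
  # within a family, corrected p is monotone non-increasing in |r|
  one_bin <- tb[tb$bin_hz == 10, ]
  ord <- order(abs(one_bin$r))
  expect_true(all(diff(one_bin$p_corrected[ord]) <= 1e-12))

  expect_warning(permutation_correct(co$spectra, co$res, co$subjects, "F",
                                     "REM", n_perm = 50, family = "bin",
                                     seed = 1), "coarse")
  # incomplete spectra are rejected
  sp_inc <- co$spectra[!(co$spectra$subject_id == "s001" &
                           co$spectra$electrode == "Cz"), ]
  expect_error(permutation_correct(sp_inc, co$res, co$subjects, "F", "REM",
                                   n_perm = 100, seed = 1),
               class = "sleepspectra_validation_error")
})

test_that("significant-range reporting drops single-channel ranges", {
  fake <- structure(list(
    table = tibble::tibble(
      electrode = rep(c("F3", "F4", "C3"), times = 10),
      bin_hz = rep(seq(3, 5.25, by = 0.25), each = 3),
      r = 0.5,
      p_uncorrected = 0.01,
      p_corrected = 0.5
    ),
    n = 30, n_perm = 100, family = "bin", seed = 1, sex = "F", state = "REM"
  ), class = "perm_result")
  # a multi-channel range 3.25-4.25, a clean gap, then a single-channel
  # (F4-only) range at 5-5.25 which must be dropped
  fake$table$p_corrected[fake$table$bin_hz >= 3.25 & fake$table$bin_hz <= 4.25 &
                           fake$table$electrode %in% c("F3", "C3")] <- 0.01
  fake$table$p_corrected[fake$table$bin_hz >= 5 & fake$table$electrode == "F4"] <- 0.01
  rg <- summarize_significant_ranges(fake)
  expect_equal(nrow(rg), 1)
  expect_equal(c(rg$first_hz, rg$last_hz), c(3.25, 4.25))
  expect_equal(rg$channels[[1]], c("C3", "F3"))

  fake$table$p_corrected <- 1
  expect_equal(nrow(summarize_significant_ranges(fake)), 0)
})
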