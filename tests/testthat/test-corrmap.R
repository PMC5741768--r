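# Age-partial correlation mapping and Fisher r-to-z comparisons.

# closed-form partial correlation oracle (independent of the residual path)
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

test_that("partial correlation equals the closed-form and residual oracles", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
    got <- partial_corr(x, y, z)
    expect_equal(got$r, oracle_partial_r(x, y, z), tolerance = 1e-12)
    # explicit two-regression residual oracle
    rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
    expect_equal(got$r, cor(rx, ry), tolerance = 1e-12)
    tt <- got$r * sqrt((n - 3) / (1 - got$r^2))
    expect_equal(got$p, 2 * pt(-abs(tt), n - 3), tolerance = 1e-12)
  }
})

test_that("orthogonal covariates reduce the partial r to the plain r", {
  set.seed(22)
  n <- 64
  x <- rnorm(n); y <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x + y))  # orthogonal to both by construction
  expect_equal(partial_corr(x, y, z)$r, cor(x, y), tolerance = 1e-12)
})

test_that("partial correlation is invariant to affine transforms", {
  set.seed(23)
  n <- 30
  z <- rnorm(n); x <- z + rnorm(n); y <- z + rnorm(n)
  base <- partial_corr(x, y, z)
  shifted <- partial_corr(3 * x - 7, 0.2 * y + 11, -5 * z + 2)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_equal(shifted$p, base$p, tolerance = 1e-12)
})

test_that("degenerate inputs are marked missing, not crashed", {
  set.seed(24)
  z <- rnorm(20); x <- rnorm(20)
  # y identical to the covariate: y-residuals are the zero vector
  out <- partial_corr(x, z, z)
  expect_true(is.na(out$r) && is.na(out$p))
  expect_error(partial_corr(rnorm(4), rnorm(4), rnorm(4)),
               class = "sleepspectra_precondition_error")
})

test_that("residualize centers under constant covariate, is orthogonal", {
  v <- c(4, 8, 15, 16, 23, 42)
  expect_equal(residualize(v, rep(2, 6)), v - mean(v), tolerance = 1e-12)
  set.seed(25)
  z <- rnorm(50); v <- 2 * z + rnorm(50)
  r <- residualize(v, z)
  expect_lt(abs(sum(r * z)), 1e-9)
})

test_that("corrmap recovers a planted effect and is null where planted null", {
  eff <- tibble::tibble(state = "REM", f_lo = 18, f_hi = 20, sex = "F",
                        rho = 0.45, electrodes = list(c("F3", "F4")))
  spec <- tiny_spec(effects = eff, n_female = 68, n_male = 60)
  rs <- replicate(30, {
    co <- generate_cohort(spec, seed = sample.int(1e6, 1))
    cm <- build_corrmap(co$spectra, co$res, co$subjects, "F", "REM")
    mean(cm$r[cm$electrode %in% c("F3", "F4") &
                cm$bin_hz >= 18 & cm$bin_hz <= 20])
  })
  # mean of planted-cell r-hats across cohorts must sit near rho = 0.45
  expect_lt(abs(mean(rs) - 0.45), 3 * sd(rs) / sqrt(length(rs)) + 0.03)

  co <- generate_cohort(spec, seed = 77)
  cmM <- build_corrmap(co$spectra, co$res, co$subjects, "M", "REM")
  # null male grid: |r| stays in a plausible null envelope
  expect_lt(mean(abs(cmM$r)), 2 / sqrt(60 - 3))
  expect_gt(min(cmM$p), 1e-6)
})

test_that("corrmap excludes missing electrodes cell-wise and flags strays", {
  spec <- tiny_spec(n_female = 30, n_male = 20,
                    missing_pattern = c(F3 = 4, O2 = 2))
  co <- generate_cohort(spec, seed = 31)
  cm <- build_corrmap(co$spectra, co$res, co$subjects, "F", "REM")
  lost <- co$ground_truth$lost_electrodes
  lost_f <- sum(lost$electrode == "F3" &
                  lost$subject_id %in% co$subjects$subject_id[co$subjects$sex == "F"])
  expect_equal(unique(cm$n[cm$electrode == "F3"]), 30 - lost_f)
  expect_equal(unique(cm$n[cm$electrode == "C3"]), 30)

  sp_bad <- co$spectra
  sp_bad$subject_id[sp_bad$subject_id == "s001"] <- "ghost"
  expect_error(build_corrmap(sp_bad, co$res, co$subjects, "F", "REM"),
               class = "sleepspectra_validation_error")
})

test_that("null cohorts give a nominal 5% significant-cell rate", {
  spec <- tiny_spec(n_female = 40, n_male = 5)
  fracs <- vapply(1:200, function(i) {
    co <- generate_cohort(spec, seed = 40000 + i)
    cm <- build_corrmap(co$spectra, co$res, co$subjects, "F", "REM")
    mean(cm$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.01)
})

test_that("Fisher comparison matches its closed form and is antisymmetric", {
  expect_equal(fisher_compare(0.3, 40, 0.3, 50)$z, 0)
  expect_equal(fisher_compare(0.3, 40, 0.3, 50)$p, 1)

  a <- fisher_compare(0.52, 68, 0.11, 83)
  b <- fisher_compare(0.11, 83, 0.52, 68)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$z, (atanh(0.52) - atanh(0.11)) /
                 sqrt(1 / 65 + 1 / 80), tolerance = 1e-12)

  expect_error(fisher_compare(1, 40, 0.2, 40),
               class = "sleepspectra_validation_error")
})

test_that("Fisher p-values are uniform under equal true correlations", {
  set.seed(29)
  n <- 30
  rho <- 0.4
  ps <- vapply(1:2000, function(i) {
    g1 <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
    g2 <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, rho, rho, 1), 2))
    fisher_compare(cor(g1)[1, 2], n, cor(g2)[1, 2], n)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("dimorphism table pulls the right cells from both maps", {
  eff <- tibble::tibble(state = "REM", f_lo = 18, f_hi = 20, sex = "F",
                        rho = 0.6, electrodes = list(c("F3", "F4")))
  co <- generate_cohort(tiny_spec(effects = eff, n_female = 40, n_male = 40),
                        seed = 51)
  cmF <- build_corrmap(co$spectra, co$res, co$subjects, "F", "REM")
  cmM <- build_corrmap(co$spectra, co$res, co$subjects, "M", "REM")
  cells <- tibble::tibble(electrode = "F3", bin_hz = 19)
  dt <- dimorphism_tests(cmF, cmM, cells)
  expect_equal(dt$r_female, cmF$r[cmF$electrode == "F3" & cmF$bin_hz == 19])
  expect_equal(dt$n_female, 40)
  expect_equal(dt$p, normal_two_tailed_p(dt$z))
})
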