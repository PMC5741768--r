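# Mass-univariate correlation mapping: age-partial Pearson correlations
# between the trait score and relative log power in every electrode x bin
# cell, computed separately per sex and sleep state, plus Fisher r-to-z
# comparisons of correlations between two independent groups.

#' Least-squares residuals against one covariate
#'
#' Residuals of `values` after linear regression on `covariate` (with
#' intercept). The Pearson correlation of two series residualized against
#' the same covariate equals their partial correlation given that covariate.
#' A constant covariate degenerates to simple centering.
#'
#' @param values Numeric vector (or matrix, residualized columnwise).
#' @param covariate Numeric vector.
#' @return Residuals with the same shape as `values`.
#' @export
residualize <- function(values, covariate) {
  v <- as.matrix(values)
  assert_that(nrow(v) == length(covariate),
              "`values` and `covariate` lengths differ")
  assert_that(nrow(v) >= 3, "at least 3 observations are required")
  if (var(covariate) < .Machine$double.eps) {
    out <- sweep(v, 2, colMeans(v))
  } else {
    out <- lm.fit(cbind(1, covariate), v)$residuals
  }
  if (is.null(dim(values))) as.vector(out) else out
}

#' Age-partial Pearson correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on `covariate`; the two-tailed p-value uses
#' `t = r * sqrt((n - 3) / (1 - r^2))` on `n - 3` degrees of freedom (one
#' covariate consumes one further degree of freedom beyond the usual two).
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector (e.g. age).
#' @return One-row tibble: `r`, `p`, `n`. Degenerate inputs (zero residual
#'   variance) yield `NA` r and p.
#' @export
partial_corr <- function(x, y, covariate) {
  keep <- stats::complete.cases(x, y, covariate)
  x <- x[keep]; y <- y[keep]; covariate <- covariate[keep]
  n <- length(x)
  assert_that(n >= 5, "at least 5 complete observations are required",
              class = "sleepspectra_precondition_error")
  rx <- residualize(x, covariate)
  ry <- residualize(y, covariate)
  if (sd(rx) < 1e-14 || sd(ry) < 1e-14) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(rx, ry)
  tibble::tibble(r = r, p = partial_corr_p(r, n), n = n)
}

# two-tailed p for an age-partial r at sample size n (df = n - 3)
partial_corr_p <- function(r, n) {
  t <- r * sqrt((n - 3) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), df = n - 3)
}

#' Critical partial correlation at a significance level
#'
#' The |r| at which the two-tailed age-partial test on `n - 3` degrees of
#' freedom is exactly `alpha`; used for the horizontal reference line on
#' spectro-correlograms.
#'
#' @param n Sample size.
#' @param alpha Two-tailed level.
#' @return Positive critical r.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- qt(1 - alpha / 2, df = n - 3)
  tc / sqrt(n - 3 + tc^2)
}

#' Build an age-partial correlation map over the electrode x bin grid
#'
#' For one sleep state and one sex, correlates the trait score with relative
#' log power in every electrode x frequency-bin cell, partialling out age.
#' Subjects with a missing electrode are excluded cell-wise (listwise per
#' electrode), so `n` varies over electrodes. Cells with fewer than
#' `min_n` subjects are marked missing with a warning.
#'
#' @param spectra Long spectra tibble (see [validate_spectra()]).
#' @param res RES tibble (`subject_id`, `res`), e.g. from
#'   [score_subjects()].
#' @param subjects Subject tibble with `subject_id`, `sex`, `age`.
#' @param sex `"F"` or `"M"`.
#' @param state `"NREM"` or `"REM"`.
#' @param min_n Minimum subjects per cell.
#' @return A `sleep_corrmap` tibble: `state`, `sex`, `electrode`, `bin_hz`,
#'   `r`, `p`, `n`.
#' @export
build_corrmap <- function(spectra, res, subjects, sex = c("F", "M"),
                          state = c("NREM", "REM"), min_n = 5) {
  sex <- match.arg(sex)
  state <- match.arg(state)
  subs <- subjects[subjects$sex == sex, c("subject_id", "age")]
  subs <- dplyr::inner_join(subs, res[c("subject_id", "res")], by = "subject_id")
  sp <- spectra[spectra$state == state & spectra$subject_id %in% subs$subject_id, ]
  stray <- setdiff(unique(spectra$subject_id), subjects$subject_id)
  assert_that(length(stray) == 0,
              sprintf("spectra contain subject(s) absent from the subject table: %s",
                      paste(head(stray, 5), collapse = ", ")),
              class = "sleepspectra_validation_error")
  assert_that(nrow(sp) > 0, sprintf("no %s spectra for sex %s", state, sex),
              class = "sleepspectra_validation_error")
  grid <- freq_bins()

  maps <- sp |>
    dplyr::group_by(.data$electrode) |>
    dplyr::group_map(function(g, key) {
      wide <- tidyr::pivot_wider(g, id_cols = "subject_id",
                                 names_from = "bin_hz", values_from = "value")
      ids <- wide$subject_id
      M <- as.matrix(wide[, -1])
      meta <- subs[match(ids, subs$subject_id), ]
      n <- nrow(M)
      if (n < min_n) {
        warn(sprintf("electrode %s has only %d %s subjects; cells marked missing",
                     key$electrode, n, sex))
        return(tibble::tibble(electrode = key$electrode, bin_hz = grid,
                              r = NA_real_, p = NA_real_, n = n))
      }
      RX <- residualize(M, meta$age)
      ry <- residualize(meta$res, meta$age)
      ssy <- sqrt(sum(ry^2))
      ssx <- unname(sqrt(colSums(RX^2)))
      r <- as.vector(crossprod(ry, RX)) / (ssy * ssx)
      degenerate <- ssx < 1e-12 | ssy < 1e-12
      r[degenerate] <- NA_real_
      tibble::tibble(electrode = key$electrode,
                     bin_hz = as.numeric(colnames(wide)[-1]),
                     r = r, p = partial_corr_p(r, n), n = n)
    }) |>
    dplyr::bind_rows()

  out <- dplyr::mutate(maps, state = state, sex = sex, .before = 1)
  out <- dplyr::arrange(out, match(.data$electrode, montage_1020()), .data$bin_hz)
  class(out) <- c("sleep_corrmap", class(out))
  out
}

#' Two-tailed standard-normal p-value
#'
#' `p = 2 * (1 - Phi(|z|))`, the tail computation backing Fisher r-to-z
#' comparisons.
#'
#' @param z Numeric z statistics.
#' @return Two-tailed p-values.
#' @export
normal_two_tailed_p <- function(z) {
  assert_that(all(is.finite(z)), "z must be finite")
  2 * pnorm(-abs(z))
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests the difference of two correlation coefficients from independent
#' groups with the variance-stabilizing transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-tailed
#' normal p. By default the ordinary `n - 3` variance is used even when the
#' correlations are age-partial; `partial_covariates` subtracts the
#' covariate count from each `n` instead.
#'
#' @param r1,r2 Correlation coefficients (strictly inside (-1, 1)).
#' @param n1,n2 Group sizes (> 6).
#' @param partial_covariates Number of partialled covariates to charge
#'   against the degrees of freedom (default 0).
#' @return Tibble with columns `z` and `p` (vectorized over inputs).
#' @export
fisher_compare <- function(r1, n1, r2, n2, partial_covariates = 0) {
  assert_that(all(abs(r1) < 1) && all(abs(r2) < 1),
              "|r| = 1 has an infinite Fisher transform",
              class = "sleepspectra_validation_error")
  assert_that(all(n1 > 6) && all(n2 > 6), "group sizes must exceed 6")
  k <- partial_covariates
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3 - k) + 1 / (n2 - 3 - k))
  tibble::tibble(z = z, p = normal_two_tailed_p(z))
}

#' Sexual-dimorphism tests at chosen grid cells
#'
#' Looks up the female and male partial correlations at the given
#' electrode x bin cells and applies [fisher_compare()] to each.
#'
#' @param corrmap_f,corrmap_m `sleep_corrmap`s for the two sexes (same
#'   state).
#' @param cells Tibble with columns `electrode` and `bin_hz`.
#' @inheritParams fisher_compare
#' @return Tibble: `electrode`, `bin_hz`, `r_female`, `n_female`, `r_male`,
#'   `n_male`, `z`, `p`.
#' @export
dimorphism_tests <- function(corrmap_f, corrmap_m, cells,
                             partial_covariates = 0) {
  pick <- function(map, suffix) {
    m <- dplyr::semi_join(tibble::as_tibble(map), cells,
                          by = c("electrode", "bin_hz"))
    m <- m[c("electrode", "bin_hz", "r", "n")]
    names(m)[3:4] <- paste0(c("r_", "n_"), suffix)
    m
  }
  out <- cells |>
    dplyr::left_join(pick(corrmap_f, "female"), by = c("electrode", "bin_hz")) |>
    dplyr::left_join(pick(corrmap_m, "male"), by = c("electrode", "bin_hz"))
  ft <- fisher_compare(out$r_female, out$n_female, out$r_male, out$n_male,
                       partial_covariates = partial_covariates)
  dplyr::bind_cols(out, ft)
}
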