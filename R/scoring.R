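# Raven Equivalent Score (RES): a composite raw intelligence score on the
# Raven APM scale. APM raw scores pass through unchanged; CFT raw scores are
# converted via norm tables (CFT raw + age -> IQ -> percentile -> APM raw).
# Real published norms are copyrighted and therefore pluggable: the package
# ships clearly labelled SYNTHETIC monotone tables for testing only.

#' Load norm tables for RES conversion
#'
#' Two CSV schemas:
#' * CFT table: columns `cft_raw`, `age_lo`, `age_hi`, `iq` — IQ equivalent
#'   of a CFT raw score within an age band (linear interpolation in
#'   `cft_raw` within a band).
#' * APM table: columns `percentile`, `raw` — APM raw score at an IQ
#'   percentile, monotonically non-decreasing (linear interpolation; ties
#'   broken toward the lower raw score).
#'
#' @param cft_path,apm_path Paths to the two CSVs. Defaults are the
#'   package's synthetic, non-normative tables.
#' @param iq_sd Standard deviation of the IQ scale used to turn IQ into a
#'   percentile of a normal distribution with mean 100.
#' @return A `norm_tables` object.
#' @export
read_norm_tables <- function(
    cft_path = system.file("extdata", "synthetic_cft_norms.csv",
                           package = "sleepspectra"),
    apm_path = system.file("extdata", "synthetic_apm_norms.csv",
                           package = "sleepspectra"),
    iq_sd = 15) {
  cft <- readr::read_csv(cft_path, show_col_types = FALSE)
  apm <- readr::read_csv(apm_path, show_col_types = FALSE)
  new_norm_tables(cft, apm, iq_sd = iq_sd)
}

#' @rdname read_norm_tables
#' @param cft,apm Data frames following the two schemas above.
#' @export
new_norm_tables <- function(cft, apm, iq_sd = 15) {
  assert_that(all(c("cft_raw", "age_lo", "age_hi", "iq") %in% names(cft)),
              "CFT norm table needs columns cft_raw, age_lo, age_hi, iq")
  assert_that(all(c("percentile", "raw") %in% names(apm)),
              "APM norm table needs columns percentile and raw")
  apm <- dplyr::arrange(apm, .data$percentile, .data$raw)
  assert_that(all(apm$percentile > 0 & apm$percentile < 100),
              "APM percentiles must lie strictly inside (0, 100)")
  assert_that(!is.unsorted(apm$raw),
              "APM raw scores must be non-decreasing in percentile",
              class = "sleepspectra_validation_error")
  # ties toward the lower raw score: keep the first row of each percentile
  apm <- apm[!duplicated(apm$percentile), ]
  structure(list(cft = tibble::as_tibble(cft),
                 apm = tibble::as_tibble(apm),
                 iq_sd = iq_sd),
            class = "norm_tables")
}

apm_range <- function(norms) range(norms$apm$raw)

cft_to_iq <- function(norms, cft_raw, age) {
  band <- norms$cft[norms$cft$age_lo <= age & age <= norms$cft$age_hi, ]
  if (nrow(band) == 0) {
    abort(sprintf("no CFT norm band covers age %.1f (bands: %s)", age,
                  paste(unique(sprintf("%g-%g", norms$cft$age_lo, norms$cft$age_hi)),
                        collapse = ", ")),
          class = "sleepspectra_validation_error")
  }
  assert_that(cft_raw >= min(band$cft_raw) && cft_raw <= max(band$cft_raw),
              sprintf("CFT raw %g outside norm coverage [%g, %g] for age %.1f",
                      cft_raw, min(band$cft_raw), max(band$cft_raw), age),
              class = "sleepspectra_validation_error")
  approx(band$cft_raw, band$iq, xout = cft_raw, ties = "ordered")$y
}

iq_to_percentile <- function(norms, iq) {
  100 * pnorm(iq, mean = 100, sd = norms$iq_sd)
}

apm_percentile_to_raw <- function(norms, percentile) {
  approx(norms$apm$percentile, norms$apm$raw, xout = percentile, rule = 2,
         ties = "min")$y
}

res_score <- function(subject_id, res, provenance) {
  tibble::tibble(subject_id = subject_id, res = res, provenance = provenance)
}

#' RES from a Raven APM raw score
#'
#' By definition the RES of an APM test is the raw score itself.
#'
#' @param raven_raw APM raw score.
#' @param norms Norm tables (used only to validate the score range).
#' @param subject_id Optional identifier carried through.
#' @return One-row tibble: `subject_id`, `res`, `provenance`.
#' @export
res_from_apm <- function(raven_raw, norms, subject_id = NA_character_) {
  rng <- apm_range(norms)
  assert_that(!is.na(raven_raw) && raven_raw >= rng[1] && raven_raw <= rng[2],
              sprintf("APM raw score %s outside table range [%g, %g]",
                      raven_raw, rng[1], rng[2]),
              class = "sleepspectra_validation_error")
  res_score(subject_id, as.numeric(raven_raw), "APM_only")
}

#' RES from a CFT raw score
#'
#' Chains the norm tables: CFT raw + age -> IQ -> normal percentile -> APM
#' raw score equivalent.
#'
#' @param cft_raw CFT raw score.
#' @param age Age in years (selects the CFT norm band).
#' @inheritParams res_from_apm
#' @return One-row tibble: `subject_id`, `res`, `provenance`.
#' @export
res_from_cft <- function(cft_raw, age, norms, subject_id = NA_character_) {
  iq <- cft_to_iq(norms, cft_raw, age)
  pct <- iq_to_percentile(norms, iq)
  res_score(subject_id, apm_percentile_to_raw(norms, pct), "CFT_only")
}

#' Composite RES from whichever scores are available
#'
#' With both an APM and a CFT score, the two RES values are averaged;
#' with one, that value is used; with neither, it is an error.
#'
#' @inheritParams res_from_cft
#' @param raven_raw APM raw score or `NA`.
#' @param cft_raw CFT raw score or `NA`.
#' @return One-row tibble: `subject_id`, `res`, `provenance`.
#' @export
res_composite <- function(raven_raw, cft_raw, age, norms,
                          subject_id = NA_character_) {
  has_apm <- !is.na(raven_raw)
  has_cft <- !is.na(cft_raw)
  assert_that(has_apm || has_cft,
              sprintf("subject %s has neither APM nor CFT score", subject_id),
              class = "sleepspectra_validation_error")
  if (has_apm && has_cft) {
    a <- res_from_apm(raven_raw, norms, subject_id)$res
    c_ <- res_from_cft(cft_raw, age, norms, subject_id)$res
    res_score(subject_id, (a + c_) / 2, "averaged")
  } else if (has_apm) {
    res_from_apm(raven_raw, norms, subject_id)
  } else {
    res_from_cft(cft_raw, age, norms, subject_id)
  }
}

#' Score a whole subject table
#'
#' @param subjects Subject tibble (see [read_subject_table()]).
#' @param norms Norm tables.
#' @return Tibble with one row per subject: `subject_id`, `res`,
#'   `provenance`.
#' @export
score_subjects <- function(subjects, norms) {
  purrr::pmap_dfr(
    subjects[c("subject_id", "raven_raw", "cft_raw", "age")],
    function(subject_id, raven_raw, cft_raw, age) {
      res_composite(raven_raw, cft_raw, age, norms, subject_id)
    }
  )
}
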