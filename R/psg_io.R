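# Plain-text dialects for scored sleep data and the long spectra table.

# Default token -> stage mapping for hypnogram files (one token per 20 s line).
default_stage_dialect <- function() {
  c(W = "WAKE", N1 = "NREM1", N2 = "NREM2", SWS = "SWS",
    REM = "REM", MT = "MOVEMENT")
}

#' Read a hypnogram file
#'
#' One stage token per line, one line per 20 s scoring epoch. The default
#' dialect understands `W`, `N1`, `N2`, `SWS`, `REM` and `MT`
#' (movement/unknown); foreign dialects are handled by passing a named
#' mapping from file token to canonical stage code.
#'
#' @param path Path to a plain-text hypnogram.
#' @param dialect Named character vector mapping file tokens to
#'   [stage_codes()] values.
#' @return A tibble with columns `epoch` (1-based) and `stage`.
#' @export
read_hypnogram <- function(path, dialect = default_stage_dialect()) {
  assert_that(all(dialect %in% stage_codes()),
              "dialect maps to unknown stage codes")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warn(sprintf("empty hypnogram: %s", path))
    return(tibble::tibble(epoch = integer(), stage = character()))
  }
  bad <- which(!(lines %in% names(dialect)))
  if (length(bad) > 0) {
    abort(sprintf("unknown stage token '%s' at line %d of %s",
                  lines[bad[1]], bad[1], path),
          class = "sleepspectra_parse_error")
  }
  tibble::tibble(epoch = seq_along(lines),
                 stage = unname(dialect[lines]))
}

#' Read an artifact mask file
#'
#' One `0`/`1` flag per line, one line per 4 s artifact-scoring segment
#' (five segments per 20 s epoch); `1` marks an artifact.
#'
#' @param path Path to a plain-text mask file.
#' @return A tibble with columns `segment` (1-based) and `artifact` (logical).
#' @export
read_artifact_mask <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  bad <- which(!(lines %in% c("0", "1")))
  if (length(bad) > 0) {
    abort(sprintf("artifact mask flag must be 0 or 1; got '%s' at line %d",
                  lines[bad[1]], bad[1]),
          class = "sleepspectra_parse_error")
  }
  tibble::tibble(segment = seq_along(lines), artifact = lines == "1")
}

#' Read and validate a subject table
#'
#' Expects a delimited file with header columns `subject_id`, `sex` (`F` or
#' `M`), `age` (years), `raven_raw`, `cft_raw` and `device_id`. Missing test
#' scores stay missing (`NA`), but every subject must have at least one of
#' the two.
#'
#' @param path Path to a CSV file.
#' @param age_range Plausible age bounds in years; ages outside are an error.
#' @return A validated tibble.
#' @export
read_subject_table <- function(path, age_range = c(10, 100)) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           sex = readr::col_character(),
                           age = readr::col_double(),
                           raven_raw = readr::col_double(),
                           cft_raw = readr::col_double(),
                           .default = readr::col_character()
                         ))
  validate_subjects(tbl, age_range = age_range)
}

#' @rdname read_subject_table
#' @param subjects A subject data frame to validate in place.
#' @export
validate_subjects <- function(subjects, age_range = c(10, 100)) {
  need <- c("subject_id", "sex", "age", "raven_raw", "cft_raw")
  missing_cols <- setdiff(need, names(subjects))
  assert_that(length(missing_cols) == 0,
              sprintf("subject table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              class = "sleepspectra_validation_error")
  if (!"device_id" %in% names(subjects)) subjects$device_id <- "unknown"
  dup <- subjects$subject_id[duplicated(subjects$subject_id)]
  assert_that(length(dup) == 0,
              sprintf("duplicate subject_id: %s", paste(unique(dup), collapse = ", ")),
              class = "sleepspectra_validation_error")
  bad_sex <- unique(subjects$sex[!subjects$sex %in% c("F", "M")])
  assert_that(length(bad_sex) == 0,
              sprintf("sex must be F or M; got: %s", paste(bad_sex, collapse = ", ")),
              class = "sleepspectra_validation_error")
  no_score <- subjects$subject_id[is.na(subjects$raven_raw) & is.na(subjects$cft_raw)]
  assert_that(length(no_score) == 0,
              sprintf("subject(s) with neither Raven APM nor CFT score: %s",
                      paste(no_score, collapse = ", ")),
              class = "sleepspectra_validation_error")
  bad_age <- subjects$subject_id[is.na(subjects$age) |
                                   subjects$age < age_range[1] |
                                   subjects$age > age_range[2]]
  assert_that(length(bad_age) == 0,
              sprintf("implausible or missing age for: %s",
                      paste(bad_age, collapse = ", ")),
              class = "sleepspectra_validation_error")
  tibble::as_tibble(subjects)
}

# ---- spectra table -----------------------------------------------------------

#' Validate a relative log-power spectra table
#'
#' The internal spectra container is a long tibble with columns `subject_id`,
#' `state` (`NREM`/`REM`), `electrode`, `bin_hz` and `value` (relative
#' log10 power). A missing electrode for a subject is represented by the
#' absence of its rows, never by imputed values. Every present
#' subject x state x electrode series must cover the full 157-bin grid and
#' its antilogs must sum to one (relative power normalization).
#'
#' @param spectra A long spectra data frame.
#' @param check_normalization Verify that `sum(10^value) == 1` within `tol`
#'   for every series.
#' @param tol Normalization tolerance.
#' @return The validated tibble (invisibly classed as before).
#' @export
validate_spectra <- function(spectra, check_normalization = TRUE, tol = 1e-9) {
  need <- c("subject_id", "state", "electrode", "bin_hz", "value")
  missing_cols <- setdiff(need, names(spectra))
  assert_that(length(missing_cols) == 0,
              sprintf("spectra table lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              class = "sleepspectra_format_error")
  assert_that(all(spectra$state %in% c("NREM", "REM")),
              "spectra state must be NREM or REM",
              class = "sleepspectra_format_error")
  grid <- freq_bins()
  by_series <- dplyr::summarise(
    dplyr::group_by(spectra, .data$subject_id, .data$state, .data$electrode),
    n_bins = dplyr::n(),
    grid_ok = isTRUE(all.equal(sort(.data$bin_hz), grid, tolerance = 1e-9)),
    antilog_sum = sum(10^.data$value),
    .groups = "drop"
  )
  bad_grid <- by_series[by_series$n_bins != length(grid) | !by_series$grid_ok, ]
  if (nrow(bad_grid) > 0) {
    abort(sprintf(
      "spectra series %s/%s/%s has %d bins; expected the 157-bin 1-40 Hz grid",
      bad_grid$subject_id[1], bad_grid$state[1], bad_grid$electrode[1],
      bad_grid$n_bins[1]
    ), class = "sleepspectra_format_error")
  }
  if (check_normalization) {
    bad_norm <- by_series[abs(by_series$antilog_sum - 1) > tol, ]
    if (nrow(bad_norm) > 0) {
      abort(sprintf(
        "spectra series %s/%s/%s antilogs sum to %.12f, not 1",
        bad_norm$subject_id[1], bad_norm$state[1], bad_norm$electrode[1],
        bad_norm$antilog_sum[1]
      ), class = "sleepspectra_format_error")
    }
  }
  tibble::as_tibble(spectra)
}

#' Write / read the long spectra table
#'
#' Lossless CSV round trip of the long-format spectra table (full double
#' precision). `read_spectra()` re-validates the bin grid on the way in, so a
#' file with a foreign grid fails loudly rather than flowing downstream.
#'
#' @param spectra A validated spectra tibble (see [validate_spectra()]).
#' @param path File path.
#' @inheritParams validate_spectra
#' @return `write_spectra()` returns `path` invisibly; `read_spectra()`
#'   returns the spectra tibble.
#' @export
write_spectra <- function(spectra, path, check_normalization = TRUE) {
  spectra <- validate_spectra(spectra, check_normalization = check_normalization)
  out <- spectra
  out$value <- sprintf("%.17g", out$value)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, check_normalization = TRUE) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           state = readr::col_character(),
                           electrode = readr::col_character(),
                           bin_hz = readr::col_double(),
                           value = readr::col_double()
                         ))
  validate_spectra(tbl, check_normalization = check_normalization)
}
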