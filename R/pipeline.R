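# End-to-end orchestration: correlate -> Rueger correction -> imputation ->
# permutation correction -> sexual-dimorphism tests, per sleep state.

#' Run the full spectra-to-report analysis
#'
#' For each requested sleep state: builds the per-sex age-partial
#' correlation maps, finds and decides Rueger areas, imputes the spectra
#' onto the 12-channel montage, runs the seeded max-statistic permutation
#' correction per sex, summarizes significant frequency ranges, and tests
#' sexual dimorphism with Fisher r-to-z at the maximal-association cell of
#' every area of potential significance.
#'
#' @param spectra Long spectra tibble (both states as available).
#' @param res RES tibble (`subject_id`, `res`).
#' @param subjects Subject tibble (`subject_id`, `sex`, `age`).
#' @param states,sexes Which slices to analyse.
#' @param n_perm Permutations for the max-statistic correction.
#' @param seed Integer seed for the permutation engine (required).
#' @param alpha Cell-level significance level.
#' @param family Permutation family (see [permutation_correct()]).
#' @param adjacency Neighbour table for [impute_channels()].
#' @return A `sleep_run_report` list: `corrmaps` (named list of
#'   `sleep_corrmap`s), `ruger` (tibble of areas with `state`/`sex`),
#'   `perm` (named list of `perm_result`s), `ranges` (tibble of significant
#'   frequency ranges), `dimorphism` (Fisher test table), and `config`.
#' @export
run_pipeline <- function(spectra, res, subjects, states = c("NREM", "REM"),
                         sexes = c("F", "M"), n_perm = 5000, seed = 1,
                         alpha = 0.05, family = c("bin", "grid"),
                         adjacency = default_adjacency()) {
  family <- match.arg(family)
  subjects <- validate_subjects(subjects, age_range = c(0, 200))
  states <- intersect(states, unique(spectra$state))
  assert_that(length(states) > 0, "spectra contain none of the requested states",
              class = "sleepspectra_validation_error")

  corrmaps <- list()
  perms <- list()
  ruger <- list()
  ranges <- list()
  dimorphism <- list()

  imputed <- impute_channels(spectra, adjacency = adjacency)

  for (st in states) {
    maps <- purrr::map(sexes, function(sx) {
      build_corrmap(spectra, res, subjects, sex = sx, state = st)
    })
    names(maps) <- sexes
    for (sx in sexes) {
      key <- paste(st, sx, sep = "_")
      corrmaps[[key]] <- maps[[sx]]
      areas <- find_ruger_areas(maps[[sx]], alpha = alpha)
      if (nrow(areas) > 0) {
        ruger[[key]] <- dplyr::mutate(tibble::as_tibble(areas), state = st,
                                      sex = sx, .before = 1)
      }
      pr <- permutation_correct(imputed, res, subjects, sex = sx, state = st,
                                n_perm = n_perm, family = family, seed = seed)
      perms[[key]] <- pr
      rg <- summarize_significant_ranges(pr, alpha = alpha)
      if (nrow(rg) > 0) {
        ranges[[key]] <- dplyr::mutate(rg, state = st, sex = sx, .before = 1)
      }
    }
    # dimorphism at the maximal cell of every area of potential significance
    if (all(c("F", "M") %in% sexes)) {
      cells <- purrr::map_dfr(sexes, function(sx) {
        a <- find_ruger_areas(maps[[sx]], alpha = alpha)
        if (nrow(a) == 0) return(NULL)
        tibble::tibble(electrode = a$max_electrode, bin_hz = a$max_bin_hz,
                       area_sex = sx)
      })
      if (nrow(cells) > 0) {
        cells <- dplyr::distinct(cells, .data$electrode, .data$bin_hz,
                                 .keep_all = TRUE)
        dt <- dimorphism_tests(maps$F, maps$M,
                               cells[c("electrode", "bin_hz")])
        dimorphism[[st]] <- dplyr::mutate(dt, state = st, .before = 1)
      }
    }
  }

  structure(
    list(
      corrmaps = corrmaps,
      ruger = dplyr::bind_rows(ruger),
      perm = perms,
      ranges = dplyr::bind_rows(ranges),
      dimorphism = dplyr::bind_rows(dimorphism),
      config = list(states = states, sexes = sexes, n_perm = n_perm,
                    seed = seed, alpha = alpha, family = family,
                    version = as.character(utils::packageVersion("sleepspectra")))
    ),
    class = "sleep_run_report"
  )
}

#' @export
print.sleep_run_report <- function(x, ...) {
  cat("<sleep_run_report>\n")
  cat(sprintf("  states: %s | sexes: %s | n_perm=%d seed=%s family=%s\n",
              paste(x$config$states, collapse = "+"),
              paste(x$config$sexes, collapse = "+"),
              x$config$n_perm, x$config$seed, x$config$family))
  if (nrow(x$ruger) > 0) {
    cat("  Rueger areas:\n")
    for (i in seq_len(nrow(x$ruger))) {
      a <- x$ruger[i, ]
      cat(sprintf(
        "    %s/%s %.2f-%.2f Hz: %d sig cells on %d electrodes, p<a/2 %.1f%%, p<a/3 %.1f%% -> %s (max |r| %.2f at %s %.2f Hz)\n",
        a$state, a$sex, a$first_hz, a$last_hz, a$n_sig, a$n_electrodes,
        100 * a$frac_half, 100 * a$frac_third,
        if (a$decision) "significant" else "not significant",
        a$max_r, a$max_electrode, a$max_bin_hz))
    }
  } else cat("  Rueger areas: none\n")
  if (nrow(x$ranges) > 0) {
    cat("  permutation-significant ranges:\n")
    for (i in seq_len(nrow(x$ranges))) {
      g <- x$ranges[i, ]
      cat(sprintf("    %s/%s %.2f-%.2f Hz (%s)\n", g$state, g$sex,
                  g$first_hz, g$last_hz,
                  paste(g$channels[[1]], collapse = ", ")))
    }
  } else cat("  permutation-significant ranges: none\n")
  if (nrow(x$dimorphism) > 0) {
    cat("  sexual-dimorphism tests (Fisher r-to-z):\n")
    for (i in seq_len(nrow(x$dimorphism))) {
      d <- x$dimorphism[i, ]
      cat(sprintf("    %s %s %.2f Hz: r_F=%.2f (n=%d) vs r_M=%.2f (n=%d), z=%.2f, p=%.4f\n",
                  d$state, d$electrode, d$bin_hz, d$r_female, d$n_female,
                  d$r_male, d$n_male, d$z, d$p))
    }
  }
  invisible(x)
}
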