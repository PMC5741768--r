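# Multiple-comparisons control over the electrode x frequency grid.
#
# Two procedures: (1) the Rueger-area method — contiguous frequency runs of
# nominally significant cells are declared globally significant when enough
# of their member tests survive stricter thresholds (alpha/2 for >= 50%,
# alpha/3 for >= 1/3); (2) a seeded max-statistic permutation test on
# age-residualized trait and spectra, which needs a complete spectra matrix
# and therefore a missing-channel imputation step.

#' Rueger-area decision rule
#'
#' An area of nominally significant tests is declared significant when at
#' least half of its member tests have `p < alpha/2` or at least a third
#' have `p < alpha/3`. The second threshold is the exact fraction
#' `alpha/3`, not its two-decimal rounding.
#'
#' @param frac_half Fraction of member cells with `p < alpha/2`.
#' @param frac_third Fraction of member cells with `p < alpha/3`.
#' @return Logical (vectorized): is the area significant?
#' @export
decide_ruger <- function(frac_half, frac_third) {
  assert_that(all(frac_half >= 0 & frac_half <= 1) &&
                all(frac_third >= 0 & frac_third <= 1),
              "fractions must lie in [0, 1]")
  frac_half >= 0.5 | frac_third >= 1 / 3
}

#' Find Rueger areas in a correlation map
#'
#' An area of potential significance is a maximal contiguous run of
#' frequency bins each containing at least one cell with `p < alpha` on any
#' electrode. Areas whose significant cells all sit on a single electrode,
#' or which span fewer than `min_bins` bins (< 1 Hz at 0.25 Hz resolution),
#' are discarded as likely narrow-band artifacts or outliers. Each retained
#' area carries its stricter-threshold fractions, the decision of
#' [decide_ruger()], and its maximal-association cell (largest |r|; ties
#' broken toward the lowest frequency, then montage order).
#'
#' The fractions are computed over *all* non-missing cells of the area
#' (every electrode at every bin of the run), not only the nominally
#' significant ones. This is what makes the decision rule a valid global
#' test: under the global null the expected count of cells with
#' `p < alpha/k` is `n_cells * alpha/k`, so by Markov's inequality the
#' probability that a fraction `1/k` of all cells passes is at most
#' `alpha`. Conditioning on nominal significance instead would make the
#' fractions pivotal (uniform p-values give `frac_half = 0.5` in
#' expectation regardless of any effect) and the rule would fire on pure
#' noise about half the time.
#'
#' @param corrmap A `sleep_corrmap` (or any tibble with `electrode`,
#'   `bin_hz`, `r`, `p`).
#' @param alpha Nominal cell-level significance level.
#' @param min_bins Minimum area width in bins.
#' @return A `ruger_areas` tibble, one row per retained area: `first_hz`,
#'   `last_hz`, `n_bins`, `n_cells` (all non-missing cells in the area),
#'   `n_sig` (nominally significant cells), `frac_half`, `frac_third`,
#'   `n_electrodes` (with a significant cell), `decision`,
#'   `max_electrode`, `max_bin_hz`, `max_r`, and a list-column `cells` of
#'   the significant member cells. Zero rows when nothing is significant.
#' @export
find_ruger_areas <- function(corrmap, alpha = 0.05, min_bins = 4) {
  # plain vectors: this runs inside tight simulation loops
  keep <- !is.na(corrmap$p)
  p <- corrmap$p[keep]
  bin <- corrmap$bin_hz[keep]
  elec <- corrmap$electrode[keep]
  r <- corrmap$r[keep]
  grid <- sort(unique(corrmap$bin_hz))

  empty <- tibble::tibble(
    first_hz = numeric(), last_hz = numeric(), n_bins = integer(),
    n_cells = integer(), n_sig = integer(),
    frac_half = numeric(), frac_third = numeric(),
    n_electrodes = integer(), decision = logical(),
    max_electrode = character(), max_bin_hz = numeric(), max_r = numeric(),
    cells = list()
  )
  is_sig <- p < alpha
  if (!any(is_sig)) return(new_ruger_areas(empty, alpha))

  bin_idx <- match(bin, grid)
  sig_bin_idx <- sort(unique(bin_idx[is_sig]))
  run_id <- cumsum(c(1, diff(sig_bin_idx) != 1))
  rows <- vector("list", max(run_id))
  for (k in seq_len(max(run_id))) {
    idx <- sig_bin_idx[run_id == k]
    in_area <- bin_idx >= idx[1] & bin_idx <= idx[length(idx)]
    cell_sig <- in_area & is_sig
    electrodes <- unique(elec[cell_sig])
    if (length(idx) < min_bins || length(electrodes) < 2) next
    # maximal association: largest |r|, ties to lowest frequency then montage
    w <- which(cell_sig)
    ord <- w[order(-abs(r[w]), bin[w], match(elec[w], montage_1020()))][1]
    frac_half <- mean(p[in_area] < alpha / 2)
    frac_third <- mean(p[in_area] < alpha / 3)
    rows[[k]] <- tibble::tibble(
      first_hz = grid[idx[1]], last_hz = grid[idx[length(idx)]],
      n_bins = length(idx), n_cells = sum(in_area), n_sig = sum(cell_sig),
      frac_half = frac_half, frac_third = frac_third,
      n_electrodes = length(electrodes),
      decision = decide_ruger(frac_half, frac_third),
      max_electrode = elec[ord], max_bin_hz = bin[ord], max_r = r[ord],
      cells = list(tibble::tibble(electrode = elec[cell_sig],
                                  bin_hz = bin[cell_sig],
                                  r = r[cell_sig], p = p[cell_sig]))
    )
  }
  areas <- dplyr::bind_rows(rows)
  if (nrow(areas) == 0) areas <- empty
  new_ruger_areas(areas, alpha)
}

new_ruger_areas <- function(tbl, alpha) {
  attr(tbl, "alpha") <- alpha
  class(tbl) <- c("ruger_areas", class(tbl))
  tbl
}

# ---- channel imputation ------------------------------------------------------

#' Default 10-20 neighbour table for channel imputation
#'
#' Editable adjacency shipped as a CSV resource (`channel`, `neighbor`) over
#' the 12-channel montage. Midline rules fall out of the table: Fz's
#' neighbours are F3/F4 and Cz's are C3/C4.
#'
#' @return Tibble with columns `channel` and `neighbor`.
#' @export
default_adjacency <- function() {
  readr::read_csv(system.file("extdata", "neighbors_1020.csv",
                              package = "sleepspectra"),
                  show_col_types = FALSE)
}

#' Impute missing channels onto the 12-channel montage
#'
#' Restricts spectra to the 12 non-temporal channels (Fp1, Fp2, F3, F4, Fz,
#' C3, C4, Cz, P3, P4, O1, O2) and fills each subject's missing channels
#' with the bin-wise average of its available neighbours on the relative
#' log-power scale: a missing Fz becomes the mean of F3 and F4, a missing
#' Cz the mean of C3 and C4, and any other missing channel the mean of its
#' configured neighbours that were actually recorded. The temporal arc (F7,
#' F8, T3, T4, T5, T6) is dropped, not imputed, because those channels have
#' neighbours on one side only.
#'
#' @param spectra Long spectra tibble.
#' @param adjacency Neighbour table (see [default_adjacency()]).
#' @param target Channels of the output montage.
#' @return Long spectra tibble on the target montage, complete for every
#'   subject x state. Imputed series are means of log-power values, so
#'   their antilogs need not sum to exactly 1.
#' @export
impute_channels <- function(spectra, adjacency = default_adjacency(),
                            target = montage_12ch()) {
  sp <- spectra[spectra$electrode %in% target, ]
  nb <- split(adjacency$neighbor, adjacency$channel)
  grid <- freq_bins()

  filled <- sp |>
    dplyr::group_by(.data$subject_id, .data$state) |>
    dplyr::group_map(function(g, key) {
      present <- unique(g$electrode)
      missing <- setdiff(target, present)
      if (length(missing) == 0) return(dplyr::bind_cols(key, g))
      wide <- tidyr::pivot_wider(g, id_cols = "electrode",
                                 names_from = "bin_hz", values_from = "value")
      M <- as.matrix(wide[, -1])
      rownames(M) <- wide$electrode
      imput <- purrr::map_dfr(missing, function(ch) {
        donors <- intersect(nb[[ch]] %||% character(), present)
        if (length(donors) == 0) {
          abort(sprintf(
            "subject %s (%s): channel %s has no available neighbour to impute from",
            key$subject_id, key$state, ch
          ), class = "sleepspectra_validation_error")
        }
        tibble::tibble(electrode = ch, bin_hz = grid,
                       value = unname(colMeans(M[donors, , drop = FALSE])))
      })
      dplyr::bind_cols(key, dplyr::bind_rows(g, imput))
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(filled, .data$subject_id, .data$state,
                 match(.data$electrode, target), .data$bin_hz)
}

# ---- permutation max-statistic correction ------------------------------------

#' Permutation max-statistic family-wise error correction
#'
#' Age-residualizes the trait and every spectra cell (per
#' [residualize()]), then permutes subject labels of the trait residuals
#' `n_perm` times, re-residualizing the permuted values on age
#' (Freedman-Lane) so the permuted statistics share the observed
#' statistic's degrees-of-freedom structure. Each permutation records,
#' within each test family, the
#' maximum |r| over all cells of the family; the corrected p-value of a
#' cell is `(1 + #(family max >= |r_obs|)) / (n_perm + 1)`. The default
#' family is all electrodes within each frequency bin; `family = "grid"`
#' takes the maximum over the whole electrode x bin grid (a larger family,
#' hence a stricter correction).
#'
#' @param spectra Complete long spectra tibble on a fixed montage (impute
#'   first with [impute_channels()]); any missing subject x electrode is an
#'   error.
#' @param res RES tibble (`subject_id`, `res`).
#' @param subjects Subject tibble (`subject_id`, `sex`, `age`).
#' @param sex,state Cohort slice to analyse.
#' @param n_perm Number of permutations (values below 100 warn).
#' @param family `"bin"` (electrodes within each frequency bin) or
#'   `"grid"`.
#' @param seed Integer seed; required for reproducible corrected p-values
#'   (`NULL` warns).
#' @return A `perm_result` object; [generics::tidy()] extracts the cell
#'   table (`electrode`, `bin_hz`, `r`, `p_uncorrected`, `p_corrected`).
#' @export
permutation_correct <- function(spectra, res, subjects, sex = c("F", "M"),
                                state = c("NREM", "REM"), n_perm = 5000,
                                family = c("bin", "grid"), seed = NULL) {
  sex <- match.arg(sex)
  state <- match.arg(state)
  family <- match.arg(family)
  if (n_perm < 100) warn("n_perm < 100 gives a very coarse p-value grid")
  if (is.null(seed)) {
    warn("no seed supplied; corrected p-values will not be reproducible")
  } else {
    set.seed(seed)
  }

  subs <- subjects[subjects$sex == sex, c("subject_id", "age")]
  subs <- dplyr::inner_join(subs, res[c("subject_id", "res")], by = "subject_id")
  sp <- spectra[spectra$state == state & spectra$subject_id %in% subs$subject_id, ]
  assert_that(nrow(sp) > 0, sprintf("no %s spectra for sex %s", state, sex),
              class = "sleepspectra_validation_error")
  electrodes <- sort(unique(sp$electrode))
  grid <- sort(unique(sp$bin_hz))
  counts <- dplyr::count(sp, .data$subject_id)
  complete_n <- length(electrodes) * length(grid)
  bad <- counts$subject_id[counts$n != complete_n]
  assert_that(length(bad) == 0,
              sprintf("incomplete spectra (impute channels first) for: %s",
                      paste(head(bad, 5), collapse = ", ")),
              class = "sleepspectra_validation_error")

  # subjects x cells matrix, cells ordered electrode-fastest within bin so
  # per-bin families are contiguous blocks of rows in the cells x perms array
  ids <- sort(unique(sp$subject_id))
  n <- length(ids)
  sp <- dplyr::arrange(sp, .data$bin_hz, match(.data$electrode, electrodes),
                       match(.data$subject_id, ids))
  X <- matrix(sp$value, nrow = n)   # rows: subjects; cols: cells (el-fastest)
  cell_key <- dplyr::distinct(sp, .data$bin_hz, .data$electrode)
  meta <- subs[match(ids, subs$subject_id), ]

  XR <- residualize(X, meta$age)
  yr <- residualize(meta$res, meta$age)
  ssx <- sqrt(colSums(XR^2))
  ssy <- sqrt(sum(yr^2))
  r_obs <- as.vector(crossprod(yr, XR)) / (ssx * ssy)

  # Freedman-Lane: permute the trait residuals, then re-residualize on age so
  # permuted statistics carry the same degrees-of-freedom structure as the
  # observed one (without this the permutation null is slightly too narrow
  # and the corrected test runs anticonservative)
  P <- vapply(seq_len(n_perm), function(i) yr[sample.int(n)], numeric(n))
  P <- residualize(P, meta$age)
  ssy_perm <- sqrt(colSums(P^2))
  R <- abs(crossprod(XR, P)) / outer(ssx, ssy_perm)   # cells x n_perm of |r|

  e <- length(electrodes)
  nb <- length(grid)
  if (family == "bin") {
    fam_max <- R[seq(1, e * nb, by = e), , drop = FALSE]
    if (e > 1) {
      for (j in 2:e) {
        fam_max <- pmax(fam_max, R[seq(j, e * nb, by = e), , drop = FALSE])
      }
    }
    p_corr <- numeric(e * nb)
    for (b in seq_len(nb)) {
      rows <- (b - 1) * e + seq_len(e)
      mx <- fam_max[b, ]
      p_corr[rows] <- vapply(abs(r_obs[rows]),
                             function(v) (1 + sum(mx >= v)) / (n_perm + 1),
                             numeric(1))
    }
  } else {
    mx <- apply(R, 2, max)
    p_corr <- vapply(abs(r_obs),
                     function(v) (1 + sum(mx >= v)) / (n_perm + 1),
                     numeric(1))
  }

  tbl <- tibble::tibble(
    electrode = cell_key$electrode, bin_hz = cell_key$bin_hz,
    r = r_obs, p_uncorrected = partial_corr_p(r_obs, n),
    p_corrected = p_corr
  )
  structure(
    list(table = tbl, n = n, n_perm = n_perm, family = family,
         seed = seed, sex = sex, state = state),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "<perm_result> %s/%s: n=%d subjects, %d cells, %d permutations, family=%s\n",
    x$state, x$sex, x$n, nrow(x$table), x$n_perm, x$family
  ))
  cat(sprintf("cells with corrected p < 0.05: %d\n",
              sum(x$table$p_corrected < 0.05)))
  invisible(x)
}

#' Report contiguous significant frequency ranges
#'
#' Summarizes a permutation result as the contiguous series of frequency
#' bins in which the corrected association is significant for at least one
#' channel; a channel is listed for a range when it has at least one
#' significant corrected cell inside it. Ranges whose significant cells sit
#' on a single channel are dropped.
#'
#' @param permresult A `perm_result`.
#' @param alpha Corrected significance level.
#' @return Tibble: `first_hz`, `last_hz`, `n_bins`, `n_channels`,
#'   `channels` (list-column of channel labels).
#' @export
summarize_significant_ranges <- function(permresult, alpha = 0.05) {
  stopifnot(inherits(permresult, "perm_result"))
  tbl <- permresult$table
  grid <- sort(unique(tbl$bin_hz))
  sig <- tbl[tbl$p_corrected < alpha, ]
  empty <- tibble::tibble(first_hz = numeric(), last_hz = numeric(),
                          n_bins = integer(), n_channels = integer(),
                          channels = list())
  if (nrow(sig) == 0) return(empty)
  idx <- sort(unique(match(sig$bin_hz, grid)))
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  out <- purrr::map_dfr(runs, function(ix) {
    bins <- grid[ix]
    chans <- sort(unique(sig$electrode[sig$bin_hz %in% bins]))
    if (length(chans) < 2) return(NULL)
    tibble::tibble(first_hz = min(bins), last_hz = max(bins),
                   n_bins = length(ix), n_channels = length(chans),
                   channels = list(chans))
  })
  if (nrow(out) == 0) empty else out
}
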