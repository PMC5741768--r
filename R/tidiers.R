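# broom-style accessors for the fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a correlation map
#' @param x A `sleep_corrmap`.
#' @param ... Unused.
#' @return The underlying tibble (one row per electrode x bin cell).
#' @export
tidy.sleep_corrmap <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sleep_corrmap")
  tibble::as_tibble(out)
}

#' @rdname tidy.sleep_corrmap
#' @export
glance.sleep_corrmap <- function(x, ...) {
  tibble::tibble(
    state = x$state[1], sex = x$sex[1],
    n_electrodes = dplyr::n_distinct(x$electrode),
    n_bins = dplyr::n_distinct(x$bin_hz),
    n_missing_cells = sum(is.na(x$r)),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    frac_sig_05 = mean(x$p < 0.05, na.rm = TRUE)
  )
}

#' Tidy Rueger areas
#' @param x A `ruger_areas` tibble.
#' @param ... Unused.
#' @return Member cells unnested: one row per significant cell with its
#'   area's bounds and decision.
#' @export
tidy.ruger_areas <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(first_hz = numeric(), last_hz = numeric(),
                          decision = logical(), electrode = character(),
                          bin_hz = numeric(), r = numeric(), p = numeric()))
  }
  tibble::as_tibble(x)[c("first_hz", "last_hz", "decision", "cells")] |>
    tidyr::unnest("cells")
}

#' @rdname tidy.ruger_areas
#' @export
glance.ruger_areas <- function(x, ...) {
  tibble::tibble(
    n_areas = nrow(x),
    n_significant = sum(x$decision),
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' Tidy a permutation result
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return The per-cell table: `electrode`, `bin_hz`, `r`, `p_uncorrected`,
#'   `p_corrected`.
#' @export
tidy.perm_result <- function(x, ...) {
  x$table
}

#' @rdname tidy.perm_result
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(
    state = x$state, sex = x$sex, n = x$n, n_perm = x$n_perm,
    family = x$family, seed = x$seed %||% NA_integer_,
    n_cells = nrow(x$table),
    n_sig_corrected = sum(x$table$p_corrected < 0.05),
    min_p_corrected = min(x$table$p_corrected)
  )
}
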