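# ggplot2 displays for the result types.

#' Spectro-correlogram
#'
#' Per-electrode curves of the age-partial correlation between trait and
#' relative power across frequency, with horizontal reference lines at the
#' critical correlation for that electrode's sample size (two-tailed
#' p = 0.05), drawn only for electrodes showing at least one nominally
#' significant bin. All-missing electrodes are omitted with a message.
#'
#' @param corrmap A `sleep_corrmap`.
#' @param alpha Level for the critical-r reference line.
#' @return A ggplot object faceted by electrode.
#' @export
plot_spectrocorrelogram <- function(corrmap, alpha = 0.05) {
  tbl <- tibble::as_tibble(corrmap)
  all_missing <- tbl |>
    dplyr::group_by(.data$electrode) |>
    dplyr::summarise(gone = all(is.na(.data$r)), .groups = "drop")
  if (any(all_missing$gone)) {
    message("omitting all-missing electrode(s): ",
            paste(all_missing$electrode[all_missing$gone], collapse = ", "))
    tbl <- tbl[!tbl$electrode %in% all_missing$electrode[all_missing$gone], ]
  }
  tbl$electrode <- factor(tbl$electrode,
                          levels = intersect(montage_1020(),
                                             unique(tbl$electrode)))
  crit <- tbl |>
    dplyr::group_by(.data$electrode) |>
    dplyr::summarise(n = .data$n[1],
                     any_sig = any(.data$p < alpha, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(r_crit = critical_r(.data$n, alpha)) |>
    dplyr::filter(.data$any_sig)

  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$bin_hz, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_hline(data = crit,
                        ggplot2::aes(yintercept = .data$r_crit),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(data = crit,
                        ggplot2::aes(yintercept = -.data$r_crit),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(ggplot2::vars(.data$electrode)) +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Age-partial Pearson r",
      title = sprintf("%s spectro-correlogram (%s)",
                      tbl$state[1] %||% "", tbl$sex[1] %||% ""),
      subtitle = sprintf("dashed: critical |r| at two-tailed p = %g", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_spectrocorrelogram
#' @param object,... Passed through (autoplot interface).
#' @export
autoplot.sleep_corrmap <- function(object, ..., alpha = 0.05) {
  plot_spectrocorrelogram(object, alpha = alpha)
}

#' Corrected p-value map of a permutation result
#'
#' Tile map of -log10 corrected p over the electrode x frequency grid, with
#' significant cells outlined.
#'
#' @param object A `perm_result`.
#' @param alpha Corrected significance level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_result <- function(object, ..., alpha = 0.05) {
  tbl <- object$table
  tbl$electrode <- factor(tbl$electrode,
                          levels = rev(intersect(montage_1020(),
                                                 unique(tbl$electrode))))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$bin_hz, y = .data$electrode,
                                    fill = -log10(.data$p_corrected))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tbl[tbl$p_corrected < alpha, ],
                        shape = 20, size = 0.4, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] * p[corr])) +
    ggplot2::labs(x = "Frequency (Hz)", y = NULL,
                  title = sprintf("%s/%s permutation-corrected p (family = %s, %d perms)",
                                  object$state, object$sex, object$family,
                                  object$n_perm)) +
    ggplot2::theme_minimal()
}
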