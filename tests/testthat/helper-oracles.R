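# Independent brute-force oracles and small fixture builders shared across
# test files. These deliberately re-derive results from first principles and
# never call the code paths they are used to check.

# --- window enumeration oracle ------------------------------------------------
# A 4 s window starting at s (a multiple of 2 s) is valid iff it lies inside
# one epoch, that epoch has a wanted stage, and every 4 s artifact segment it
# overlaps is clean. Enumerates every candidate start directly.
oracle_windows <- function(hypnogram, mask, state) {
  wanted <- if (state == "NREM") c("NREM2", "SWS") else "REM"
  total_s <- nrow(hypnogram) * 20
  starts <- seq(0, total_s - 4, by = 2)
  keep <- vapply(starts, function(s) {
    ep <- floor(s / 20) + 1
    ep_end <- floor((s + 4 - 0.001) / 20) + 1
    if (ep != ep_end) return(FALSE)                  # crosses epoch boundary
    if (!(hypnogram$stage[ep] %in% wanted)) return(FALSE)
    segs <- unique(c(floor(s / 4), floor((s + 4 - 0.001) / 4))) + 1
    all(!mask$artifact[segs])
  }, logical(1))
  sort(starts[keep])
}

# --- Rueger area oracle -------------------------------------------------------
# Direct scan re-implementation of the area rules: contiguous bins with any
# p < alpha cell; discard areas with < min_bins bins or significant cells on
# a single electrode; fractions over all non-missing cells of the area.
oracle_ruger <- function(corrmap, alpha = 0.05, min_bins = 4) {
  grid <- sort(unique(corrmap$bin_hz))
  sig_bin <- vapply(grid, function(b) {
    any(corrmap$p[corrmap$bin_hz == b] < alpha, na.rm = TRUE)
  }, logical(1))
  out <- list()
  b <- 1
  while (b <= length(grid)) {
    if (!sig_bin[b]) { b <- b + 1; next }
    e <- b
    while (e < length(grid) && sig_bin[e + 1]) e <- e + 1
    bins <- grid[b:e]
    inarea <- corrmap[corrmap$bin_hz %in% bins & !is.na(corrmap$p), ]
    sigcells <- inarea[inarea$p < alpha, ]
    if (length(bins) >= min_bins && length(unique(sigcells$electrode)) >= 2) {
      out[[length(out) + 1]] <- list(
        first_hz = min(bins), last_hz = max(bins),
        n_sig = nrow(sigcells),
        frac_half = mean(inarea$p < alpha / 2),
        frac_third = mean(inarea$p < alpha / 3),
        decision = mean(inarea$p < alpha / 2) >= 0.5 ||
          mean(inarea$p < alpha / 3) >= 1 / 3
      )
    }
    b <- e + 1
  }
  out
}

# corrmap-shaped tibble from a logical significance pattern (electrodes x
# bins); significant cells get p-values cycling through fixed sub-thresholds
# so the fraction rules are exercised too.
pattern_corrmap <- function(sig, bins_hz = NULL) {
  ne <- nrow(sig); nb <- ncol(sig)
  bins_hz <- bins_hz %||% seq(1, by = 0.25, length.out = nb)
  p <- matrix(0.5, ne, nb)
  subp <- c(0.001, 0.02, 0.03, 0.045)
  idx <- which(sig)
  p[idx] <- subp[(seq_along(idx) - 1) %% length(subp) + 1]
  # base data.frame: this builder runs tens of thousands of times
  data.frame(
    electrode = rep(montage_1020()[seq_len(ne)], times = nb),
    bin_hz = rep(bins_hz, each = ne),
    r = as.vector(ifelse(sig, 0.5, 0.05)) *
      rep_len(c(1, -1), ne * nb),
    p = as.vector(p)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small, fast cohort spec for statistical tests (null unless effects given)
tiny_spec <- function(effects = NULL, n_female = 20, n_male = 20,
                      missing_pattern = NULL, ...) {
  cohort_spec(
    n_female = n_female, n_male = n_male,
    electrodes = c("F3", "F4", "C3", "C4", "O1", "O2"),
    states = "REM", missing_pattern = missing_pattern, effects = effects, ...
  )
}

# norms with an APM range that includes 0, for range-edge tests
toy_norms <- function() {
  new_norm_tables(
    cft = tibble::tibble(cft_raw = c(10, 30, 50), age_lo = 15, age_hi = 70,
                         iq = c(70, 100, 130)),
    apm = tibble::tibble(percentile = c(1, 25, 50, 75, 99),
                         raw = c(0, 14, 21, 27, 36))
  )
}

# pattern-vs-oracle comparison used by both the unit and acceptance suites
check_vs_oracle <- function(sig, label) {
  cm <- pattern_corrmap(sig)
  got <- find_ruger_areas(cm)
  orc <- oracle_ruger(cm)
  if (nrow(got) != length(orc)) return(sprintf("%s: area count", label))
  if (nrow(got) > 0) {
    ok <- all(got$first_hz == vapply(orc, `[[`, numeric(1), "first_hz")) &&
      all(got$last_hz == vapply(orc, `[[`, numeric(1), "last_hz")) &&
      all(got$n_sig == vapply(orc, `[[`, numeric(1), "n_sig")) &&
      all(abs(got$frac_half - vapply(orc, `[[`, numeric(1), "frac_half")) < 1e-12) &&
      all(abs(got$frac_third - vapply(orc, `[[`, numeric(1), "frac_third")) < 1e-12) &&
      all(got$decision == vapply(orc, `[[`, logical(1), "decision"))
    if (!ok) return(sprintf("%s: area contents", label))
  }
  NULL
}

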