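#' Pairwise Granger causality tests for a field-potential dataset
#'
#' For every (session, condition) cell and every source-target channel pair
#' (by default all MPFC-to-LH pairs), extracts the post-stimulus analysis
#' window, screens outlier trials (3-MAD rule on the mean LFP), selects the
#' model order by AIC, fits the pair VAR, runs the diagnostics, and computes
#' the time-domain Granger F-test and the spectral Granger causality.
#' Pairs failing a diagnostic are excluded (flagged, not tested).
#' Benjamini-Hochberg FDR is applied per (session, condition) family.
#'
#' @param lfp An `lfp_data` object.
#' @param window_ms Analysis window, ms after stimulus onset (inclusive).
#'   Default `c(1, 250)`.
#' @param max_order AIC search bound, samples. Default 20.
#' @param freqs Spectral grid, Hz. Default [gc_frequency_grid()].
#' @param direction `"forward"` (MPFC to LH) or `"reverse"`.
#' @param q FDR level. Default 0.05.
#' @param lh_mask Optional logical mask over LH channels (electrode contacts
#'   verified to lie inside the nucleus); default all.
#' @return A `gc_result`: list with `pairs` (tibble: session, condition,
#'   source, target, order, gc, f_stat, p_value, fdr_pass, diagnostics) and
#'   `spectra` (tibble: one row per pair x frequency with `gc` and
#'   `sig_at_freq`). A pair is counted significant at a frequency when it
#'   passes FDR and its spectral GC at that frequency exceeds the median of
#'   its own spectrum.
#' @export
granger_pair_tests <- function(lfp, window_ms = c(1, 250), max_order = 20,
                               freqs = gc_frequency_grid(),
                               direction = c("forward", "reverse"),
                               q = 0.05, lh_mask = NULL) {
  stopifnot(inherits(lfp, "lfp_data"))
  direction <- match.arg(direction)
  mpfc <- which(lfp$areas == "MPFC")
  lh <- which(lfp$areas == "LH")
  if (!is.null(lh_mask)) lh <- lh[lh_mask]
  pairs <- expand.grid(src = mpfc, tgt = lh)
  if (direction == "reverse") pairs <- setNames(rev(pairs), c("src", "tgt"))
  key <- unique(lfp$trials[c("session", "condition")])
  win_idx <- which(lfp$time * 1000 >= window_ms[1] &
                     lfp$time * 1000 <= window_ms[2])
  pair_rows <- list()
  spec_rows <- list()
  for (r in seq_len(nrow(key))) {
    sel <- lfp$trials$session == key$session[r] &
      lfp$trials$condition == key$condition[r]
    sub <- lfp_subset(lfp, sel)
    keep <- lfp_trial_filter(sub)
    w <- sub$lfp[keep, , win_idx, drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      src <- pairs$src[k]
      tgt <- pairs$tgt[k]
      xw <- w[, c(src, tgt), , drop = FALSE]
      ord <- select_order(xw, max_order)$order
      model <- fit_mvar(xw, ord)
      diag_flags <- run_diagnostics(xw, model)
      row <- tibble(
        session = key$session[r], condition = key$condition[r],
        source = src, target = tgt, order = ord,
        collinear = diag_flags$collinear,
        nonstationary = diag_flags$nonstationary,
        heteroscedastic = diag_flags$heteroscedastic,
        ok = diag_flags$ok,
        gc = NA_real_, f_stat = NA_real_, p_value = NA_real_,
        n_trials = sum(keep)
      )
      if (diag_flags$ok) {
        tt <- time_gc_test(xw, source = 1, target = 2, order = ord)
        row$gc <- tt$gc
        row$f_stat <- tt$f_stat
        row$p_value <- tt$p_value
        sp <- spectral_gc(model, source = 1, target = 2, freqs = freqs,
                          fs = lfp$fs)
        spec_rows[[length(spec_rows) + 1]] <- dplyr::mutate(
          sp,
          session = key$session[r], condition = key$condition[r],
          source = src, target = tgt
        )
      }
      pair_rows[[length(pair_rows) + 1]] <- row
    }
  }
  pair_tab <- dplyr::bind_rows(pair_rows)
  pair_tab <- dplyr::group_by(pair_tab, .data$session, .data$condition)
  pair_tab <- dplyr::mutate(
    pair_tab,
    fdr_pass = {
      m <- rep(FALSE, dplyr::n())
      tested <- !is.na(.data$p_value)
      if (any(tested)) m[tested] <- fdr_bh(.data$p_value[tested], q)
      m
    }
  )
  pair_tab <- dplyr::ungroup(pair_tab)
  spectra <- dplyr::bind_rows(spec_rows)
  if (nrow(spectra) > 0) {
    spectra <- dplyr::group_by(spectra, .data$session, .data$condition,
                               .data$source, .data$target)
    spectra <- dplyr::mutate(spectra, above_median = .data$gc >
                               median(.data$gc, na.rm = TRUE))
    spectra <- dplyr::ungroup(spectra)
    spectra <- dplyr::left_join(
      spectra,
      pair_tab[c("session", "condition", "source", "target", "fdr_pass")],
      by = c("session", "condition", "source", "target")
    )
    spectra <- dplyr::mutate(
      spectra, sig_at_freq = .data$fdr_pass & .data$above_median
    )
  }
  structure(
    list(pairs = pair_tab, spectra = spectra, freqs = freqs,
         direction = direction, window_ms = window_ms, q = q),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf(
    "<gc_result> %s direction, %d pair fits (%d FDR-significant)\n",
    x$direction, nrow(x$pairs), sum(x$pairs$fdr_pass, na.rm = TRUE)
  ))
  invisible(x)
}

#' Tidy pairwise Granger results
#'
#' @param x A `gc_result`.
#' @param ... Unused.
#' @return The pair-level test table.
#' @export
tidy.gc_result <- function(x, ...) x$pairs

#' Session-level summary and paired tests of Granger causality
#'
#' Per (session, condition, frequency), the proportion of tested channel
#' pairs significant at that frequency; then, per frequency, a one-sided
#' paired t-test across sessions of whether the proportion is lower under
#' the drug condition than under control, and the mean spectral GC
#' difference (drug minus control) with the analogous one-sided paired
#' t-test.
#'
#' @param result A `gc_result` covering both conditions and >= 2 sessions.
#' @param conditions Length-2 character vector, control first.
#' @return A `gc_session_summary`: list of `proportions` (tibble per
#'   session/condition/freq) and `freq_tests` (tibble per freq:
#'   `prop_control`, `prop_drug`, `p_prop`, `gc_diff`, `p_gc`).
#' @export
session_gc_summary <- function(result, conditions = c("vehicle", "DCZ")) {
  stopifnot(inherits(result, "gc_result"))
  sp <- result$spectra
  if (is.null(sp) || nrow(sp) == 0) abort("No tested pairs to summarise.")
  n_sessions <- length(unique(sp$session))
  if (n_sessions < 2) abort("Need >= 2 sessions for the paired test.")
  props <- dplyr::summarise(
    dplyr::group_by(sp, .data$session, .data$condition, .data$freq),
    prop = mean(.data$sig_at_freq), mean_gc = mean(.data$gc),
    n_pairs = dplyr::n(), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    props,
    id_cols = c("session", "freq"),
    names_from = "condition", values_from = c("prop", "mean_gc")
  )
  pc <- paste0("prop_", conditions[1])
  pd <- paste0("prop_", conditions[2])
  gc_c <- paste0("mean_gc_", conditions[1])
  gc_d <- paste0("mean_gc_", conditions[2])
  freq_tests <- dplyr::summarise(
    dplyr::group_by(wide, .data$freq),
    prop_control = mean(.data[[pc]]),
    prop_drug = mean(.data[[pd]]),
    p_prop = paired_one_sided_p(.data[[pd]], .data[[pc]]),
    gc_diff = mean(.data[[gc_d]] - .data[[gc_c]]),
    p_gc = paired_one_sided_p(.data[[gc_d]], .data[[gc_c]]),
    n_sessions = dplyr::n(),
    .groups = "drop"
  )
  structure(
    list(proportions = props, freq_tests = freq_tests,
         conditions = conditions),
    class = "gc_session_summary"
  )
}

# One-sided paired t-test p-value for mean(drug - control) < 0; returns NA
# when the differences are degenerate (zero variance).
paired_one_sided_p <- function(drug, control) {
  d <- drug - control
  if (length(d) < 2 || sd(d) == 0) return(NA_real_)
  t.test(d, alternative = "less")$p.value
}

#' @export
print.gc_session_summary <- function(x, ...) {
  sig <- sum(x$freq_tests$p_prop < 0.05, na.rm = TRUE)
  cat(sprintf(
    "<gc_session_summary> %d frequencies, %d with significantly lower proportion under %s\n",
    nrow(x$freq_tests), sig, x$conditions[2]
  ))
  invisible(x)
}

#' @export
tidy.gc_session_summary <- function(x, ...) x$freq_tests

#' Plot session-level Granger proportions by condition
#'
#' Mean proportion of significant pairs per frequency and condition
#' (logarithmic frequency axis), with frequencies whose one-sided paired
#' test falls below 0.05 marked.
#'
#' @param object A `gc_session_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_session_summary <- function(object, ...) {
  ft <- object$freq_tests
  df <- tidyr::pivot_longer(
    ft[c("freq", "prop_control", "prop_drug")],
    cols = c("prop_control", "prop_drug"),
    names_to = "condition", values_to = "prop"
  )
  sig <- ft[!is.na(ft$p_prop) & ft$p_prop < 0.05, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$prop,
                                        colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = "proportion of significant pairs")
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_point(
      data = sig, ggplot2::aes(x = .data$freq, y = pmax(.data$prop_control,
                                                        .data$prop_drug)),
      inherit.aes = FALSE, colour = "red", shape = 1
    )
  }
  p + ggplot2::scale_x_continuous(
    trans = "log1p", breaks = c(0, 2, 4, 8, 16, 32, 64, 128)
  )
}
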