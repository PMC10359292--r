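#' Detect lick events by threshold crossing
#'
#' A lick is an upward crossing of `threshold` (previous sample below, current
#' sample at or above), subject to a refractory period that suppresses
#' crossings caused by sensor ripple.
#'
#' @param trace Numeric lick-envelope samples.
#' @param threshold Detection threshold (> 0).
#' @param refractory_ms Minimum separation between accepted events,
#'   milliseconds. Default 50.
#' @param fs Sampling rate, Hz. Default 1000.
#' @return Integer sample indices of accepted rising edges.
#' @export
#' @examples
#' detect_licks(c(0, 0, 1, 1, 0, 0, 1, 0), threshold = 0.5, refractory_ms = 1)
detect_licks <- function(trace, threshold = 0.5, refractory_ms = 50, fs = 1000) {
  if (all(is.na(trace))) abort("Lick trace is all-NaN; nothing to detect.")
  if (threshold <= 0) abort("`threshold` must be positive.")
  x <- trace
  x[is.na(x)] <- -Inf
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  if (length(up) == 0) return(integer(0))
  refr <- refractory_ms * fs / 1000
  keep <- up[1]
  last <- up[1]
  for (t in up[-1]) {
    if (t - last >= refr) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

#' Per-trial lick frequencies with pooled baseline z-scoring
#'
#' Counts detected licks in the 500-ms baseline epoch (immediately before
#' stimulus onset) and in the animal-specific 500-ms stimulus epoch, converts
#' to frequencies (licks/s), and z-scores the stimulus-epoch frequency
#' against the baseline frequencies pooled across the trials of each
#' (session, block, condition) cell: `z = (stim - mean(base)) / sd(base)`.
#'
#' @param licks A `lick_data` object from [simulate_licks()] (or an
#'   equivalently shaped recording).
#' @param threshold,refractory_ms Passed to [detect_licks()].
#' @return The trial tibble with added columns `base_freq`, `stim_freq`,
#'   `lick_z`.
#' @export
lick_zscores <- function(licks, threshold = 0.5, refractory_ms = 50) {
  stopifnot(inherits(licks, "lick_data"))
  t0 <- licks$t0
  ep <- licks$epoch_stim
  base_idx <- seq(t0 - 500L, t0 - 1L)
  stim_idx <- seq(t0 + ep[1], t0 + ep[2])
  n <- nrow(licks$traces)
  base_freq <- stim_freq <- numeric(n)
  for (i in seq_len(n)) {
    ev <- detect_licks(licks$traces[i, ], threshold, refractory_ms, licks$fs)
    base_freq[i] <- sum(ev %in% base_idx) / 0.5
    stim_freq[i] <- sum(ev %in% stim_idx) / 0.5
  }
  out <- dplyr::mutate(licks$trials, base_freq = base_freq, stim_freq = stim_freq)
  out <- dplyr::group_by(out, .data$session, .data$block, .data$condition)
  out <- dplyr::mutate(out, lick_z = pooled_z(.data$stim_freq, .data$base_freq))
  dplyr::ungroup(out)
}

# z-score stimulus-epoch values against pooled baseline mean/SD.
pooled_z <- function(stim, base) {
  s <- sd(base)
  if (!is.finite(s) || s == 0) {
    abort(paste0(
      "Baseline lick frequencies have zero variance in one analysis cell; ",
      "the pooled z-score is undefined."
    ))
  }
  (stim - mean(base)) / s
}

#' Median-absolute-deviation outlier mask
#'
#' Keeps `x[i]` iff `|x[i] - median(x)| <= k * MAD`, where
#' `MAD = median(|x - median(x)|)` without any normal-consistency scaling.
#' When the MAD is zero only values equal to the median are kept.
#'
#' @param x Numeric vector (at least 3 finite values).
#' @param k Threshold in MAD units. Default 3.
#' @return Logical inclusion mask, same length as `x`.
#' @export
#' @examples
#' mad_keep(c(1, 2, 3, 100)) # drops 100
mad_keep <- function(x, k = 3) {
  if (length(x) == 0) abort("`x` is empty.")
  if (sum(is.finite(x)) < 3) abort("Need at least 3 finite values.")
  med <- median(x, na.rm = TRUE)
  m <- median(abs(x - med), na.rm = TRUE)
  if (m == 0) {
    out <- x == med
  } else {
    out <- abs(x - med) <= k * m
  }
  out & is.finite(x)
}

#' Spearman rank association between lick response and reward probability
#'
#' Midrank ties; two-sided p-value, by exact enumeration for n <= 10 without
#' ties and by the t approximation otherwise.
#'
#' @param values Numeric responses (e.g. z-scored lick frequencies).
#' @param probs Matching reward probabilities.
#' @return One-row tibble: `rho`, `p_value`, `n`, `degenerate` (TRUE when an
#'   input is constant and rho is undefined).
#' @export
spearman_association <- function(values, probs) {
  ok <- is.finite(values) & is.finite(probs)
  values <- values[ok]
  probs <- probs[ok]
  if (length(values) < 3) abort("Need at least 3 paired observations.")
  if (sd(values) == 0 || sd(probs) == 0) {
    warn("Constant input: Spearman rho is undefined.")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = length(values),
                  degenerate = TRUE))
  }
  exact <- length(values) <= 10 && !anyDuplicated(values) && !anyDuplicated(probs)
  ct <- suppressWarnings(
    cor.test(probs, values, method = "spearman", exact = exact,
             alternative = "two.sided")
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(values),
         degenerate = FALSE)
}

# Split one block's trials into preferred / non-preferred groups.
# Self-variable block: preferred = highest self-reward probability;
# partner-variable block: preferred = lowest partner-reward probability.
preference_groups <- function(data) {
  block <- unique(data$block)
  if (length(block) != 1) abort("`data` must contain a single block.")
  if (grepl("self", block)) {
    probs <- data$p_self
    pref_p <- max(probs)
    nonpref_p <- min(probs)
  } else {
    probs <- data$p_partner
    pref_p <- min(probs)
    nonpref_p <- max(probs)
  }
  if (pref_p == nonpref_p) {
    abort("Both preferred and non-preferred trials are required.")
  }
  list(
    preferred = data[probs == pref_p, , drop = FALSE],
    nonpreferred = data[probs == nonpref_p, , drop = FALSE]
  )
}

#' Chronologically-paired licking modulation
#'
#' Within one block and condition, trials with the preferred and
#' non-preferred variable-reward probability are each sorted
#' chronologically; the i-th preferred trial is paired with the i-th
#' non-preferred trial (truncating to the shorter group) and the modulation
#' is the mean of the paired differences (preferred minus non-preferred).
#' The chronological pairing absorbs slow within-session trends shared by
#' neighbouring trials.
#'
#' @param data Tibble for one block and condition with columns `block`,
#'   `p_self`, `p_partner`, `trial_index`, and the response in `value_col`.
#' @param value_col Name of the response column. Default `"lick_z"`.
#' @return One-row tibble: `modulation`, `n_pairs`.
#' @export
licking_modulation <- function(data, value_col = "lick_z") {
  d <- paired_differences(data, value_col)
  tibble(modulation = mean(d), n_pairs = length(d))
}

paired_differences <- function(data, value_col = "lick_z") {
  g <- preference_groups(data)
  if (nrow(g$preferred) == 0 || nrow(g$nonpreferred) == 0) {
    abort("Both preferred and non-preferred trials are required.")
  }
  pref <- g$preferred[[value_col]][order(g$preferred$trial_index)]
  nonp <- g$nonpreferred[[value_col]][order(g$nonpreferred$trial_index)]
  m <- min(length(pref), length(nonp))
  pref[seq_len(m)] - nonp[seq_len(m)]
}

#' Welch's two-sample t-test, tidied
#'
#' Two-sided Welch t-test (unequal variances, Satterthwaite degrees of
#' freedom) returned as a one-row tibble.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return Tibble: `estimate` (mean difference a - b), `statistic`, `df`,
#'   `p_value`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("Each sample needs n >= 2.")
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(
    estimate = unname(diff(rev(tt$estimate))), statistic = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value
  )
}
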