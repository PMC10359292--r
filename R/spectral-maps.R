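#' Baseline-normalise coherence maps
#'
#' Per frequency (and per map), subtracts the mean coherence over the
#' pre-stimulus baseline window (default the 500 ms immediately before
#' onset), so the baseline-window mean of the output is zero.
#'
#' @param stack A `tfr_stack` (raw coherence).
#' @param baseline_s Baseline window, seconds, `c(start, end)` with the
#'   window half-open at `end`. Default `c(-0.5, 0)`.
#' @return A `tfr_stack` with `meaning = "normalized coherence"`.
#' @export
baseline_normalize <- function(stack, baseline_s = c(-0.5, 0)) {
  stopifnot(inherits(stack, "tfr_stack"))
  base_idx <- which(stack$time >= baseline_s[1] & stack$time < baseline_s[2])
  if (length(base_idx) == 0) abort("Baseline window contains no samples.")
  v <- stack$values
  for (k in seq_len(dim(v)[3])) {
    base_mean <- colMeans(v[base_idx, , k, drop = FALSE][, , 1, drop = TRUE])
    v[, , k] <- sweep(v[, , k], 2, base_mean)
  }
  out <- stack
  out$values <- v
  out$meaning <- "normalized coherence"
  out
}

#' Coherence modulation between conditions
#'
#' Per channel pair, subtracts the normalised coherence map of the control
#' condition from that of the drug condition (drug minus control); the
#' observed modulation map is the average of the per-pair differences.
#'
#' @param norm_control,norm_drug `tfr_stack`s of normalised coherence with
#'   pairs matched by position.
#' @return List with `diff` (a `tfr_stack` of per-pair difference maps) and
#'   `observed` (time x freq matrix, the across-pair mean map).
#' @export
coherence_modulation <- function(norm_control, norm_drug) {
  stopifnot(
    inherits(norm_control, "tfr_stack"), inherits(norm_drug, "tfr_stack"),
    all(dim(norm_control$values) == dim(norm_drug$values))
  )
  d <- norm_drug$values - norm_control$values
  diff_stack <- new_tfr_stack(d, norm_control$time, norm_control$freqs,
                              pairs = norm_control$pairs,
                              meaning = "modulation")
  list(diff = diff_stack, observed = apply(d, c(1, 2), mean))
}

#' Simulate a stack of normalised coherence maps
#'
#' Generates per-pair normalised-coherence maps as temporally smoothed
#' Gaussian noise with per-bin standard deviation `noise_sd`, baseline-mean
#' subtracted per frequency. The default `noise_sd` of 0.025 corresponds to
#' the asymptotic sampling error of magnitude-squared coherence,
#' `sqrt(2 C (1 - C)^2 / n)`, for weak coherence (C about 0.1) estimated
#' from roughly 250 trials. An additive effect can be injected into a
#' time-frequency region of every map, emulating a condition-specific
#' coherence change.
#'
#' @param n_pairs Number of maps.
#' @param noise_sd Per-bin standard deviation. Default 0.025.
#' @param effect Optional list `(time = c(start, end) seconds,
#'   freq_bins = indices, delta = shift)` added to all maps.
#' @param smooth_ms Gaussian temporal smoothing SD, ms. Default 20.
#' @param time,freqs Map axes; defaults are the standard 1500-point,
#'   24-frequency axes.
#' @param seed Integer seed.
#' @return A `tfr_stack` of `meaning = "normalized coherence"`.
#' @export
simulate_coherence_stack <- function(n_pairs, noise_sd = 0.025, effect = NULL,
                                     smooth_ms = 20,
                                     time = seq(-0.5, 0.999, by = 0.001),
                                     freqs = coherence_freqs(), seed = 1) {
  nt <- length(time)
  nf <- length(freqs)
  kern <- stats::dnorm(seq(-3 * smooth_ms, 3 * smooth_ms), sd = smooth_ms)
  kern <- kern / sqrt(sum(kern^2)) # unit output SD for white-noise input
  lw <- length(kern)
  nfft <- stats::nextn(nt + lw - 1, 2)
  K <- fft(c(kern, rep(0, nfft - lw)))
  half <- (lw - 1) / 2
  base_idx <- which(time < 0)
  vals <- with_seed(derive_seed(seed, "stack"), {
    v <- array(0, c(nt, nf, n_pairs))
    chunk <- 50
    for (k0 in seq(1, n_pairs, by = chunk)) {
      kk <- k0:min(k0 + chunk - 1, n_pairs)
      z <- matrix(0, nfft, nf * length(kk))
      z[seq_len(nt), ] <- rnorm(nt * nf * length(kk))
      conv <- Re(stats::mvfft(stats::mvfft(z) * K, inverse = TRUE)) / nfft
      v[, , kk] <- array(conv[(half + 1):(half + nt), ] * noise_sd,
                         c(nt, nf, length(kk)))
    }
    v
  })
  if (!is.null(effect)) {
    t_idx <- which(time >= effect$time[1] & time < effect$time[2])
    vals[t_idx, effect$freq_bins, ] <- vals[t_idx, effect$freq_bins, ] +
      effect$delta
  }
  for (k in seq_len(n_pairs)) {
    bm <- colMeans(vals[base_idx, , k, drop = FALSE][, , 1, drop = TRUE])
    vals[, , k] <- sweep(vals[, , k], 2, bm)
  }
  new_tfr_stack(vals, time, freqs, meaning = "normalized coherence")
}
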