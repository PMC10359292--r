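#' Standard frequency axis of the coherence analysis
#'
#' 24 logarithmically spaced frequency bins spanning 1-128 Hz:
#' `2^(k * 7 / 23)` for `k = 0..23`.
#'
#' @return Numeric vector of length 24.
#' @export
coherence_freqs <- function() 2^((0:23) * 7 / 23)

# L2-normalised complex Morlet wavelet at frequency f (Hz).
morlet_wavelet <- function(f, fs, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f)
  t <- seq(-4 * sigma_t, 4 * sigma_t, by = 1 / fs)
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Complex Morlet wavelet transform
#'
#' Convolves `x` with an L2-normalised complex Morlet wavelet (fixed cycle
#' count) at each requested frequency, via FFT, returning the centred
#' same-length coefficients. When trials are analysed, they are concatenated
#' into one long series before convolution and re-segmented afterwards (see
#' [wavelet_coherence_maps()]).
#'
#' @param x Numeric series.
#' @param freqs Frequencies, Hz (0 < f < Nyquist).
#' @param fs Sampling rate, Hz.
#' @param n_cycles Morlet cycle count. Default 7.
#' @return Complex matrix, `length(x)` x `length(freqs)`.
#' @export
morlet_transform <- function(x, freqs = coherence_freqs(), fs = 1000,
                             n_cycles = 7) {
  if (any(freqs <= 0 | freqs >= fs / 2)) {
    abort("Wavelet frequencies must lie strictly between 0 and Nyquist.")
  }
  nx <- length(x)
  wl <- vapply(freqs, function(f) {
    length(morlet_wavelet(f, fs, n_cycles))
  }, numeric(1))
  if (nx < max(wl)) {
    abort("Series shorter than the longest wavelet support.")
  }
  nfft <- stats::nextn(nx + max(wl) - 1, 2)
  X <- fft(c(x, rep(0, nfft - nx)))
  out <- matrix(0i, nx, length(freqs))
  for (j in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[j], fs, n_cycles)
    lw <- length(w)
    W <- fft(c(w, rep(0, nfft - lw)))
    conv <- fft(X * W, inverse = TRUE) / nfft
    half <- (lw - 1) / 2
    out[, j] <- conv[(half + 1):(half + nx)]
  }
  out
}

#' Trial-averaged wavelet coherence maps for channel pairs
#'
#' For each requested MPFC-LH channel pair: the per-trial segments are
#' concatenated into one long series per channel, notch-filtered, wavelet
#' transformed, re-segmented into the original trial segments, and the
#' magnitude-squared coherence is computed per time-frequency bin from the
#' trial-averaged cross- and auto-spectra:
#' \deqn{C = |mean_t(W_x W_y^*)|^2 / (mean_t|W_x|^2 \, mean_t|W_y|^2).}
#' Maps are returned on the analysis window (default -0.5 s to +1 s around
#' onset: 1500 time points x 24 frequencies).
#'
#' @param lfp An `lfp_data` object (one condition/block; subset first with
#'   [lfp_subset()]).
#' @param pairs Optional two-column matrix/data frame of (MPFC channel,
#'   LH channel) indices; default all MPFC x LH combinations.
#' @param freqs Frequency bins, Hz. Default [coherence_freqs()].
#' @param n_cycles Morlet cycle count. Default 7.
#' @param notch Notch frequencies passed to [remove_line_noise()]; `NULL`
#'   disables filtering.
#' @param window_s Analysis window around onset, seconds, half-open on the
#'   right. Default `c(-0.5, 1)`.
#' @return A `tfr_stack`: list with `values` (time x freq x pair array of
#'   raw coherence), `time` (s), `freqs` (Hz), `pairs` (tibble), `meaning =
#'   "coherence"`.
#' @export
wavelet_coherence_maps <- function(lfp, pairs = NULL,
                                   freqs = coherence_freqs(), n_cycles = 7,
                                   notch = c(60, 120),
                                   window_s = c(-0.5, 1)) {
  stopifnot(inherits(lfp, "lfp_data"))
  n_trials <- dim(lfp$lfp)[1]
  if (n_trials < 2) {
    abort("Coherence needs >= 2 trials (single-trial coherence is degenerate).")
  }
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(
      mpfc = which(lfp$areas == "MPFC"), lh = which(lfp$areas == "LH")
    ))
  }
  pairs <- as.matrix(pairs)
  colnames(pairs) <- c("source", "target")
  n_samp <- dim(lfp$lfp)[3]
  win_idx <- which(lfp$time >= window_s[1] & lfp$time < window_s[2])
  nt <- length(win_idx)
  nf <- length(freqs)
  # wavelet coefficients per channel, kept only on the analysis window
  chans <- sort(unique(as.vector(pairs)))
  coeffs <- vector("list", max(chans))
  for (ch in chans) {
    long <- as.vector(t(lfp$lfp[, ch, ]))
    if (!is.null(notch)) long <- remove_line_noise(long, notch, lfp$fs)
    W <- morlet_transform(long, freqs, lfp$fs, n_cycles)
    seg <- array(0i, c(n_trials, nt, nf))
    for (tr in seq_len(n_trials)) {
      seg[tr, , ] <- W[(tr - 1) * n_samp + win_idx, ]
    }
    coeffs[[ch]] <- seg
  }
  values <- array(0, c(nt, nf, nrow(pairs)))
  for (k in seq_len(nrow(pairs))) {
    Wx <- coeffs[[pairs[k, 1]]]
    Wy <- coeffs[[pairs[k, 2]]]
    Sxy <- apply(Wx * Conj(Wy), c(2, 3), mean)
    Sxx <- apply(Mod(Wx)^2, c(2, 3), mean)
    Syy <- apply(Mod(Wy)^2, c(2, 3), mean)
    values[, , k] <- Mod(Sxy)^2 / (Sxx * Syy)
  }
  new_tfr_stack(values, lfp$time[win_idx], freqs,
                pairs = as_tibble(pairs), meaning = "coherence")
}

new_tfr_stack <- function(values, time, freqs, pairs = NULL,
                          meaning = "coherence") {
  structure(
    list(values = values, time = time, freqs = freqs, pairs = pairs,
         meaning = meaning),
    class = "tfr_stack"
  )
}

#' @export
print.tfr_stack <- function(x, ...) {
  cat(sprintf(
    "<tfr_stack> %d time x %d freq x %d maps (%s)\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$meaning
  ))
  invisible(x)
}
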