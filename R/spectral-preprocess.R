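#' Remove mains-hum components from a field-potential series
#'
#' Zero-phase band-stop (notch) filtering at each listed frequency using a
#' second-order Butterworth design applied forwards and backwards
#' ([signal::filtfilt()]), with a 2 Hz half-width by default.
#'
#' @param series Numeric series sampled at `fs`.
#' @param freqs Notch centre frequencies, Hz. Default `c(60, 120)`.
#' @param fs Sampling rate, Hz. Default 1000.
#' @param half_width Half-width of each stop band, Hz. Default 2.
#' @return Filtered series, same length.
#' @export
remove_line_noise <- function(series, freqs = c(60, 120), fs = 1000,
                              half_width = 2) {
  nyq <- fs / 2
  if (any(freqs + half_width >= nyq)) {
    abort("Notch frequency too close to or above the Nyquist frequency.")
  }
  # filter around the series mean: the zero-padded forward-backward pass
  # otherwise leaves edge transients on signals with an offset
  mu <- mean(series)
  out <- series - mu
  for (f in freqs) {
    flt <- signal::butter(2, c(f - half_width, f + half_width) / nyq,
                          type = "stop")
    out <- signal::filtfilt(flt, out)
  }
  out + mu
}

#' Screen trials by mean field-potential amplitude
#'
#' Per trial, the mean LFP value over channels and samples is computed and
#' screened with the 3-MAD rule ([mad_keep()]); trials whose mean amplitude
#' is an outlier are excluded from coherence and causality analyses.
#'
#' @param lfp An `lfp_data` object.
#' @param k MAD threshold. Default 3.
#' @return Logical inclusion mask over trials.
#' @export
lfp_trial_filter <- function(lfp, k = 3) {
  stopifnot(inherits(lfp, "lfp_data"))
  trial_means <- apply(lfp$lfp, 1, mean)
  mad_keep(trial_means, k = k)
}

#' Subset an `lfp_data` object by trial
#'
#' @param lfp An `lfp_data` object.
#' @param idx Logical or integer trial selector.
#' @return An `lfp_data` containing the selected trials.
#' @export
lfp_subset <- function(lfp, idx) {
  stopifnot(inherits(lfp, "lfp_data"))
  lfp$trials <- lfp$trials[idx, , drop = FALSE]
  lfp$lfp <- lfp$lfp[idx, , , drop = FALSE]
  lfp
}
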