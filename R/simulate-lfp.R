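#' Simulate a coupled dual-site field-potential dataset
#'
#' For every trial, simulates an (MPFC + LH)-channel VAR segment at 1 kHz
#' spanning the window in `spec` (default -2 s to +2 s around stimulus
#' onset, 4001 samples). Samples up to and including onset use the baseline
#' coefficients; post-onset samples use coefficients whose MPFC-to-LH
#' blocks are scaled by `stimulus_coupling_gain` (vehicle trials) or
#' `dcz_coupling_gain` (DCZ trials). A burn-in is simulated and discarded
#' before the segment so the pre-stimulus window is stationary.
#'
#' @param trials Trial table ([simulate_trials()]).
#' @param spec A [coupling_spec()].
#' @param seed Integer seed.
#' @return An `lfp_data` object: list with `trials`, `lfp` (array
#'   trials x channels x samples), `areas` (channel labels), `fs`, `time`
#'   (seconds relative to onset) and `onset` (sample index of t = 0).
#' @export
simulate_lfp <- function(trials, spec = coupling_spec(), seed = 1) {
  stopifnot(inherits(spec, "coupling_spec"), nrow(trials) > 0)
  n_ch <- spec$n_mpfc + spec$n_lh
  p <- spec$order
  tm <- seq(spec$window_s[1], spec$window_s[2], by = 1 / spec$fs)
  n_samp <- length(tm)
  onset <- which.min(abs(tm))
  L <- chol(spec$innovation_cov)
  A_pre <- coupling_coeff(spec, 1)
  lfp <- array(0, c(nrow(trials), n_ch, n_samp))
  key <- interaction(trials$session, trials$block, trials$condition, drop = TRUE)
  with_seed(derive_seed(seed, "lfp"), {
    for (grp in levels(key)) {
      idx <- which(key == grp)
      gain <- if (trials$condition[idx[1]] == "DCZ") {
        spec$dcz_coupling_gain
      } else {
        spec$stimulus_coupling_gain
      }
      A_post <- coupling_coeff(spec, gain)
      nt <- length(idx)
      total <- spec$burn_in + n_samp
      # lag buffer: list of n_ch x nt matrices, most recent first
      lags <- replicate(p, matrix(0, n_ch, nt), simplify = FALSE)
      seg <- array(0, c(nt, n_ch, n_samp))
      for (s in seq_len(total)) {
        samp_i <- s - spec$burn_in
        A <- if (samp_i > onset) A_post else A_pre
        x <- crossprod(L, matrix(rnorm(n_ch * nt), n_ch, nt))
        for (k in seq_len(p)) x <- x + A[, , k] %*% lags[[k]]
        if (p > 1) lags[seq(2, p)] <- lags[seq_len(p - 1)]
        lags[[1]] <- x
        if (samp_i >= 1) seg[, , samp_i] <- t(x)
      }
      lfp[idx, , ] <- seg
    }
  })
  structure(
    list(
      trials = trials, lfp = lfp, areas = spec$areas, fs = spec$fs,
      time = tm, onset = onset
    ),
    class = "lfp_data"
  )
}

#' @export
print.lfp_data <- function(x, ...) {
  cat(sprintf(
    "<lfp_data> %d trials x %d channels (%s) x %d samples at %g Hz\n",
    dim(x$lfp)[1], dim(x$lfp)[2], paste(x$areas, collapse = ","),
    dim(x$lfp)[3], x$fs
  ))
  invisible(x)
}
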