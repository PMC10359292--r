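#' Simulate lick-sensor envelopes for a trial table
#'
#' Produces, for every trial, a 1 kHz envelope spanning -0.5 s to +1.0 s
#' around stimulus onset (1501 samples; onset at sample 501). Lick events
#' are an inhomogeneous Bernoulli process
#' per 1-ms bin whose rate is `baseline_rate` before onset and
#' `baseline_rate + self_slope * p_self + partner_slope * p_partner` from
#' onset on (with `partner_slope` attenuated under DCZ); events are
#' convolved with a 20-ms boxcar to mimic the sensor envelope, and Gaussian
#' sensor noise is added. A negative expected rate is clipped at zero with a
#' warning.
#'
#' @param trials A trial table from [simulate_trials()].
#' @param spec A [lick_effect_spec()].
#' @param seed Integer seed.
#' @return A `lick_data` object: list with `trials` (the input tibble),
#'   `traces` (trials x 1501 matrix), `t0` (index of the onset sample),
#'   `fs`, and `epoch_stim` (ms after onset).
#' @export
simulate_licks <- function(trials, spec = lick_effect_spec(), seed = 1) {
  stopifnot(inherits(spec, "lick_effect_spec"), nrow(trials) > 0)
  n_pre <- 500L
  n_post <- 1001L # 0..1000 ms inclusive
  n_samp <- n_pre + n_post
  slope_p <- ifelse(trials$condition == "DCZ",
    spec$partner_slope * spec$dcz_partner_attenuation, spec$partner_slope
  )
  rate_stim <- spec$baseline_rate + spec$self_slope * trials$p_self +
    slope_p * trials$p_partner
  if (any(rate_stim < 0)) {
    warn("Negative expected lick rate clipped at 0 for some trials.")
    rate_stim <- pmax(rate_stim, 0)
  }
  kernel <- rep(1, 20)
  traces <- with_seed(derive_seed(seed, "licks"), {
    out <- matrix(0, nrow(trials), n_samp)
    for (i in seq_len(nrow(trials))) {
      p <- c(
        rep(spec$baseline_rate / spec$fs, n_pre),
        rep(rate_stim[i] / spec$fs, n_post)
      )
      events <- rbinom(n_samp, 1, pmin(p, 1))
      env <- stats::filter(events, kernel, sides = 1)
      env[is.na(env)] <- 0
      out[i, ] <- as.numeric(env) + rnorm(n_samp, sd = spec$noise_sd)
    }
    out
  })
  structure(
    list(
      trials = trials, traces = traces, t0 = n_pre + 1L, fs = spec$fs,
      epoch_stim = spec$epoch_stim
    ),
    class = "lick_data"
  )
}

#' @export
print.lick_data <- function(x, ...) {
  cat(sprintf(
    "<lick_data> %d trials, %d samples at %g Hz (stimulus epoch %d-%d ms)\n",
    nrow(x$traces), ncol(x$traces), x$fs, x$epoch_stim[1], x$epoch_stim[2]
  ))
  invisible(x)
}
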