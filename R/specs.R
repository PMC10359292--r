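#' Task configuration for the dyadic conditioning generator
#'
#' Describes the two-block social Pavlovian task: in the self-variable block
#' the subject's own reward probability varies across the three conditioned
#' stimuli while the partner's is fixed; in the partner-variable block the
#' roles are swapped. The two animals are never rewarded on the same trial.
#'
#' @param trials_per_block Trials per block; must be divisible by the number
#'   of stimuli so each stimulus appears equally often. Default 120.
#' @param variable_probs Reward probabilities of the three stimuli on the
#'   varying dimension. Default `c(0.25, 0.5, 0.75)`.
#' @param fixed_prob Reward probability on the fixed dimension. Default 0.2.
#' @param blocks Ordered block labels.
#' @param conditions Drug condition labels (control first).
#' @param n_sessions Number of recording sessions to generate.
#' @return A `task_config` object (a validated list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$trials_per_block
task_config <- function(trials_per_block = 120,
                        variable_probs = c(0.25, 0.5, 0.75),
                        fixed_prob = 0.2,
                        blocks = c("self-variable", "partner-variable"),
                        conditions = c("vehicle", "DCZ"),
                        n_sessions = 1) {
  if (any(variable_probs < 0 | variable_probs > 1) ||
      fixed_prob < 0 || fixed_prob > 1) {
    abort("Reward probabilities must lie in [0, 1].")
  }
  if (trials_per_block %% length(variable_probs) != 0) {
    abort(sprintf(
      "`trials_per_block` (%d) must be divisible by the number of stimuli (%d).",
      trials_per_block, length(variable_probs)
    ))
  }
  if (any(variable_probs + fixed_prob > 1)) {
    abort(paste0(
      "Infeasible probability pair: p_self + p_partner exceeds 1 for some ",
      "stimulus, which contradicts the never-both-rewarded constraint."
    ))
  }
  structure(
    list(
      trials_per_block = as.integer(trials_per_block),
      variable_probs = variable_probs,
      fixed_prob = fixed_prob,
      blocks = blocks,
      conditions = conditions,
      n_sessions = as.integer(n_sessions)
    ),
    class = "task_config"
  )
}

#' Anticipatory-licking effect specification
#'
#' Parameters of the synthetic lick generator. The expected lick rate in the
#' stimulus epoch is `baseline_rate + self_slope * p_self +
#' partner_slope * p_partner` (licks/s); under the DCZ condition
#' `partner_slope` is multiplied by `dcz_partner_attenuation`. Licks are
#' placed as an inhomogeneous Bernoulli process per 1-ms bin, convolved with
#' a 20-ms boxcar to mimic the envelope of a vibration sensor, plus Gaussian
#' sensor noise.
#'
#' Effect sizes in physical units are free parameters of the generator (the
#' behavioural literature reports modulation only on a normalised scale);
#' the defaults give a clearly detectable but not extreme probability
#' dependence at the standard block size.
#'
#' @param baseline_rate Baseline lick rate, licks/s. Default 3.
#' @param self_slope Change in lick rate per unit self-reward probability,
#'   licks/s. Default 4.
#' @param partner_slope Change per unit partner-reward probability, licks/s
#'   (negative: prospective partner reward suppresses licking). Default -3.
#' @param dcz_partner_attenuation Multiplier in \[0, 1\] applied to
#'   `partner_slope` under DCZ; 0 removes the partner effect entirely.
#'   Default 0.1.
#' @param noise_sd Gaussian sensor noise SD added to the envelope, small
#'   relative to the unit pulse height so the threshold detector sees
#'   essentially noise-free edges. Default 0.1.
#' @param fs Sampling rate of the lick envelope, Hz. Default 1000.
#' @param epoch_stim Stimulus epoch, ms after onset, as `c(start, end)` of a
#'   half-open 500-ms interval. Animal-specific (e.g. `c(501, 1000)` or
#'   `c(251, 750)`). Default `c(501, 1000)`.
#' @return A `lick_effect_spec` object.
#' @export
lick_effect_spec <- function(baseline_rate = 3, self_slope = 4,
                             partner_slope = -3,
                             dcz_partner_attenuation = 0.1,
                             noise_sd = 0.1, fs = 1000,
                             epoch_stim = c(501, 1000)) {
  if (baseline_rate < 0) abort("`baseline_rate` must be non-negative.")
  if (dcz_partner_attenuation < 0 || dcz_partner_attenuation > 1) {
    abort("`dcz_partner_attenuation` must lie in [0, 1].")
  }
  if (diff(epoch_stim) + 1 != 500) {
    abort("`epoch_stim` must span exactly 500 ms.")
  }
  structure(
    list(
      baseline_rate = baseline_rate, self_slope = self_slope,
      partner_slope = partner_slope,
      dcz_partner_attenuation = dcz_partner_attenuation,
      noise_sd = noise_sd, fs = fs, epoch_stim = as.integer(epoch_stim)
    ),
    class = "lick_effect_spec"
  )
}

#' Coupled-field-potential generator specification
#'
#' Defines a stimulus-locked vector autoregressive (VAR) generator for
#' dual-site field potentials: `n_mpfc` prefrontal and `n_lh` hypothalamic
#' channels, each an AR(1) with coefficient `ar`, with a directed lag-1
#' coupling of strength `coupling` from every MPFC channel onto every LH
#' channel. Before stimulus onset the coupling blocks are used as given;
#' after onset they are multiplied by `stimulus_coupling_gain` (vehicle) or
#' `dcz_coupling_gain` (DCZ). The ground-truth causal direction is
#' MPFC to LH only.
#'
#' Because the coupling is feed-forward the companion matrix is block
#' triangular and stability is governed by `ar` alone, for any gain.
#'
#' @param n_mpfc,n_lh Channel counts per area. Defaults 2 and 2.
#' @param ar Diagonal AR(1) coefficient of every channel (|ar| < 1).
#'   Default 0.9, putting most spectral mass below ~20 Hz at 1 kHz.
#' @param coupling Baseline MPFC-to-LH lag-1 coefficient. Default 0.25.
#' @param stimulus_coupling_gain Multiplier on the coupling blocks after
#'   stimulus onset in the vehicle condition. Default 1.
#' @param dcz_coupling_gain Post-onset multiplier under DCZ. Default 0.2.
#' @param innovation_sd Innovation SD per channel (diagonal innovation
#'   covariance). Default 1.
#' @param fs Sampling rate, Hz. Default 1000.
#' @param window_s Segment extent around stimulus onset, seconds. Default
#'   `c(-2, 2)` (4001 samples at 1 kHz).
#' @param burn_in Samples simulated and discarded before the segment.
#'   Default 200.
#' @return A `coupling_spec` object carrying the per-regime coefficient
#'   arrays and the innovation covariance.
#' @export
coupling_spec <- function(n_mpfc = 2, n_lh = 2, ar = 0.9, coupling = 0.25,
                          stimulus_coupling_gain = 1, dcz_coupling_gain = 0.2,
                          innovation_sd = 1, fs = 1000, window_s = c(-2, 2),
                          burn_in = 200) {
  n <- n_mpfc + n_lh
  A <- matrix(0, n, n)
  diag(A) <- ar
  A[(n_mpfc + 1):n, seq_len(n_mpfc)] <- coupling
  spec <- structure(
    list(
      n_mpfc = as.integer(n_mpfc), n_lh = as.integer(n_lh),
      order = 1L,
      coeff = array(A, c(n, n, 1)),
      innovation_cov = diag(innovation_sd^2, n),
      stimulus_coupling_gain = stimulus_coupling_gain,
      dcz_coupling_gain = dcz_coupling_gain,
      fs = fs, window_s = window_s, burn_in = as.integer(burn_in),
      areas = rep(c("MPFC", "LH"), c(n_mpfc, n_lh))
    ),
    class = "coupling_spec"
  )
  for (g in c(1, stimulus_coupling_gain, dcz_coupling_gain)) {
    rho <- companion_spectral_radius(coupling_coeff(spec, g))
    if (rho >= 1) {
      abort(sprintf(
        "Unstable coefficient set (companion spectral radius %.3f >= 1).", rho
      ))
    }
  }
  spec
}

# Coefficient array with the MPFC->LH blocks scaled by `gain`.
coupling_coeff <- function(spec, gain) {
  A <- spec$coeff
  src <- seq_len(spec$n_mpfc)
  tgt <- spec$n_mpfc + seq_len(spec$n_lh)
  A[tgt, src, ] <- A[tgt, src, ] * gain
  A
}

#' Gaze generator specification
#'
#' Per-trial region-of-interest (ROI) occupancy proportions are drawn from a
#' beta distribution with condition-specific means; gaze samples at 500 Hz
#' are then placed inside or outside the ROI accordingly. A small fraction
#' of samples is marked invalid (blinks / tracking loss).
#'
#' @param stim_occupancy Named mean ROI occupancy during the stimulus period
#'   per condition, each in \[0, 1\].
#' @param outcome_occupancy Same for the outcome period (partner ROI).
#' @param concentration Beta concentration (larger = less trial-to-trial
#'   spread). Default 20.
#' @param blink_rate Expected fraction of invalid samples. Default 0.02.
#' @param fs Gaze sampling rate, Hz. Default 500.
#' @param period_s Period length, seconds. Default 1.
#' @param roi Stimulus ROI rectangle, degrees, as
#'   `c(xmin, xmax, ymin, ymax)`.
#' @return A `gaze_spec` object.
#' @export
gaze_spec <- function(stim_occupancy = c(vehicle = 0.55, DCZ = 0.55),
                      outcome_occupancy = c(vehicle = 0.4, DCZ = 0.4),
                      concentration = 20, blink_rate = 0.02, fs = 500,
                      period_s = 1, roi = c(-5, 5, -5, 5)) {
  occ <- c(stim_occupancy, outcome_occupancy)
  if (any(occ < 0 | occ > 1)) {
    abort("ROI occupancy parameters must lie in [0, 1].")
  }
  if (roi[2] <= roi[1] || roi[4] <= roi[3]) abort("ROI must have positive area.")
  structure(
    list(
      stim_occupancy = stim_occupancy, outcome_occupancy = outcome_occupancy,
      concentration = concentration, blink_rate = blink_rate, fs = fs,
      period_s = period_s, roi = roi
    ),
    class = "gaze_spec"
  )
}
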