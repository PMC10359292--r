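#' Simulate a trial table for the dyadic conditioning task
#'
#' Generates one row per trial for every combination of session, block and
#' condition in `config`. Within each block the three stimuli appear equally
#' often in pseudorandom order. Outcomes respect the resource-limitation
#' constraint of the task: the subject and the partner are never rewarded on
#' the same trial, so each trial ends `"self"`, `"partner"` or `"neither"`
#' with probabilities `p_self`, `p_partner` and `1 - p_self - p_partner`.
#'
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `session`, `block`, `condition`,
#'   `stimulus_id`, `p_self`, `p_partner`, `outcome`, `trial_index`
#'   (chronological within session/block/condition).
#' @export
#' @examples
#' trials <- simulate_trials(task_config(), seed = 1)
#' dplyr::count(trials, block, stimulus_id)
simulate_trials <- function(config = task_config(), seed = 1) {
  stopifnot(inherits(config, "task_config"))
  n_stim <- length(config$variable_probs)
  reps <- config$trials_per_block / n_stim
  grid <- tidyr::expand_grid(
    session = seq_len(config$n_sessions),
    condition = config$conditions,
    block = config$blocks
  )
  with_seed(derive_seed(seed, "trials"), {
    purrr::pmap_dfr(grid, function(session, condition, block) {
      stim <- sample(rep(seq_len(n_stim), reps))
      varying <- config$variable_probs[stim]
      if (grepl("self", block)) {
        p_self <- varying
        p_partner <- rep(config$fixed_prob, length(stim))
      } else {
        p_self <- rep(config$fixed_prob, length(stim))
        p_partner <- varying
      }
      u <- runif(length(stim))
      outcome <- ifelse(u < p_self, "self",
        ifelse(u < p_self + p_partner, "partner", "neither")
      )
      tibble(
        session = session, block = block, condition = condition,
        stimulus_id = stim, p_self = p_self, p_partner = p_partner,
        outcome = outcome, trial_index = seq_along(stim)
      )
    })
  })
}
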