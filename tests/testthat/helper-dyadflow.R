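# Shared fixtures built in code.

# Minimal lick_data wrapper around a trace matrix.
make_lick_data <- function(traces, trials = NULL, epoch_stim = c(501, 1000)) {
  if (is.null(trials)) {
    trials <- tibble::tibble(
      session = 1, block = "self-variable", condition = "vehicle",
      stimulus_id = 1, p_self = 0.5, p_partner = 0.2, outcome = "neither",
      trial_index = seq_len(nrow(traces))
    )
  }
  structure(
    list(trials = trials, traces = traces, t0 = 501L, fs = 1000,
         epoch_stim = as.integer(epoch_stim)),
    class = "lick_data"
  )
}

# One-block tibble with explicit preferred/non-preferred values for the
# modulation statistic. `block` decides which probability column varies.
make_block <- function(pref_values, nonpref_values, condition = "vehicle",
                       block = "partner-variable",
                       pref_index = seq_along(pref_values),
                       nonpref_index = seq_along(nonpref_values)) {
  if (block == "partner-variable") {
    p_pref <- 0.25
    p_nonpref <- 0.75
    tibble::tibble(
      block = block, condition = condition,
      p_self = 0.2,
      p_partner = c(rep(p_pref, length(pref_values)),
                    rep(p_nonpref, length(nonpref_values))),
      trial_index = c(pref_index, nonpref_index),
      lick_z = c(pref_values, nonpref_values)
    )
  } else {
    tibble::tibble(
      block = block, condition = condition,
      p_self = c(rep(0.75, length(pref_values)),
                 rep(0.25, length(nonpref_values))),
      p_partner = 0.2,
      trial_index = c(pref_index, nonpref_index),
      lick_z = c(pref_values, nonpref_values)
    )
  }
}

# Simulate a stationary VAR path (channels x n), vectorised over trials:
# returns array trials x channels x n. Independent of the package's
# generator (plain R loop over time).
sim_var <- function(A, sigma = NULL, n, n_trials = 1, burn = 200) {
  n_ch <- dim(A)[1]
  p <- dim(A)[3]
  if (is.null(sigma)) sigma <- diag(n_ch)
  L <- chol(sigma)
  lags <- replicate(p, matrix(0, n_ch, n_trials), simplify = FALSE)
  out <- array(0, c(n_trials, n_ch, n))
  for (s in seq_len(burn + n)) {
    x <- crossprod(L, matrix(rnorm(n_ch * n_trials), n_ch, n_trials))
    for (k in seq_len(p)) x <- x + A[, , k] %*% lags[[k]]
    if (p > 1) lags[seq(2, p)] <- lags[seq_len(p - 1)]
    lags[[1]] <- x
    if (s > burn) out[, , s - burn] <- t(x)
  }
  out
}

# Small lfp_data constructor for hand-built channel data.
make_lfp_data <- function(arr, areas, fs = 1000,
                          time = seq(-2, 2, by = 1 / 1000)) {
  structure(
    list(
      trials = tibble::tibble(
        session = 1, block = "partner-variable", condition = "vehicle",
        trial_index = seq_len(dim(arr)[1])
      ),
      lfp = arr, areas = areas, fs = fs, time = time,
      onset = which.min(abs(time))
    ),
    class = "lfp_data"
  )
}
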