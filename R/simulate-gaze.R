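#' Simulate gaze samples for a trial table
#'
#' Draws a per-trial ROI occupancy proportion from a beta distribution with
#' condition-specific mean, then places 500 Hz gaze samples inside or
#' outside the ROI accordingly (uniformly within the ROI, and uniformly in
#' a surrounding field otherwise). A fraction `blink_rate` of samples is
#' invalidated (NaN position) to emulate blinks and tracking loss.
#'
#' @param trials Trial table.
#' @param spec A [gaze_spec()].
#' @param period `"stimulus"` or `"outcome"`; selects the occupancy
#'   parameter set and labels the output.
#' @param seed Integer seed.
#' @return A `gaze_data` object: list with `trials`, `x`, `y` (trials x
#'   samples matrices, NaN where invalid), `valid`, `roi`, `fs`, `period`.
#' @export
simulate_gaze <- function(trials, spec = gaze_spec(),
                          period = c("stimulus", "outcome"), seed = 1) {
  stopifnot(inherits(spec, "gaze_spec"), nrow(trials) > 0)
  period <- match.arg(period)
  occ <- if (period == "stimulus") spec$stim_occupancy else spec$outcome_occupancy
  mu <- unname(occ[trials$condition])
  if (anyNA(mu)) abort("Occupancy parameters missing for some condition.")
  n <- round(spec$fs * spec$period_s)
  roi <- spec$roi
  halo <- c(
    roi[1] - diff(roi[1:2]), roi[2] + diff(roi[1:2]),
    roi[3] - diff(roi[3:4]), roi[4] + diff(roi[3:4])
  )
  k <- spec$concentration
  with_seed(derive_seed(seed, paste0("gaze-", period)), {
    props <- ifelse(mu %in% c(0, 1), mu, rbeta(length(mu), mu * k, (1 - mu) * k))
    X <- Y <- matrix(NaN, nrow(trials), n)
    valid <- matrix(TRUE, nrow(trials), n)
    dwell <- 75 # mean fixation dwell scale, samples (150 ms at 500 Hz)
    for (i in seq_len(nrow(trials))) {
      # two-state Markov chain with stationary probability props[i] and
      # persistent runs, mimicking fixations rather than per-sample darts
      pr <- props[i]
      inside <- logical(n)
      inside[1] <- runif(1) < pr
      p_oi <- pr / dwell # out -> in
      p_io <- (1 - pr) / dwell # in -> out
      u <- runif(n - 1)
      for (s in 2:n) {
        inside[s] <- if (inside[s - 1]) u[s - 1] >= p_io else u[s - 1] < p_oi
      }
      x <- runif(n, halo[1], halo[2])
      y <- runif(n, halo[3], halo[4])
      x[inside] <- runif(sum(inside), roi[1], roi[2])
      y[inside] <- runif(sum(inside), roi[3], roi[4])
      redo <- which(!inside & x >= roi[1] & x <= roi[2] &
                      y >= roi[3] & y <= roi[4])
      while (length(redo) > 0) {
        x[redo] <- runif(length(redo), halo[1], halo[2])
        y[redo] <- runif(length(redo), halo[3], halo[4])
        redo <- redo[x[redo] >= roi[1] & x[redo] <= roi[2] &
                       y[redo] >= roi[3] & y[redo] <= roi[4]]
      }
      blink <- runif(n) < spec$blink_rate
      x[blink] <- NaN
      y[blink] <- NaN
      valid[i, ] <- !blink
      X[i, ] <- x
      Y[i, ] <- y
    }
    structure(
      list(
        trials = trials, x = X, y = Y, valid = valid, roi = roi,
        fs = spec$fs, period = period
      ),
      class = "gaze_data"
    )
  })
}
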