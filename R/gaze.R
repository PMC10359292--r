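#' Per-trial ROI occupancy proportions
#'
#' For each trial, the fraction of valid (non-blink) gaze samples falling
#' inside the ROI rectangle, boundary inclusive. Invalid samples are dropped
#' from both numerator and denominator; a trial without any valid sample
#' gets `NA` and is excluded downstream.
#'
#' @param gaze A `gaze_data` object from [simulate_gaze()] (or an
#'   equivalently shaped recording).
#' @param roi Optional ROI override, `c(xmin, xmax, ymin, ymax)`; defaults
#'   to the ROI stored in `gaze`.
#' @return The trial tibble with added columns `prop` and `n_valid`.
#' @export
roi_proportions <- function(gaze, roi = NULL) {
  stopifnot(inherits(gaze, "gaze_data"))
  roi <- roi %||% gaze$roi
  if (roi[2] <= roi[1] || roi[4] <= roi[3]) abort("ROI must have positive area.")
  inside <- gaze$x >= roi[1] & gaze$x <= roi[2] &
    gaze$y >= roi[3] & gaze$y <= roi[4]
  valid <- is.finite(gaze$x) & is.finite(gaze$y)
  n_valid <- rowSums(valid)
  hits <- rowSums(inside & valid, na.rm = TRUE)
  prop <- ifelse(n_valid > 0, hits / pmax(n_valid, 1), NA_real_)
  dplyr::mutate(gaze$trials, prop = prop, n_valid = n_valid,
                period = gaze$period)
}

#' Compare ROI occupancy between conditions
#'
#' Two-sided Welch t-test on per-trial ROI occupancy proportions between a
#' control and a drug condition. For the outcome period the comparison is
#' restricted to partner-rewarded trials, since gaze toward the partner is
#' only defined when the partner receives its reward.
#'
#' @param props Output of [roi_proportions()].
#' @param conditions Length-2 character vector, control condition first.
#' @return One-row tibble: condition means, `estimate` (control - drug),
#'   `statistic`, `df`, `p_value`, sample sizes.
#' @export
compare_roi_occupancy <- function(props, conditions = c("vehicle", "DCZ")) {
  d <- props[!is.na(props$prop), , drop = FALSE]
  if (all(d$period == "outcome") && "outcome" %in% names(d)) {
    d <- d[d$outcome == "partner", , drop = FALSE]
  }
  a <- d$prop[d$condition == conditions[1]]
  b <- d$prop[d$condition == conditions[2]]
  w <- welch_test(a, b)
  tibble(
    period = unique(d$period),
    mean_control = mean(a), mean_drug = mean(b),
    estimate = w$estimate, statistic = w$statistic, df = w$df,
    p_value = w$p_value, n_control = length(a), n_drug = length(b)
  )
}
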