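#' Derive a labelled child seed from a master seed
#'
#' Each simulation stage draws from its own RNG stream so that, e.g.,
#' regenerating gaze data does not perturb the lick traces of the same study.
#' Streams are derived deterministically from the master seed and a fixed
#' text label.
#'
#' @param seed Master integer seed.
#' @param label Character label of the consuming stage, e.g. `"licks"`.
#' @return An integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "licks")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) * 2654435 + h) %% 2147483629 + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
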