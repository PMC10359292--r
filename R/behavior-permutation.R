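#' Monte Carlo permutation test for an intervention effect on licking
#'
#' Tests whether the chronologically-paired licking modulation differs
#' between a control and a drug condition within one block. Preferred trials
#' are pooled across the two conditions, as are non-preferred trials; each
#' repetition randomly re-splits both pools into groups of the original
#' sizes, assigns them to simulated control/drug conditions, recomputes the
#' modulation per simulated condition exactly as for the observed data
#' (chronological sorting and pairing), and records the simulated
#' intervention effect (simulated control minus simulated drug). The
#' re-split destroys both the chronological pairing and the condition
#' labels, which is the null hypothesis of no intervention effect.
#'
#' The two-sided Monte Carlo p-value is `2 * min(tail proportions)` with
#' add-one smoothing, `(1 + #{sim >= obs}) / (n_perm + 1)` per tail. The
#' one-line criterion used in reporting (observed effect above the 97.5th
#' percentile of the simulated distribution) is returned as a flag.
#'
#' @param data Tibble for one block, both conditions, with columns `block`,
#'   `condition`, `p_self`, `p_partner`, `trial_index` and the response in
#'   `value_col`.
#' @param n_perm Number of permutations. Default 1000.
#' @param seed Integer seed (required: the test is Monte Carlo).
#' @param conditions Length-2 character vector, control condition first.
#' @param value_col Response column name. Default `"lick_z"`.
#' @return A `lick_perm_test` object; see [tidy.lick_perm_test()].
#' @export
lick_permutation_test <- function(data, n_perm = 1000, seed,
                                  conditions = c("vehicle", "DCZ"),
                                  value_col = "lick_z") {
  if (missing(seed)) abort("`seed` is required for a reproducible test.")
  if (n_perm < 100) warn("`n_perm` < 100 gives a coarse p-value.")
  stopifnot(length(conditions) == 2)
  d1 <- data[data$condition == conditions[1], , drop = FALSE]
  d2 <- data[data$condition == conditions[2], , drop = FALSE]
  if (nrow(d1) == 0 || nrow(d2) == 0) abort("Both conditions must be present.")
  g1 <- preference_groups(d1)
  g2 <- preference_groups(d2)
  for (g in list(g1, g2)) {
    if (nrow(g$preferred) == 0 || nrow(g$nonpreferred) == 0) {
      abort("Each condition needs preferred and non-preferred trials.")
    }
  }
  mod1 <- mean(paired_differences(d1, value_col))
  mod2 <- mean(paired_differences(d2, value_col))
  observed <- mod1 - mod2

  # Pools keep (value, chronological index); sizes of the original groups.
  pool_pref <- rbind(
    pick_vi(g1$preferred, value_col), pick_vi(g2$preferred, value_col)
  )
  pool_nonp <- rbind(
    pick_vi(g1$nonpreferred, value_col), pick_vi(g2$nonpreferred, value_col)
  )
  n1p <- nrow(g1$preferred)
  n1n <- nrow(g1$nonpreferred)
  sim <- with_seed(derive_seed(seed, "perm"), {
    vapply(seq_len(n_perm), function(r) {
      ip <- sample.int(nrow(pool_pref), n1p)
      iq <- sample.int(nrow(pool_nonp), n1n)
      m1 <- sim_modulation(pool_pref[ip, , drop = FALSE],
                           pool_nonp[iq, , drop = FALSE])
      m2 <- sim_modulation(pool_pref[-ip, , drop = FALSE],
                           pool_nonp[-iq, , drop = FALSE])
      m1 - m2
    }, numeric(1))
  })
  hi <- (1 + sum(sim >= observed)) / (n_perm + 1)
  lo <- (1 + sum(sim <= observed)) / (n_perm + 1)
  structure(
    list(
      modulation = setNames(c(mod1, mod2), conditions),
      observed_effect = observed,
      perm = sim,
      perm_p = min(1, 2 * min(hi, lo)),
      above_97_5 = observed > quantile(sim, 0.975, names = FALSE),
      welch = welch_test(paired_differences(d1, value_col),
                         paired_differences(d2, value_col)),
      n_pairs = c(
        min(nrow(g1$preferred), nrow(g1$nonpreferred)),
        min(nrow(g2$preferred), nrow(g2$nonpreferred))
      ),
      n_perm = n_perm, block = unique(data$block), conditions = conditions
    ),
    class = "lick_perm_test"
  )
}

pick_vi <- function(g, value_col) {
  cbind(value = g[[value_col]], index = g$trial_index)
}

# Modulation of a simulated condition: sort each group chronologically and
# pair positionally, truncating to the shorter group.
sim_modulation <- function(pref, nonp) {
  pv <- pref[order(pref[, "index"]), "value"]
  nv <- nonp[order(nonp[, "index"]), "value"]
  m <- min(length(pv), length(nv))
  mean(pv[seq_len(m)] - nv[seq_len(m)])
}

#' @export
print.lick_perm_test <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<lick_perm_test> block: %s\n",
      "  modulation %s = %.4f, %s = %.4f\n",
      "  observed effect = %.4f; permutation p = %.4g (%d permutations)\n",
      "  Welch p = %.4g\n"
    ),
    x$block, x$conditions[1], x$modulation[1], x$conditions[2],
    x$modulation[2], x$observed_effect, x$perm_p, x$n_perm, x$welch$p_value
  ))
  invisible(x)
}

#' Tidy a licking permutation test
#'
#' @param x A `lick_perm_test`.
#' @param ... Unused.
#' @return One row per condition with the observed modulation and pair
#'   count.
#' @export
tidy.lick_perm_test <- function(x, ...) {
  tibble(
    block = x$block, condition = x$conditions,
    modulation = unname(x$modulation), n_pairs = x$n_pairs
  )
}

#' One-row summary of a licking permutation test
#'
#' @param x A `lick_perm_test`.
#' @param ... Unused.
#' @export
glance.lick_perm_test <- function(x, ...) {
  tibble(
    block = x$block, observed_effect = x$observed_effect,
    perm_p = x$perm_p, above_97_5 = x$above_97_5,
    welch_p = x$welch$p_value, n_perm = x$n_perm
  )
}

#' Plot the simulated intervention-effect distribution
#'
#' Histogram of the permutation distribution with the observed effect marked
#' by an arrowhead-style vertical line, as conventionally shown for Monte
#' Carlo permutation tests.
#'
#' @param object A `lick_perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lick_perm_test <- function(object, ...) {
  df <- tibble(effect = object$perm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$observed_effect, colour = "red") +
    ggplot2::labs(
      x = "simulated intervention effect",
      y = "count",
      title = sprintf("%s block: permutation p = %.3g",
                      object$block, object$perm_p)
    )
}
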