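test_that("lick detection finds rising edges with a refractory period", {
  expect_identical(detect_licks(rep(0, 100)), integer(0))
  # one square pulse: a single event at its rising edge
  pulse <- c(rep(0, 20), rep(1, 10), rep(0, 70))
  expect_identical(detect_licks(pulse), 21L)
  # seven injected pulses at least a refractory period apart: brute-force
  # positions are the expected events
  starts <- c(10, 80, 150, 230, 300, 380, 460)
  tr <- rep(0, 520)
  for (s in starts) tr[s:(s + 5)] <- 1
  expect_identical(detect_licks(tr), as.integer(starts))
  # ripple within the refractory period is not double-counted
  ripple <- rep(0, 200)
  ripple[c(50:55, 70:75)] <- 1 # 20 ms apart < 50 ms refractory
  expect_identical(detect_licks(ripple), 50L)
  expect_error(detect_licks(rep(NA_real_, 10)), "NaN")
})

test_that("pooled z-scoring matches its arithmetic definition and an independent oracle", {
  # pooled baseline mean 2, SD 1, stimulus value 5 -> z = 3
  base <- c(1, 2, 3) # mean 2, sd 1
  expect_equal(dyadflow:::pooled_z(5, base), 3)
  expect_equal(dyadflow:::pooled_z(2, base), 0)
  expect_error(dyadflow:::pooled_z(1, c(2, 2, 2)), "zero variance")

  # 100 simulated trials against an independently coded two-pass oracle
  tr <- simulate_trials(
    task_config(trials_per_block = 99, blocks = "self-variable",
                conditions = "vehicle"),
    seed = 6
  )
  lk <- simulate_licks(tr, seed = 6)
  z <- lick_zscores(lk)
  base_counts <- stim_counts <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    ev <- detect_licks(lk$traces[i, ])
    base_counts[i] <- sum(ev >= 1 & ev <= 500)
    stim_counts[i] <- sum(ev >= 501 + 501 & ev <= 501 + 1000)
  }
  mu <- mean(base_counts / 0.5)
  s <- sd(base_counts / 0.5)
  expect_equal(z$lick_z, (stim_counts / 0.5 - mu) / s, tolerance = 1e-12)
})

test_that("the 3-MAD rule keeps and drops the right points", {
  expect_identical(mad_keep(c(1, 2, 3, 100)), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(mad_keep(rep(5, 6)))) # zero MAD: only the median kept
  x <- c(-2, -1, 0, 1, 2)
  expect_true(all(mad_keep(x))) # nothing beyond 3 MAD
  expect_error(mad_keep(numeric(0)), "empty")
})

test_that("Spearman association uses midranks and exact small-sample p-values", {
  s <- spearman_association(1:6, c(0.25, 0.25, 0.5, 0.5, 0.75, 0.75))
  expect_gt(s$rho, 0.9)
  # fixed n = 9 table: rho from exhaustive midrank computation
  vals <- 1:9
  probs <- rep(c(0.25, 0.5, 0.75), each = 3)
  r1 <- rank(vals)
  r2 <- rank(probs)
  rho_oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  s9 <- spearman_association(vals, probs)
  expect_equal(s9$rho, rho_oracle, tolerance = 1e-12)
  # perfectly increasing, untied map: rho exactly 1
  expect_equal(spearman_association(1:8, (1:8) / 10)$rho, 1)
  expect_warning(out <- spearman_association(rep(1, 5), 1:5), "undefined")
  expect_true(out$degenerate)
})

test_that("null Spearman associations stay below the critical value", {
  n_inside <- 0
  for (s in 1:200) {
    withr::with_seed(1000 + s, {
      z <- rnorm(1000)
      p <- sample(c(0.25, 0.5, 0.75), 1000, replace = TRUE)
    })
    if (abs(spearman_association(z, p)$rho) < 0.08) n_inside <- n_inside + 1
  }
  expect_gte(n_inside, 190) # >= 95% of 200 seeds
})

test_that("licking modulation pairs chronologically and truncates to the shorter group", {
  # identical sequences in both groups: modulation 0
  b0 <- make_block(c(1, 2, 3), c(1, 2, 3))
  expect_equal(licking_modulation(b0)$modulation, 0)
  # preferred [3, 5] vs non-preferred [1, 2, 9]: pairs (3-1), (5-2) -> 2.5
  b1 <- make_block(c(3, 5), c(1, 2, 9))
  m1 <- licking_modulation(b1)
  expect_equal(m1$modulation, 2.5)
  expect_equal(m1$n_pairs, 2)
  # chronological order, not input order, defines the pairing
  b2 <- make_block(c(5, 3), c(1, 2, 9), pref_index = c(2, 1))
  expect_equal(licking_modulation(b2)$modulation, 2.5)
  # antisymmetry under swapping the preferred and non-preferred labels:
  # in the self-variable block preference is reversed relative to the
  # partner-variable block, so relabelling flips the sign
  b3 <- make_block(c(3, 5), c(1, 2), block = "self-variable")
  b3_swapped <- make_block(c(1, 2), c(3, 5), block = "self-variable")
  expect_equal(licking_modulation(b3)$modulation,
               -licking_modulation(b3_swapped)$modulation)
  expect_error(licking_modulation(make_block(numeric(0), c(1, 2))), "required")
})

test_that("the generator produces positive self-block modulation", {
  hits <- 0
  for (s in 1:50) {
    tr <- simulate_trials(
      task_config(trials_per_block = 120, blocks = "self-variable",
                  conditions = "vehicle"),
      seed = 3000 + s
    )
    z <- lick_zscores(simulate_licks(tr, seed = 3000 + s))
    if (licking_modulation(z)$modulation > 0) hits <- hits + 1
  }
  expect_gte(hits, 47) # >= 95%-ish detection at 40 trials/group
})

test_that("Welch's test matches the closed form and handles identical samples", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  w <- welch_test(a, b)
  # closed-form Welch statistic and Satterthwaite df
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_oracle <- (mean(a) - mean(b)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                          (var(b) / length(b))^2 / (length(b) - 1))
  p_oracle <- 2 * pt(abs(t_oracle), df_oracle, lower.tail = FALSE)
  expect_equal(w$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(w$df, df_oracle, tolerance = 1e-10)
  expect_equal(w$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(welch_test(a, a)$p_value, 1)
})
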