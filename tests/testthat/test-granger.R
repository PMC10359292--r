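# Independent spectral oracle for the bivariate decomposition: computes the
# target spectrum and its intrinsic part from the transfer function written
# out long-hand (explicit 2x2 inversion, no shared code with the package).
biv_spectral_oracle <- function(A, sigma, freqs, fs, source = 1, target = 2) {
  vapply(freqs, function(f) {
    lam <- 2 * pi * f / fs
    P <- diag(2) + 0i
    for (k in seq_len(dim(A)[3])) P <- P - A[, , k] * exp(-1i * lam * k)
    det_p <- P[1, 1] * P[2, 2] - P[1, 2] * P[2, 1]
    H <- matrix(c(P[2, 2], -P[2, 1], -P[1, 2], P[1, 1]), 2) / det_p
    S <- H %*% sigma %*% Conj(t(H))
    psig <- sigma[source, source] -
      sigma[source, target]^2 / sigma[target, target]
    s_tt <- Re(S[target, target])
    intrinsic <- s_tt - Mod(H[target, source])^2 * psig
    log(s_tt) - log(intrinsic)
  }, numeric(1))
}

make_model <- function(A, sigma = NULL) {
  n <- dim(A)[1]
  if (is.null(sigma)) sigma <- diag(n)
  structure(
    list(A = A, sigma = sigma, order = dim(A)[3], n_ch = n,
         spectral_radius = dyadflow:::companion_spectral_radius(A)),
    class = "mvar_model"
  )
}

test_that("bivariate spectral GC matches the transfer-function oracle", {
  A <- array(c(0.5, 0.5, 0, 0.7), c(2, 2, 1)) # coupling 1 -> 2 of 0.5
  sigma <- matrix(c(1, 0.2, 0.2, 1.5), 2)
  m <- make_model(A, sigma)
  freqs <- gc_frequency_grid()
  sp <- spectral_gc(m, source = 1, target = 2, freqs = freqs)
  oracle <- biv_spectral_oracle(A, sigma, freqs, fs = 1000)
  expect_equal(sp$gc, oracle, tolerance = 1e-10)
  expect_true(all(sp$gc >= 0))
})

test_that("zero coupling gives identically zero spectral GC", {
  A <- array(c(0.5, 0, 0, 0.7), c(2, 2, 1))
  m <- make_model(A)
  sp <- spectral_gc(m, source = 1, target = 2)
  expect_lt(max(sp$gc), 1e-10)
  expect_equal(time_gc_model(m, source = 1, target = 2), 0,
               tolerance = 1e-10)
})

test_that("the spectral GC integrates to the time-domain GC (Geweke identity)", {
  fixtures <- list(
    list(A = array(c(0.5, 0.4, 0, 0.7), c(2, 2, 1)), sigma = diag(2)),
    list(A = array(c(0.9, 0.25, 0, 0.9), c(2, 2, 1)), sigma = diag(2)),
    list(
      A = array(c(0.4, 0.3, 0.1, 0.5, # lag 1
                  -0.2, 0.1, 0, -0.3), c(2, 2, 2)),
      sigma = matrix(c(1, 0.4, 0.4, 2), 2)
    )
  )
  grid <- seq(0, 500, length.out = 1025) # full Nyquist range
  for (fx in fixtures) {
    m <- make_model(fx$A, fx$sigma)
    sp <- spectral_gc(m, source = 1, target = 2, freqs = grid, fs = 1000)
    tg <- time_gc_model(m, source = 1, target = 2)
    expect_gt(tg, 0)
    expect_lt(abs(mean(sp$gc) - tg) / tg, 0.02)
  }
})

test_that("conditional GC reduces to bivariate when the extra channel is independent", {
  A <- array(0, c(3, 3, 1))
  A[1, 1, 1] <- 0.5
  A[2, 2, 1] <- 0.7
  A[2, 1, 1] <- 0.4
  A[3, 3, 1] <- 0.6
  m3 <- make_model(A)
  m2 <- make_model(A[1:2, 1:2, , drop = FALSE])
  grid <- gc_frequency_grid()
  cond <- spectral_gc(m3, source = 1, target = 2, conditioning = 3,
                      freqs = grid)
  biv <- spectral_gc(m2, source = 1, target = 2, freqs = grid)
  expect_equal(cond$gc, biv$gc, tolerance = 1e-8)
})

test_that("conditional GC removes mediated influence", {
  # chain 1 -> 3 -> 2: conditioning on the mediator kills the 1 -> 2 GC
  A <- array(0, c(3, 3, 1))
  diag(A[, , 1]) <- c(0.5, 0.5, 0.5)
  A[3, 1, 1] <- 0.5 # 1 -> 3
  A[2, 3, 1] <- 0.5 # 3 -> 2
  m <- make_model(A)
  grid <- gc_frequency_grid()
  cond <- spectral_gc(m, source = 1, target = 2, conditioning = 3,
                      freqs = grid)
  expect_lt(max(cond$gc, na.rm = TRUE), 1e-6)
  tgc <- time_gc_model(m, source = 1, target = 2, conditioning = 3)
  expect_lt(tgc, 1e-6)
})

test_that("the data-based GC F-test controls type-I error and has power", {
  null_rej <- 0
  n_runs <- 300
  for (s in seq_len(n_runs)) {
    withr::with_seed(900 + s, {
      x <- array(rnorm(2 * 1000), c(1, 2, 1000))
    })
    tt <- time_gc_test(x, source = 1, target = 2, order = 3)
    if (tt$p_value < 0.05) null_rej <- null_rej + 1
  }
  expect_gte(null_rej / n_runs, 0.02)
  expect_lte(null_rej / n_runs, 0.085)
  # power: coupling 0.5 at 11 trials x 250 samples
  A <- array(c(0.5, 0.5, 0, 0.7), c(2, 2, 1))
  detections <- 0
  for (s in 1:20) {
    withr::with_seed(950 + s, x <- sim_var(A, n = 250, n_trials = 11))
    tt <- time_gc_test(x, source = 1, target = 2, order = 3)
    if (tt$p_value < 0.05) detections <- detections + 1
    expect_gte(tt$gc, 0)
  }
  expect_gte(detections, 19) # >= 95% power
})

test_that("GC is invariant to nonsingular channel rescaling", {
  A <- array(c(0.5, 0.4, 0, 0.7), c(2, 2, 1))
  withr::with_seed(77, x <- sim_var(A, n = 400, n_trials = 5))
  x_scaled <- x
  x_scaled[, 1, ] <- 13 * x_scaled[, 1, ]
  x_scaled[, 2, ] <- 0.05 * x_scaled[, 2, ]
  t1 <- time_gc_test(x, source = 1, target = 2, order = 2)
  t2 <- time_gc_test(x_scaled, source = 1, target = 2, order = 2)
  expect_equal(t1$gc, t2$gc, tolerance = 1e-6)
  expect_equal(t1$f_stat, t2$f_stat, tolerance = 1e-6)
  m1 <- fit_mvar(x, 2)
  m2 <- fit_mvar(x_scaled, 2)
  s1 <- spectral_gc(m1, source = 1, target = 2)
  s2 <- spectral_gc(m2, source = 1, target = 2)
  expect_equal(s1$gc, s2$gc, tolerance = 1e-6)
})

test_that("Benjamini-Hochberg matches a brute-force step-up oracle", {
  bh_oracle <- function(p, q) {
    n <- length(p)
    o <- order(p)
    thresh <- which(p[o] <= q * seq_len(n) / n)
    reject <- rep(FALSE, n)
    if (length(thresh) > 0) reject[o[seq_len(max(thresh))]] <- TRUE
    reject
  }
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)))
  expect_false(any(fdr_bh(rep(1, 10))))
  for (s in 1:1000) {
    withr::with_seed(2000 + s, p <- runif(sample(3:30, 1))^sample(1:3, 1))
    expect_identical(fdr_bh(p, 0.05), bh_oracle(p, 0.05))
  }
})

test_that("session summaries compute exact proportions on a crafted example", {
  freqs <- c(2, 4)
  spectra <- tidyr::expand_grid(
    session = 1:2, condition = c("vehicle", "DCZ"),
    source = 1, target = c(3, 4), freq = freqs
  )
  # vehicle: both pairs significant at 2 Hz, one at 4 Hz; DCZ: none
  spectra$gc <- 0.1
  spectra$sig_at_freq <- with(
    spectra,
    condition == "vehicle" & (freq == 2 | (freq == 4 & target == 3))
  )
  res <- structure(list(
    pairs = NULL, spectra = spectra, freqs = freqs, direction = "forward",
    window_ms = c(1, 250), q = 0.05
  ), class = "gc_result")
  summ <- session_gc_summary(res)
  props <- summ$proportions
  expect_equal(props$prop[props$condition == "vehicle" & props$freq == 2],
               c(1, 1))
  expect_equal(props$prop[props$condition == "vehicle" & props$freq == 4],
               c(0.5, 0.5))
  expect_true(all(props$prop[props$condition == "DCZ"] == 0))
  expect_true(all(summ$freq_tests$prop_control >
                    summ$freq_tests$prop_drug))
  one_session <- res
  one_session$spectra <- spectra[spectra$session == 1, ]
  expect_error(session_gc_summary(one_session), "sessions")
})
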