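#' Frequency grid of the Granger causality analysis
#'
#' 0 to 128 Hz in 1.67-Hz steps (77 points; the last grid point is
#' 126.92 Hz since the step does not land exactly on 128).
#'
#' @param step Step, Hz. Default 1.67.
#' @param fmax Upper bound, Hz. Default 128.
#' @return Numeric vector of frequencies.
#' @export
gc_frequency_grid <- function(step = 1.67, fmax = 128) {
  seq(0, fmax, by = step)
}

# Transfer function H(f) = (I - sum_k A_k e^(-i 2 pi f k / fs))^(-1)
# at each frequency; returns n x n x n_freq complex array.
var_transfer <- function(A, freqs, fs) {
  n <- dim(A)[1]
  p <- dim(A)[3]
  H <- array(0i, c(n, n, length(freqs)))
  for (fi in seq_along(freqs)) {
    lam <- 2 * pi * freqs[fi] / fs
    Af <- diag(n) + 0i
    for (k in seq_len(p)) Af <- Af - A[, , k] * exp(-1i * lam * k)
    H[, , fi] <- solve(Af)
  }
  H
}

# Inverse transfer (no matrix inversion): I - sum_k A_k e^(-i lam k).
var_inverse_transfer <- function(A, freqs, fs) {
  n <- dim(A)[1]
  p <- dim(A)[3]
  B <- array(0i, c(n, n, length(freqs)))
  for (fi in seq_along(freqs)) {
    lam <- 2 * pi * freqs[fi] / fs
    Af <- diag(n) + 0i
    for (k in seq_len(p)) Af <- Af - A[, , k] * exp(-1i * lam * k)
    B[, , fi] <- Af
  }
  B
}

#' Spectral (Geweke) Granger causality from a fitted MVAR model
#'
#' Frequency-domain decomposition of the Granger causality from `source` to
#' `target` channels. With an empty conditioning set the classic bivariate
#' Geweke decomposition is used (the model must then contain exactly the
#' source and target). With a non-empty conditioning set the conditional
#' decomposition is computed: a reduced model of (target, conditioning) is
#' recovered from the full model's autocovariance sequence via Yule-Walker,
#' the full transfer function is premultiplied by the reduced model's
#' inverse transfer, and at each frequency
#' \deqn{f(\lambda) = \ln\frac{\det \Sigma^R_{xx}}{\det(\Sigma^R_{xx} -
#'   Q_{xy} \tilde\Sigma_{yy} Q_{xy}^*)}}
#' with \eqn{\tilde\Sigma_{yy}} the source innovation covariance partialled
#' on the remaining innovations.
#'
#' @param model An `mvar_model`.
#' @param source,target Channel indices within the model.
#' @param conditioning Channel indices conditioned on (possibly empty).
#' @param freqs Frequency grid, Hz. Default [gc_frequency_grid()].
#' @param fs Sampling rate, Hz. Default 1000.
#' @param red_order Order of the reduced model recovered from the
#'   autocovariances (conditional mode); default `NULL` chooses a lag depth
#'   at which the autocovariances have decayed.
#' @return Tibble: `freq`, `gc` (nonnegative; `NA` where the spectral
#'   density was numerically singular).
#' @export
spectral_gc <- function(model, source, target, conditioning = integer(0),
                        freqs = gc_frequency_grid(), fs = 1000,
                        red_order = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  if (length(conditioning) == 0) {
    if (model$n_ch != length(source) + length(target)) {
      abort(paste0(
        "Bivariate mode requires a model over exactly the source and ",
        "target channels; pass `conditioning` otherwise."
      ))
    }
    return(spectral_gc_bivariate(model, source, target, freqs, fs))
  }
  spectral_gc_conditional(model, source, target, conditioning, freqs, fs,
                          red_order)
}

spectral_gc_bivariate <- function(model, source, target, freqs, fs) {
  H <- var_transfer(model$A, freqs, fs)
  S2 <- model$sigma
  s <- source
  t_ <- target
  # source innovations partialled on target innovations
  psig <- S2[s, s] - S2[s, t_] %*% solve(S2[t_, t_]) %*% S2[t_, s]
  gc <- vapply(seq_along(freqs), function(fi) {
    Hf <- H[, , fi]
    Sf <- Hf %*% S2 %*% Conj(t(Hf))
    Stt <- Re(det_c(Sf[t_, t_, drop = FALSE]))
    intrinsic <- Sf[t_, t_, drop = FALSE] -
      Hf[t_, s, drop = FALSE] %*% psig %*% Conj(t(Hf[t_, s, drop = FALSE]))
    den <- Re(det_c(intrinsic))
    if (Stt <= 0 || den <= 0) return(NA_real_)
    max(0, log(Stt) - log(den))
  }, numeric(1))
  tibble(freq = freqs, gc = gc)
}

spectral_gc_conditional <- function(model, source, target, conditioning,
                                    freqs, fs, red_order = NULL) {
  x <- target
  y <- source
  z <- conditioning
  ord <- c(x, z, y) # target block first, source last
  nx <- length(x)
  nxz <- length(x) + length(z)
  if (is.null(red_order)) {
    rho <- min(model$spectral_radius, 0.99)
    red_order <- min(max(4 * model$order, ceiling(log(1e-9) / log(rho))), 200)
  }
  G <- autocov_from_mvar(model, red_order)
  Gr <- G[c(x, z), c(x, z), , drop = FALSE]
  red <- autocov_to_var(Gr, red_order)
  sig_r_xx <- red$sigma[seq_len(nx), seq_len(nx), drop = FALSE]
  S2 <- model$sigma[ord, ord]
  A_ord <- model$A[ord, ord, , drop = FALSE]
  yi <- (nxz + 1):length(ord)
  psig <- S2[yi, yi, drop = FALSE] -
    S2[yi, seq_len(nxz), drop = FALSE] %*%
    solve(S2[seq_len(nxz), seq_len(nxz), drop = FALSE]) %*%
    S2[seq_len(nxz), yi, drop = FALSE]
  HF <- var_transfer(A_ord, freqs, fs)
  BR <- var_inverse_transfer(red$A, freqs, fs)
  num <- Re(det_c(sig_r_xx))
  gc <- vapply(seq_along(freqs), function(fi) {
    Q_top <- BR[, , fi] %*% HF[seq_len(nxz), , fi]
    Q_xy <- Q_top[seq_len(nx), yi, drop = FALSE]
    den_m <- sig_r_xx - Q_xy %*% psig %*% Conj(t(Q_xy))
    den <- Re(det_c(den_m))
    if (num <= 0 || den <= 0) return(NA_real_)
    max(0, log(num) - log(den))
  }, numeric(1))
  tibble(freq = freqs, gc = gc)
}

det_c <- function(m) {
  if (length(m) == 1) return(m[1, 1])
  det(m)
}

#' Model-based time-domain Granger causality
#'
#' `ln(det Sigma_reduced / det Sigma_full)` restricted to the target block,
#' with the reduced model of (target, conditioning) recovered from the full
#' model's autocovariance sequence.
#'
#' @inheritParams spectral_gc
#' @return Scalar GC (nonnegative).
#' @export
time_gc_model <- function(model, source, target, conditioning = integer(0),
                          red_order = NULL) {
  x <- target
  z <- conditioning
  nx <- length(x)
  if (is.null(red_order)) {
    rho <- min(model$spectral_radius, 0.99)
    red_order <- min(max(4 * model$order, ceiling(log(1e-9) / log(rho))), 200)
  }
  G <- autocov_from_mvar(model, red_order)
  red <- autocov_to_var(G[c(x, z), c(x, z), , drop = FALSE], red_order)
  sig_r <- red$sigma[seq_len(nx), seq_len(nx), drop = FALSE]
  sig_f <- model$sigma[x, x, drop = FALSE]
  max(0, log(Re(det_c(sig_r))) - log(Re(det_c(sig_f))))
}

#' Data-based Granger causality F-test for one direction
#'
#' Nested OLS regressions of the target channel on its own (and
#' conditioning-channel) lags, with and without the source-channel lags,
#' over identical effective samples. `GC = ln(RSS_reduced / RSS_full)`; the
#' F-statistic uses the standard nested-model degrees of freedom.
#'
#' @param x Window data (trials x channels x samples array).
#' @param source,target,conditioning Channel indices.
#' @param order Model order (samples).
#' @return One-row tibble: `gc`, `f_stat`, `df1`, `df2`, `p_value`, `n_obs`.
#' @export
time_gc_test <- function(x, source, target, conditioning = integer(0),
                         order) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  chans <- c(target, conditioning, source)
  d <- var_design(x[, chans, , drop = FALSE], order)
  yi <- seq_along(target)
  Y <- d$Y[, yi, drop = FALSE]
  n_ch <- length(chans)
  src_cols <- as.vector(vapply(seq_len(order), function(k) {
    (k - 1) * n_ch + length(target) + length(conditioning) + seq_along(source)
  }, numeric(length(source))))
  X_full <- d$X
  X_red <- d$X[, -src_cols, drop = FALSE]
  rss_f <- rss_of(X_full, Y)
  rss_r <- rss_of(X_red, Y)
  N <- nrow(Y)
  k_full <- ncol(X_full)
  df1 <- length(src_cols)
  df2 <- N - k_full
  f_stat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  tibble(
    gc = max(0, log(rss_r / rss_f)),
    f_stat = f_stat, df1 = df1, df2 = df2,
    p_value = pf(f_stat, df1, df2, lower.tail = FALSE),
    n_obs = N
  )
}

rss_of <- function(X, Y) {
  B <- qr.coef(qr(X), Y)
  B[is.na(B)] <- 0
  sum((Y - X %*% B)^2)
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up false discovery rate control over a family of p-values.
#'
#' @param p Numeric p-values.
#' @param q FDR level. Default 0.05.
#' @return Logical rejection mask.
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04)) # all rejected at Q = 0.05
fdr_bh <- function(p, q = 0.05) {
  p.adjust(p, method = "BH") <= q
}
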