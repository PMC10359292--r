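# ---- design construction -------------------------------------------------

# Stack per-trial lagged regressions; rows never span trial boundaries.
# x: array trials x channels x samples (or channels x samples matrix).
# Returns Y (N x n), X (N x n*p_lags) using `trim` initial samples per trial
# (trim >= p_lags keeps effective samples identical across candidate orders).
var_design <- function(x, p, trim = p) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  stopifnot(trim >= p)
  n_tr <- dim(x)[1]
  n_ch <- dim(x)[2]
  n_s <- dim(x)[3]
  if (n_s - trim < 1) abort("Window too short for the requested model order.")
  rows_per <- n_s - trim
  Y <- matrix(0, n_tr * rows_per, n_ch)
  X <- matrix(0, n_tr * rows_per, n_ch * p)
  t_idx <- (trim + 1):n_s
  for (tr in seq_len(n_tr)) {
    block <- (tr - 1) * rows_per + seq_len(rows_per)
    xt <- t(x[tr, , , drop = TRUE])
    if (n_ch == 1) xt <- matrix(x[tr, 1, ], ncol = 1)
    Y[block, ] <- xt[t_idx, , drop = FALSE]
    for (k in seq_len(p)) {
      X[block, (k - 1) * n_ch + seq_len(n_ch)] <- xt[t_idx - k, , drop = FALSE]
    }
  }
  list(Y = Y, X = X, n_ch = n_ch, p = p)
}

# ---- fitting and order selection -----------------------------------------

#' Fit a multivariate vector autoregressive model by OLS
#'
#' Trials are treated as multiple realisations of one stationary process:
#' lagged regressions are built per trial and stacked, so no regression row
#' spans a trial boundary.
#'
#' @param x Array (trials x channels x samples) or matrix
#'   (channels x samples) of a stationary window.
#' @param order Model order p (>= 1), in samples.
#' @return An `mvar_model`: coefficient array `A` (n x n x p), residual
#'   covariance `sigma` (unbiased) and `sigma_ml`, effective sample count
#'   `n_obs`, the regressor condition number, and `spectral_radius` of the
#'   companion matrix.
#' @export
fit_mvar <- function(x, order) {
  stopifnot(order >= 1)
  d <- var_design(x, order)
  qrX <- qr(d$X)
  rank_deficient <- qrX$rank < ncol(d$X)
  B <- qr.coef(qrX, d$Y)
  # exactly collinear columns get NA coefficients; zero them (a valid
  # least-squares solution) and let the collinearity diagnostic exclude
  B[is.na(B)] <- 0
  res <- d$Y - d$X %*% B
  N <- nrow(d$Y)
  k <- ncol(d$X)
  sv <- svd(d$X, nu = 0, nv = 0)$d
  sv <- sv[sv > 0]
  A <- array(0, c(d$n_ch, d$n_ch, order))
  for (j in seq_len(order)) {
    A[, , j] <- t(B[(j - 1) * d$n_ch + seq_len(d$n_ch), , drop = FALSE])
  }
  structure(
    list(
      A = A, order = order, n_ch = d$n_ch,
      sigma = crossprod(res) / (N - k),
      sigma_ml = crossprod(res) / N,
      n_obs = N, rss = crossprod(res),
      cond_number = if (rank_deficient) Inf else sv[1] / sv[length(sv)],
      spectral_radius = companion_spectral_radius(A),
      residuals = res
    ),
    class = "mvar_model"
  )
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf(
    "<mvar_model> %d channels, order %d, %d obs; spectral radius %.3f\n",
    x$n_ch, x$order, x$n_obs, x$spectral_radius
  ))
  invisible(x)
}

#' Select the MVAR model order by AIC
#'
#' Fits every candidate order on identical effective samples (all
#' regressions discard `max_order` initial samples per trial) and minimises
#' `AIC(p) = N log det(Sigma_ML(p)) + 2 p n^2`.
#'
#' @param x Window data as in [fit_mvar()].
#' @param max_order Largest candidate order, samples. Default 50 (50 ms at
#'   1 kHz). Must be at most a fifth of the window length.
#' @return List: `order` (the minimiser), `aic` tibble over candidates.
#' @export
select_order <- function(x, max_order = 50) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  n_s <- dim(x)[3]
  if (max_order > n_s / 5) {
    abort("`max_order` exceeds a fifth of the window length.")
  }
  n_ch <- dim(x)[2]
  aic <- numeric(max_order)
  for (p in seq_len(max_order)) {
    d <- var_design(x, p, trim = max_order)
    B <- qr.coef(qr(d$X), d$Y)
    res <- d$Y - d$X %*% B
    N <- nrow(d$Y)
    sig <- crossprod(res) / N
    aic[p] <- N * log(det(sig)) + 2 * p * n_ch^2
  }
  list(
    order = which.min(aic),
    aic = tibble(order = seq_len(max_order), aic = aic)
  )
}

# ---- companion form and stability ----------------------------------------

companion_matrix <- function(A) {
  n <- dim(A)[1]
  p <- dim(A)[3]
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[seq_len(n), (k - 1) * n + seq_len(n)] <- A[, , k]
  if (p > 1) {
    comp[(n + 1):(n * p), seq_len(n * (p - 1))] <- diag(n * (p - 1))
  }
  comp
}

companion_spectral_radius <- function(A) {
  max(Mod(eigen(companion_matrix(A), only.values = TRUE)$values))
}

# ---- diagnostics ----------------------------------------------------------

#' Diagnose an MVAR fit for collinearity, nonstationarity and
#' heteroscedasticity
#'
#' Window data failing any diagnostic are excluded from Granger analysis.
#' Collinearity is flagged by the regressor condition number;
#' nonstationarity by the companion spectral radius approaching 1 or a
#' per-channel augmented Dickey-Fuller regression failing to reject a unit
#' root; heteroscedasticity by an ARCH LM test on the residuals.
#'
#' @param x Window data (as passed to [fit_mvar()]).
#' @param model The fitted `mvar_model`.
#' @param cond_limit Condition-number threshold. Default 1e10.
#' @param eps Stability margin: flagged when spectral radius >= 1 - eps.
#'   Default 0.02.
#' @param arch_lags ARCH test lag count. Default 10.
#' @param arch_alpha ARCH test level. Default 0.01.
#' @return Tibble of logical flags `collinear`, `nonstationary`,
#'   `heteroscedastic`, and `ok` (none flagged).
#' @export
run_diagnostics <- function(x, model, cond_limit = 1e10, eps = 0.02,
                            arch_lags = 10, arch_alpha = 0.01) {
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  collinear <- model$cond_number > cond_limit
  nonstat <- model$spectral_radius >= 1 - eps
  if (!nonstat) {
    adf <- vapply(seq_len(dim(x)[2]), function(ch) {
      adf_stat(x[, ch, , drop = TRUE])
    }, numeric(1))
    # tau critical value ~ -1.95 (5%, no-constant variant)
    nonstat <- any(adf > -1.95)
  }
  hetero <- FALSE
  for (ch in seq_len(ncol(model$residuals))) {
    if (arch_lm_p(model$residuals[, ch], arch_lags) < arch_alpha) {
      hetero <- TRUE
      break
    }
  }
  tibble(
    collinear = collinear, nonstationary = nonstat,
    heteroscedastic = hetero,
    ok = !(collinear || nonstat || hetero)
  )
}

# Augmented Dickey-Fuller t-statistic (no constant), lag order `lags`,
# pooled across trials (rows of `x` when a matrix).
adf_stat <- function(x, lags = 5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  ylist <- xlist <- list()
  for (tr in seq_len(nrow(x))) {
    s <- x[tr, ]
    dx <- diff(s)
    idx <- (lags + 1):length(dx)
    X <- cbind(s[idx], vapply(seq_len(lags), function(k) dx[idx - k],
                              numeric(length(idx))))
    ylist[[tr]] <- dx[idx]
    xlist[[tr]] <- X
  }
  y <- unlist(ylist)
  X <- do.call(rbind, xlist)
  fit <- stats::lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / (length(y) - ncol(X))
  se <- sqrt(s2 * solve(crossprod(X))[1, 1])
  fit$coefficients[1] / se
}

# ARCH LM test p-value: regress squared residuals on their own lags.
arch_lm_p <- function(e, lags = 10) {
  e2 <- e^2
  n <- length(e2)
  idx <- (lags + 1):n
  X <- cbind(1, vapply(seq_len(lags), function(k) e2[idx - k],
                       numeric(length(idx))))
  y <- e2[idx]
  fit <- stats::lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  stats::pchisq(length(y) * r2, df = lags, lower.tail = FALSE)
}
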