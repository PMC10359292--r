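#' Autocovariance sequence of a fitted MVAR model
#'
#' `Gamma_0` solves the discrete Lyapunov equation of the companion form
#' (computed by a doubling iteration); higher lags follow the recursion
#' `Gamma_k = sum_j A_j Gamma_(k-j)`. Lag-k autocovariance is
#' `E[x_t x_(t-k)']`.
#'
#' @param model An `mvar_model` (or a list with `A` and innovation
#'   covariance in `sigma`).
#' @param n_lags Number of lags beyond zero.
#' @return Array n x n x (n_lags + 1); slice k is `Gamma_(k-1)`.
#' @export
autocov_from_mvar <- function(model, n_lags) {
  A <- model$A
  n <- dim(A)[1]
  p <- dim(A)[3]
  rho <- companion_spectral_radius(A)
  if (rho >= 1) {
    abort(sprintf("Unstable model (spectral radius %.3f).", rho))
  }
  comp <- companion_matrix(A)
  Q <- matrix(0, n * p, n * p)
  Q[seq_len(n), seq_len(n)] <- model$sigma
  # doubling iteration for X = comp X comp' + Q
  X <- Q
  Ak <- comp
  for (it in 1:60) {
    X_new <- X + Ak %*% X %*% t(Ak)
    Ak <- Ak %*% Ak
    if (max(abs(X_new - X)) < 1e-14 * max(1, max(abs(X_new)))) {
      X <- X_new
      break
    }
    X <- X_new
  }
  G <- array(0, c(n, n, n_lags + 1))
  for (k in seq_len(min(p, n_lags + 1))) {
    G[, , k] <- X[seq_len(n), (k - 1) * n + seq_len(n)]
  }
  if (n_lags + 1 > p) {
    for (m in (p + 1):(n_lags + 1)) { # m-1 is the lag
      acc <- matrix(0, n, n)
      for (j in seq_len(p)) {
        lag <- (m - 1) - j
        acc <- acc + A[, , j] %*% gamma_at(G, lag)
      }
      G[, , m] <- acc
    }
  }
  G
}

# Gamma at possibly negative lag from the stored sequence.
gamma_at <- function(G, lag) {
  if (lag >= 0) G[, , lag + 1] else t(G[, , -lag + 1])
}

#' Solve Yule-Walker equations: VAR coefficients from an autocovariance
#' sequence
#'
#' Direct block-Toeplitz solve of
#' `Gamma_m = sum_j A_j Gamma_(m-j)`, m = 1..p, with innovation covariance
#' `Sigma = Gamma_0 - sum_j A_j Gamma_j'`. Used to obtain reduced
#' (sub-process) models from a full model's autocovariances.
#'
#' @param G Autocovariance array from [autocov_from_mvar()] (or compatible).
#' @param p Order of the VAR to solve for (needs `dim(G)[3] > p`).
#' @return List `A` (n x n x p), `sigma`.
#' @export
autocov_to_var <- function(G, p) {
  n <- dim(G)[1]
  if (dim(G)[3] < p + 1) abort("Autocovariance sequence shorter than order.")
  B <- matrix(0, n * p, n * p)
  R <- matrix(0, n, n * p)
  for (m in seq_len(p)) {
    R[, (m - 1) * n + seq_len(n)] <- G[, , m + 1]
    for (j in seq_len(p)) {
      B[(j - 1) * n + seq_len(n), (m - 1) * n + seq_len(n)] <-
        gamma_at(G, m - j)
    }
  }
  A_row <- R %*% solve(B)
  A <- array(0, c(n, n, p))
  sigma <- G[, , 1]
  for (j in seq_len(p)) {
    A[, , j] <- A_row[, (j - 1) * n + seq_len(n), drop = FALSE]
    sigma <- sigma - A[, , j] %*% t(G[, , j + 1])
  }
  list(A = A, sigma = (sigma + t(sigma)) / 2)
}
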