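# Shared oracles and generators for the test suite.

# random symmetric positive-definite matrix
random_psd <- function(D, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(D * D), D)
  crossprod(A) + diag(0.1, D)
}

# closed-form Kalman recursion for a linear-Gaussian system
#   x_k = A x_{k-1} + w,  w ~ N(0, Q);  y_k = H x_k + v,  v ~ N(0, R)
kalman_closed_form <- function(A, H, Q, R, y, m0, P0) {
  A <- as.matrix(A); H <- matrix(H, nrow = 1)
  Q <- as.matrix(Q); P <- as.matrix(P0)
  m <- m0
  n <- length(y)
  means <- matrix(NA_real_, n, length(m0))
  covs <- vector("list", n)
  for (k in seq_len(n)) {
    m_pr <- drop(A %*% m)
    P_pr <- A %*% P %*% t(A) + Q
    S <- drop(H %*% P_pr %*% t(H)) + R
    K <- P_pr %*% t(H) / S
    m <- m_pr + drop(K) * (y[k] - drop(H %*% m_pr))
    P <- P_pr - K %*% H %*% P_pr
    means[k, ] <- m
    covs[[k]] <- P
  }
  list(means = means, covs = covs)
}

# simulate a linear-Gaussian system
simulate_linear <- function(A, H, Q, R, n, m0, seed = 1) {
  set.seed(seed)
  A <- as.matrix(A)
  d <- nrow(A)
  L <- chol(as.matrix(Q) + diag(1e-12, d))
  x <- m0
  y <- numeric(n)
  for (k in seq_len(n)) {
    x <- drop(A %*% x) + drop(t(L) %*% rnorm(d))
    y[k] <- drop(matrix(H, 1) %*% x) + rnorm(1, 0, sqrt(R))
  }
  y
}

# direct transcription of the gating rate formulas (independent of the
# package's guarded implementation; valid away from the singular points)
rates_direct <- function(V) {
  c(alpha_m = 0.1 * (V + 30) / (1 - exp(-0.1 * (V + 30))),
    beta_m  = 4 * exp(-(V + 55) / 18),
    alpha_h = 0.07 * exp(-(V + 44) / 20),
    beta_h  = 1 / (1 + exp(-0.1 * (V + 14))),
    alpha_n = 0.01 * (V + 34) / (1 - exp(-0.1 * (V + 34))),
    beta_n  = 0.125 * exp(-(V + 44) / 80))
}

random_cell_state <- function(seed = 1) {
  set.seed(seed)
  c(V = runif(1, -90, 30), m = runif(1), h = runif(1), n = runif(1),
    Ca_i = runif(1, 0, 1), K_o = runif(1, 2, 12), Na_i = runif(1, 10, 30))
}
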