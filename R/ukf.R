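# Generic sigma-point (unscented) Kalman filter with equal weights.
# This pure-R implementation accepts arbitrary transition and observation
# closures; the compiled fast path in src/ specializes it to the neuron
# models and is tested against this one.

#' Equal-weight sigma points of a Gaussian belief
#'
#' For a D-dimensional belief (mean, covariance P) returns the 2D points
#' mean +/- columns of a matrix square root of D*P, each with implicit
#' weight 1/(2D).  Their sample mean equals the generating mean exactly
#' and their population covariance reproduces P.  A lower-triangular
#' Cholesky factor is used, with a symmetric-eigendecomposition fallback
#' after conditioning.
#'
#' @param mean numeric vector (length D).
#' @param cov D x D covariance matrix.
#' @param jitter relative eigenvalue floor used if factorization fails.
#' @return D x 2D matrix whose columns are the sigma points.
#' @export
sigma_points <- function(mean, cov, jitter = 1e-10) {
  D <- length(mean)
  cov <- as.matrix(cov)
  S <- tryCatch(t(chol(D * cov)), error = function(e) NULL)
  if (is.null(S)) {
    covc <- condition_covariance(cov, jitter = max(jitter, 1e-12))
    S <- tryCatch(t(chol(D * covc)), error = function(e) {
      e <- eigen(D * covc, symmetric = TRUE)
      e$vectors %*% diag(sqrt(pmax(e$values, 0)), D)
    })
  }
  if (is.null(S)) stop("matrix square root failed")
  cbind(mean + S, mean - S)
}

#' Symmetrize and floor a covariance matrix
#'
#' Returns (P + t(P))/2 with eigenvalues floored at
#' jitter * trace(P) / D.  Idempotent on already-valid input.
#'
#' @param P square matrix.
#' @param jitter relative floor.
#' @return conditioned covariance matrix.
#' @export
condition_covariance <- function(P, jitter = 1e-10) {
  P <- as.matrix(P)
  if (any(!is.finite(P))) stop("non-finite covariance entries")
  P <- (P + t(P)) / 2
  fl <- jitter * sum(diag(P)) / nrow(P)
  e <- eigen(P, symmetric = TRUE)
  if (min(e$values) >= fl) return(P)
  v <- pmax(e$values, fl)
  Pc <- e$vectors %*% (v * t(e$vectors))
  (Pc + t(Pc)) / 2
}

#' Prediction step of the sigma-point filter
#'
#' Propagates the sigma points of the current belief through the
#' transition function; the a-priori mean is their plain average and the
#' a-priori covariance their scatter plus the process noise Q.
#'
#' @param belief list(mean, cov).
#' @param transition function(state vector) -> propagated state vector.
#' @param Q process-noise covariance (D x D).
#' @param jitter conditioning floor.
#' @return list(mean, cov, sigma) where \code{sigma} holds the propagated
#'   sigma points (columns).
#' @export
ukf_predict <- function(belief, transition, Q, jitter = 1e-10) {
  X <- sigma_points(belief$mean, belief$cov, jitter)
  Xp <- apply(X, 2, transition)
  if (is.null(dim(Xp))) Xp <- matrix(Xp, nrow = 1)
  if (any(!is.finite(Xp))) {
    bad <- which(colSums(!is.finite(Xp)) > 0)[1]
    stop("sigma point ", bad, " diverged during propagation")
  }
  m <- rowMeans(Xp)
  Xc <- Xp - m
  P <- Xc %*% t(Xc) / ncol(Xp) + as.matrix(Q)
  list(mean = m, cov = condition_covariance(P, jitter), sigma = Xp)
}

#' Measurement update of the sigma-point filter
#'
#' Computes the predicted measurement mean, innovation covariance
#' (plus R), state-measurement cross covariance and Kalman gain, and
#' returns the posterior belief.  By default new sigma points are drawn
#' from the a-priori belief; setting \code{redraw = FALSE} reuses the
#' propagated points (cheaper, slightly less accurate).
#'
#' @param prior list(mean, cov) from [ukf_predict()].
#' @param sigma propagated sigma points (used when \code{redraw = FALSE}).
#' @param observation function(state vector) -> observation vector.
#' @param R measurement-noise covariance (scalar or matrix).
#' @param y observed value(s).
#' @param redraw draw fresh sigma points from the prior (default TRUE).
#' @param jitter conditioning floor.
#' @return list(mean, cov, gain, innovation, ypred).
#' @export
ukf_update <- function(prior, sigma, observation, R, y, redraw = TRUE,
                       jitter = 1e-10) {
  if (any(!is.finite(y))) stop("observation must be finite")
  X <- if (redraw) sigma_points(prior$mean, prior$cov, jitter) else sigma
  Y <- apply(X, 2, observation)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  ybar <- rowMeans(Y)
  Yc <- Y - ybar
  Xc <- X - prior$mean
  ns <- ncol(X)
  Pyy <- Yc %*% t(Yc) / ns + as.matrix(R)
  Pxy <- Xc %*% t(Yc) / ns
  K <- tryCatch(Pxy %*% solve(Pyy), error = function(e)
    stop("singular innovation covariance"))
  innov <- y - ybar
  mean_post <- prior$mean + drop(K %*% innov)
  cov_post <- prior$cov - K %*% Pyy %*% t(K)
  list(mean = mean_post, cov = condition_covariance(cov_post, jitter),
       gain = K, innovation = innov, ypred = ybar)
}

#' Run the sigma-point filter over an observation sequence (generic)
#'
#' Iterates [ukf_predict()] and [ukf_update()] over the columns/elements
#' of \code{y}.  This generic driver accepts arbitrary R closures and is
#' the reference implementation; model-based assimilation of voltage
#' traces uses the compiled specialization through [assimilate()].
#'
#' @param transition function(state) -> next state (one observation
#'   interval).
#' @param observation function(state) -> predicted observation.
#' @param y observations: vector (scalar case) or matrix with one column
#'   per time step.
#' @param Q,R process / measurement noise covariances.
#' @param belief0 list(mean, cov) initial belief.
#' @param redraw redraw sigma points at the update (default TRUE).
#' @param jitter conditioning floor.
#' @return list with \code{means} (steps x D), \code{covs} (list of D x D),
#'   \code{innovations}, \code{ypred}, \code{gains}.
#' @export
run_filter <- function(transition, observation, y, Q, R, belief0,
                       redraw = TRUE, jitter = 1e-10) {
  ymat <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  n <- ncol(ymat)
  D <- length(belief0$mean)
  means <- matrix(NA_real_, n, D)
  covs <- vector("list", n)
  innovations <- matrix(NA_real_, nrow(ymat), n)
  ypred <- matrix(NA_real_, nrow(ymat), n)
  gains <- numeric(n)
  belief <- belief0
  for (k in seq_len(n)) {
    prior <- ukf_predict(belief, transition, Q, jitter)
    upd <- ukf_update(prior, prior$sigma, observation, R, ymat[, k],
                      redraw = redraw, jitter = jitter)
    belief <- list(mean = upd$mean, cov = upd$cov)
    means[k, ] <- upd$mean
    covs[[k]] <- upd$cov
    innovations[, k] <- upd$innovation
    ypred[, k] <- upd$ypred
    gains[k] <- sqrt(sum(upd$gain^2))
  }
  list(means = means, covs = covs, innovations = drop(innovations),
       ypred = drop(ypred), gains = gains)
}
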