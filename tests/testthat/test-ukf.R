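test_that("sigma points match the scalar case and the generating moments", {
  X <- sigma_points(0, matrix(1, 1, 1))
  expect_equal(sort(as.numeric(X)), c(-1, 1), tolerance = 1e-12)
  # sample mean equals the input mean exactly, covariance to 1e-8 relative
  for (D in c(2, 3, 5, 10, 30)) {
    P <- random_psd(D, seed = D)
    m <- rnorm(D)
    X <- sigma_points(m, P)
    expect_identical(dim(X), as.integer(c(D, 2 * D)))
    expect_equal(rowMeans(X), m, tolerance = 1e-10)
    Xc <- X - m
    Phat <- Xc %*% t(Xc) / ncol(X)
    expect_lt(max(abs(Phat - P)) / max(abs(P)), 1e-8)
  }
})

test_that("covariance conditioning symmetrizes, floors and is idempotent", {
  P <- random_psd(4, seed = 2)
  expect_equal(condition_covariance(P), P, tolerance = 1e-15)
  # asymmetric perturbation is removed exactly
  Pa <- P
  Pa[1, 2] <- Pa[1, 2] + 1e-3
  Pc <- condition_covariance(Pa)
  expect_identical(Pc, t(Pc))
  # a slightly negative eigenvalue is raised to the floor
  e <- eigen(P, symmetric = TRUE)
  vals <- e$values
  vals[4] <- -1e-14
  Pneg <- e$vectors %*% (vals * t(e$vectors))
  Pfix <- condition_covariance(Pneg, jitter = 1e-10)
  ev <- eigen(Pfix, symmetric = TRUE)$values
  expect_gte(min(ev), 1e-10 * sum(diag(Pfix)) / 4 * (1 - 1e-8))
  expect_error(condition_covariance(matrix(c(1, NA, NA, 1), 2)), "finite")
})

test_that("prediction step is exact on linear maps and preserves parameters", {
  belief <- list(mean = c(1, -2), cov = random_psd(2, seed = 5))
  # identity transition with Q = 0 returns the belief unchanged
  pr <- ukf_predict(belief, identity, diag(0, 2))
  expect_equal(pr$mean, belief$mean, tolerance = 1e-10)
  expect_equal(pr$cov, belief$cov, tolerance = 1e-8)
  # general linear map: mean -> A m, cov -> A P A' + Q
  A <- matrix(c(0.9, 0.2, -0.1, 0.8), 2)
  Q <- diag(c(0.1, 0.2))
  pr2 <- ukf_predict(belief, function(x) drop(A %*% x), Q)
  expect_equal(pr2$mean, drop(A %*% belief$mean), tolerance = 1e-8)
  expect_equal(pr2$cov, A %*% belief$cov %*% t(A) + Q, tolerance = 1e-8)
  # components with trivial dynamics come through every sigma point intact
  trans <- function(x) c(x[1] * 0.5, x[2], x[3])
  b3 <- list(mean = c(1, 2, 3), cov = diag(c(1, 2, 3)))
  pr3 <- ukf_predict(b3, trans, diag(0, 3))
  X <- sigma_points(b3$mean, b3$cov)
  expect_identical(pr3$sigma[2:3, ], X[2:3, ])
  expect_error(ukf_predict(b3, function(x) c(Inf, x[2], x[3]), diag(0, 3)),
               "diverged")
})

test_that("measurement update reproduces the analytic Kalman gain", {
  prior <- list(mean = 2, cov = matrix(4, 1, 1))
  X <- sigma_points(prior$mean, prior$cov)
  # scalar linear observation: gain = P/(P+R)
  for (R in c(0.5, 2, 10)) {
    up <- ukf_update(prior, X, function(x) x[1], R, y = 3)
    expect_equal(as.numeric(up$gain), 4 / (4 + R), tolerance = 1e-10)
    expect_equal(up$mean, 2 + 4 / (4 + R) * 1, tolerance = 1e-10)
  }
  # uninformative observation: gain ~ 0, posterior ~ prior
  up_big <- ukf_update(prior, X, function(x) x[1], 1e12, y = 50)
  expect_lt(abs(as.numeric(up_big$gain)), 1e-10)
  expect_equal(up_big$mean, prior$mean, tolerance = 1e-6)
  # informative observation pins the observed component near y
  b <- list(mean = c(0, 1), cov = diag(c(4, 4)))
  Xb <- sigma_points(b$mean, b$cov)
  up_tiny <- ukf_update(b, Xb, function(x) x[1], 1e-6, y = 1.7)
  expect_lt(abs(up_tiny$mean[1] - 1.7), 3e-3)
  expect_error(ukf_update(prior, X, function(x) x[1], 0.5, y = NaN), "finite")
})

test_that("filter equals the closed-form Kalman recursion on linear systems", {
  # scalar
  A <- 0.95; H <- 1; Q <- 0.04; R <- 0.25
  y <- simulate_linear(A, H, Q, R, 100, 0, seed = 11)
  cf <- kalman_closed_form(A, H, Q, R, y, 0, matrix(1))
  uk <- run_filter(function(x) A * x, function(x) x[1], y,
                   matrix(Q), matrix(R), list(mean = 0, cov = matrix(1)))
  expect_lt(max(abs(uk$means - cf$means)), 1e-8)
  # 2-D oscillator observed in one component
  th <- 0.1
  A2 <- 0.98 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Q2 <- diag(c(0.02, 0.02)); R2 <- 0.3
  y2 <- simulate_linear(A2, c(1, 0), Q2, R2, 100, c(1, 0), seed = 12)
  cf2 <- kalman_closed_form(A2, c(1, 0), Q2, R2, y2, c(1, 0), diag(2))
  uk2 <- run_filter(function(x) drop(A2 %*% x), function(x) x[1], y2,
                    Q2, matrix(R2), list(mean = c(1, 0), cov = diag(2)))
  expect_lt(max(abs(uk2$means - cf2$means)), 1e-8)
  for (k in c(1, 50, 100))
    expect_lt(max(abs(uk2$covs[[k]] - cf2$covs[[k]])), 1e-8)
})

test_that("innovations on the linear benchmark are white", {
  A <- 0.9; Q <- 0.04; R <- 0.25
  y <- simulate_linear(A, 1, Q, R, 1000, 0, seed = 21)
  uk <- run_filter(function(x) A * x, function(x) x[1], y,
                   matrix(Q), matrix(R), list(mean = 0, cov = matrix(1)))
  r1 <- acf(uk$innovations, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.1)
})

test_that("skipping the redraw is exact without process noise, approximate with it", {
  A <- 0.95; R <- 0.25
  y <- simulate_linear(A, 1, 0.04, R, 50, 0, seed = 31)
  # with Q = 0 the propagated points already carry the prior scatter,
  # so skipping the redraw changes nothing
  cf0 <- kalman_closed_form(A, 1, 0, R, y, 0, matrix(1))
  uk0 <- run_filter(function(x) A * x, function(x) x[1], y, matrix(0),
                    matrix(R), list(mean = 0, cov = matrix(1)),
                    redraw = FALSE)
  expect_lt(max(abs(uk0$means - cf0$means)), 1e-8)
  # with Q > 0 the reused points miss the process-noise inflation in the
  # cross covariance: cheaper, close, but not exact
  cf <- kalman_closed_form(A, 1, 0.04, R, y, 0, matrix(1))
  uk <- run_filter(function(x) A * x, function(x) x[1], y, matrix(0.04),
                   matrix(R), list(mean = 0, cov = matrix(1)),
                   redraw = FALSE)
  expect_gt(max(abs(uk$means - cf$means)), 1e-8)
  expect_lt(max(abs(uk$means - cf$means)), 0.2)
})

test_that("compiled model filter agrees with the generic R implementation", {
  par <- neuron_params()
  init <- resting_state(par)
  init["V"] <- -60
  traj <- simulate_neuron(par, duration = 10, dt = 0.01, init = init,
                          record_every_ms = 0.1)
  trace <- make_observations(traj, 0.1, noise_sd = 0.5, seed = 5)
  x0 <- init
  x0["V"] <- trace$v_mV[1]
  x0["Ca_i"] <- 0.01   # away from the Ca >= 0 boundary
  # spreads kept small enough that the compiled path's physical-domain
  # clamps never engage, so the two implementations follow the same math
  q <- c(0.1, rep(1e-4, 3), 1e-5, 1e-4, 1e-4)
  p0 <- c(1, rep(0.002, 3), 0.002, 0.1, 0.5)
  fit_cpp <- assimilate(trace, "pc_full", params = par, init_mean = x0,
                        q_sd = setNames(q, names(init)),
                        p0_sd = setNames(p0, names(init)), jitter = 1e-10)
  # generic path: R closures around the R integrator
  trans <- function(x) {
    names(x) <- names(init)
    drop(tail(integrate_fixed(function(t, s) rhs_single_cell(s, par),
                              x, 0.1, 0.01)$states, 1))
  }
  ref <- run_filter(trans, function(x) x[1], trace$v_mV,
                    diag(q^2), matrix(0.25),
                    list(mean = unname(x0), cov = diag(p0^2)),
                    jitter = 1e-10)
  expect_lt(max(abs(fit_cpp$means - ref$means)), 1e-5)
  expect_lt(max(abs(fit_cpp$innovations - ref$innovations)), 1e-5)
})

test_that("posterior covariances stay positive semi-definite through a fit", {
  fx <- spiking_pc_fixture(seed = 3, duration = 300, onset = 50,
                           pulse_ms = 200)
  fit <- assimilate(fx$trace, "pc_full", params = fx$params,
                    protocol = fx$protocol, psd_check = TRUE)
  expect_true(all(fit$min_eig > -1e-10))
})

test_that("tracked parameters follow trivial dynamics through prediction", {
  fx <- spiking_pc_fixture(seed = 4, duration = 100, onset = 20,
                           pulse_ms = 60)
  # zero process noise and zero initial uncertainty freeze the parameter
  # (up to the covariance conditioning floor, which re-injects a tiny
  # spread each step)
  fit <- assimilate(fx$trace, "pc_full", params = fx$params,
                    protocol = fx$protocol, track = "g_Na",
                    q_sd = c(g_Na = 0), p0_sd = c(g_Na = 0), jitter = 0)
  expect_true(all(abs(fit$tracked[, "g_Na"] - 100) < 0.1))
})

test_that("parameter transform round-trips through the augmented state", {
  fx <- spiking_pc_fixture(seed = 5, duration = 50, onset = 10,
                           pulse_ms = 30)
  fit <- assimilate(fx$trace, "pc_full", params = fx$params,
                    protocol = fx$protocol,
                    track = c("G_glia", "eps", "K_bath"))
  expect_identical(colnames(fit$means)[8:10], c("G_glia", "eps", "K_bath"))
  expect_equal(unname(fit$tracked[1, ]),
               unname(exp(fit$means[1, 8:10])), tolerance = 1e-12)
  expect_error(assimilate(fx$trace, "pc_full", track = "not_a_param"),
               "unknown parameter")
})
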