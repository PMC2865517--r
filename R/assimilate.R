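# The user-facing model-fitting interface: joint state-and-parameter
# estimation from a voltage trace by the sigma-point filter, specialized
# to the compiled neuron models.

model_table <- function(model) {
  switch(model,
         pc_full     = list(model = 0L, mode = 0L, dyn = .state_names_single),
         pc_fixed_ions = list(model = 0L, mode = 1L, dyn = .state_names_single),
         pc_crippled = list(model = 0L, mode = 2L, dyn = .state_names_single),
         pair        = list(model = 1L, mode = 0L, dyn = .state_names_pair),
         stop("unknown model variant: ", model))
}

default_q_sd <- function(dyn, track, model) {
  q <- rep(1e-3, length(dyn))
  names(q) <- dyn
  q[grep("(^|_)V$", dyn)] <- 0.5
  q[dyn %in% c("m", "h", "n") | grepl("_(m|h|n)$", dyn)] <- 0.02
  q[grep("Ca_i", dyn)] <- 1e-4
  q[grep("K_o", dyn)] <- 5e-3
  q[grep("Na_i", dyn)] <- 2e-3
  q[dyn %in% c("s_p", "s_i")] <- 0.01
  q[dyn %in% c("eta_p", "eta_i")] <- 1e-3
  qt <- rep(1e-3, length(track))
  names(qt) <- track
  c(q, qt)
}

default_p0_sd <- function(dyn, track, transform) {
  p <- rep(0.1, length(dyn))
  names(p) <- dyn
  p[grep("(^|_)V$", dyn)] <- 5
  p[dyn %in% c("m", "h", "n") | grepl("_(m|h|n)$", dyn)] <- 0.1
  p[grep("Ca_i", dyn)] <- 0.05
  p[grep("K_o", dyn)] <- 0.5
  p[grep("Na_i", dyn)] <- 1
  p[dyn %in% c("s_p", "s_i", "eta_p", "eta_i")] <- 0.1
  pt <- ifelse(transform == "log", 0.3, 1)
  if (length(track)) names(pt) <- track
  c(p, pt)
}

#' Assimilate a voltage trace with a biophysical neuron model
#'
#' Fuses a single noisy membrane-potential recording with one of the
#' conductance-based models through the equal-weight sigma-point filter,
#' jointly estimating all unobserved state variables and any tracked
#' parameters (introduced as extra state components with trivial
#' dynamics).  This is the package's central fitting function; it returns
#' a \code{"ukf_fit"} object with the usual modelling methods
#' (\code{print}, \code{summary}, \code{coef}, \code{predict},
#' \code{residuals}, \code{fitted}, \code{plot}, \code{simulate}).
#'
#' @param trace data frame with columns \code{time_ms} (uniform grid) and
#'   \code{v_mV}, as produced by the fixtures or [read_trace()].
#' @param model model variant: \code{"pc_full"} (single cell with dynamic
#'   ion concentrations), \code{"pc_fixed_ions"} (concentrations pinned),
#'   \code{"pc_crippled"} (alpha_m replaced by a constant, normally
#'   tracked), or \code{"pair"} (coupled PC-IN).
#' @param params parameter bundle ([neuron_params()] or [pair_params()]);
#'   defaults to the physiological defaults for the chosen variant.
#' @param track character vector of tracked parameter names; unprefixed
#'   names refer to the (single/pyramidal) cell, \code{"in."} and
#'   \code{"syn."} prefixes to the interneuron and synapse blocks.
#' @param param_init named numeric, initial guesses for tracked
#'   parameters; defaults to their values in \code{params}.
#' @param transform named character ("log"/"identity") per tracked
#'   parameter; positive-scale parameters default to "log".
#' @param observe which cell's potential the trace observes (pair model).
#' @param q_sd named per-component process-noise SDs (native scale for
#'   state, transformed scale for parameters); unnamed entries fall back
#'   to documented defaults.
#' @param R measurement-noise variance (mV^2); default: the trace's
#'   noise-SD attribute squared, else 0.25.
#' @param init_mean initial mean for the dynamic state; defaults to a
#'   near-resting state with V taken from the first observation.
#' @param p0_sd named per-component initial-uncertainty SDs.
#' @param dt model integration substep (ms); the observation interval
#'   must be an integer multiple of it.
#' @param protocol,protocol_in stimulus protocols assumed known to the
#'   filter (applied current is part of the experiment design).
#' @param pin pinned concentrations for \code{"pc_fixed_ions"}.
#' @param redraw redraw sigma points before the measurement update
#'   (default TRUE); skipping is cheaper but slightly less accurate.
#' @param jitter relative eigenvalue floor for covariance conditioning.
#' @param psd_check record the minimum eigenvalue of every posterior
#'   covariance (costs one symmetric eigendecomposition per step).
#' @return An object of class \code{"ukf_fit"}.
#' @examples
#' fx <- spiking_pc_fixture(seed = 1, duration = 120, onset = 20,
#'                          pulse_ms = 100)
#' fit <- assimilate(fx$trace, "pc_full", protocol = fx$protocol)
#' summary(fit)
#' @export
assimilate <- function(trace, model = "pc_full", params = NULL,
                       track = character(), param_init = NULL,
                       transform = NULL, observe = c("pc", "in"),
                       q_sd = NULL, R = NULL, init_mean = NULL, p0_sd = NULL,
                       dt = 0.01, protocol = NULL, protocol_in = NULL,
                       pin = c(K_o = 4, Na_i = 18), redraw = TRUE,
                       jitter = 1e-8, psd_check = FALSE) {
  mt <- model_table(model)
  observe <- match.arg(observe)
  if (!all(c("time_ms", "v_mV") %in% names(trace)))
    stop("trace must have columns time_ms and v_mV")
  y <- trace$v_mV
  dt_obs <- trace$time_ms[2] - trace$time_ms[1]
  n_sub <- check_interval(dt_obs, dt)

  if (is.null(params))
    params <- if (mt$model == 1L) pair_params() else neuron_params()
  if (is.null(R)) {
    nsd <- attr(trace, "noise_sd")
    R <- if (!is.null(nsd) && nsd > 0) nsd^2 else 0.25
  }

  # parameter blocks
  if (mt$model == 1L) {
    ppc <- pack_cell_pars(params$pc$cell, params$pc$env)
    pinr <- pack_cell_pars(params$int$cell, params$int$env)
    psn <- pack_syn_pars(params$syn, delta = params$pc$env$delta)
    stim <- pack_stim(protocol, protocol_in,
                      base_pc = params$pc$cell$I_stim,
                      base_in = params$int$cell$I_stim)
    obs_index <- if (observe == "pc") 0L else 7L
  } else {
    alpha0 <- if (!is.null(param_init) && "alpha_m" %in% names(param_init))
      param_init[["alpha_m"]] else 1
    ppc <- pack_cell_pars(params$cell, params$env, alpha_m = alpha0,
                          pin_K_o = pin[["K_o"]], pin_Na_i = pin[["Na_i"]])
    pinr <- ppc
    psn <- pack_syn_pars(synapse_params())
    stim <- pack_stim(protocol, base_pc = params$cell$I_stim)
    obs_index <- 0L
  }

  tracked_idx <- resolve_tracked(track, model)
  if (is.null(transform)) transform <- default_transforms(track)
  transform <- transform[track]
  log_flags <- transform == "log"

  # initial parameter guesses on the transformed scale
  all_pars <- c(ppc, pinr, psn)
  par0_nat <- vapply(seq_along(track), function(j) {
    nm <- track[j]
    if (!is.null(param_init) && nm %in% names(param_init))
      param_init[[nm]] else all_pars[[tracked_idx[j] + 1L]]
  }, numeric(1))
  par0 <- ifelse(log_flags, log(par0_nat), par0_nat)

  dyn <- mt$dyn
  if (is.null(init_mean)) {
    if (mt$model == 1L) {
      rest <- c(V = y[1], gating_steady_state(y[1]), Ca_i = 0.01,
                K_o = params$pc$env$K_bath, Na_i = 18)
      init_mean <- c(rest, rest, 0.1, 0.1, 0.1, 0.1)
      names(init_mean) <- dyn
      init_mean["in_K_o"] <- params$int$env$K_bath
    } else {
      v0 <- min(max(y[1], -90), -40)
      init_mean <- c(V = v0, gating_steady_state(v0), Ca_i = 0.01,
                     K_o = params$env$K_bath, Na_i = 18)
      names(init_mean) <- dyn
      if (mt$mode == 1L) {
        init_mean["K_o"] <- pin[["K_o"]]
        init_mean["Na_i"] <- pin[["Na_i"]]
      }
    }
  }
  q_def <- default_q_sd(dyn, track, model)
  if (!is.null(q_sd)) q_def[names(q_sd)] <- q_sd
  p_def <- default_p0_sd(dyn, track, transform)
  if (!is.null(p0_sd)) p_def[names(p0_sd)] <- p0_sd
  if (mt$mode == 1L) {        # pinned concentrations stay pinned
    fixed <- c("K_o", "Na_i")
    q_def[fixed] <- 0
    p_def[fixed] <- 0
  }

  D <- length(dyn) + length(track)
  x0 <- c(init_mean[dyn], par0)
  Q <- diag(q_def^2, D)
  P0 <- diag(p_def^2, D)
  # generous transformed-scale box keeping tracked parameters finite
  par_lo <- par0 - 6
  par_hi <- par0 + 6

  t_elapsed <- system.time(
    res <- cpp_ukf(y, trace$time_ms[1], dt_obs, n_sub, dt, mt$model, mt$mode,
                   ppc, pinr, psn, stim, obs_index,
                   as.integer(tracked_idx), log_flags,
                   as.numeric(x0), P0, Q, R, redraw, jitter, psd_check,
                   as.numeric(par_lo), as.numeric(par_hi))
  )[["elapsed"]]

  comp_names <- c(dyn, track)
  colnames(res$means) <- comp_names
  colnames(res$sds) <- comp_names
  tracked_nat <- NULL
  if (length(track)) {
    tracked_nat <- res$means[, track, drop = FALSE]
    for (j in seq_along(track))
      if (log_flags[j]) tracked_nat[, j] <- exp(tracked_nat[, j])
  }
  fit <- structure(list(
    means = res$means, sds = res$sds, innovations = drop(res$innovations),
    ypred = drop(res$ypred), gain_norm = drop(res$gain_norm),
    min_eig = drop(res$min_eig), P_final = res$P_final,
    tracked = tracked_nat, track = track, transform = transform,
    model = model, observe = observe, obs_index = obs_index,
    trace = trace, time = trace$time_ms[seq_len(nrow(res$means))],
    R = R, Q = Q, P0 = P0, dt = dt, n_sub = n_sub,
    params = params, protocol = protocol, pin = pin,
    converged = isTRUE(res$ok), err_step = res$err_step,
    runtime_s = t_elapsed), class = "ukf_fit")
  if (!res$ok)
    warning("filter diverged at observation ", res$err_step,
            "; partial result returned")
  fit
}

#' @export
print.ukf_fit <- function(x, ...) {
  cat("Sigma-point filter fit (", x$model, "), ",
      length(x$innovations), " observations\n", sep = "")
  cat("  innovation RMS: ", format(sqrt(mean(x$innovations^2)), digits = 4),
      " mV (R = ", format(x$R, digits = 3), " mV^2)\n", sep = "")
  if (length(x$track)) {
    cat("  tracked parameters (terminal):\n")
    print(signif(coef(x), 4))
  }
  invisible(x)
}

#' @export
coef.ukf_fit <- function(object, ...) {
  if (!length(object$track)) return(numeric(0))
  est <- object$tracked[nrow(object$tracked), ]
  setNames(as.numeric(est), object$track)
}

#' @export
residuals.ukf_fit <- function(object, ...) object$innovations

#' @export
fitted.ukf_fit <- function(object, ...) {
  object$means[, object$obs_index + 1L]
}

#' Predicted (a-priori) observations of a fit
#' @param object a \code{"ukf_fit"}.
#' @param ... unused.
#' @return numeric vector of one-step-ahead predicted voltages (mV).
#' @export
predict.ukf_fit <- function(object, ...) object$ypred

#' @export
summary.ukf_fit <- function(object, ...) {
  n <- length(object$innovations)
  tail_idx <- seq(floor(0.8 * n) + 1, n)
  rms_curve <- rms_error_curve(object$ypred,
                               object$trace$v_mV[seq_len(n)],
                               window = max(1, round(n / 50)))
  conv <- convergence_time(rms_curve, object$time, 2 * sqrt(object$R))
  out <- list(model = object$model, n_obs = n,
              innovation_rms = sqrt(mean(object$innovations^2)),
              innovation_rms_tail = sqrt(mean(object$innovations[tail_idx]^2)),
              convergence_time_ms = conv,
              runtime_s = object$runtime_s, converged = object$converged)
  if (length(object$track)) {
    term <- coef(object)
    sd_t <- object$sds[nrow(object$sds), object$track]
    out$parameters <- data.frame(estimate = as.numeric(term),
                                 transformed_sd = as.numeric(sd_t),
                                 row.names = object$track)
  }
  structure(out, class = "summary.ukf_fit")
}

#' @export
print.summary.ukf_fit <- function(x, ...) {
  cat("Sigma-point filter fit (", x$model, ")\n", sep = "")
  cat("  observations:     ", x$n_obs, "\n")
  cat("  innovation RMS:   ", format(x$innovation_rms, digits = 4), " mV\n")
  cat("  tail RMS (last 20%):", format(x$innovation_rms_tail, digits = 4),
      " mV\n")
  cat("  convergence time: ",
      if (is.na(x$convergence_time_ms)) "not reached"
      else paste(format(x$convergence_time_ms, digits = 4), "ms"), "\n")
  cat("  runtime:          ", format(x$runtime_s, digits = 3), " s\n")
  if (!is.null(x$parameters)) {
    cat("  tracked parameters (terminal posterior):\n")
    print(signif(x$parameters, 4))
  }
  invisible(x)
}

#' Plot an assimilation fit
#'
#' Observed vs estimated voltage plus, when parameters are tracked, their
#' posterior trajectories.
#'
#' @param x a \code{"ukf_fit"}.
#' @param which_panels "voltage", "parameters" or both.
#' @param ... unused.
#' @export
plot.ukf_fit <- function(x, which_panels = c("voltage", "parameters"), ...) {
  which_panels <- match.arg(which_panels, several.ok = TRUE)
  np <- ("voltage" %in% which_panels) +
    ("parameters" %in% which_panels && length(x$track) > 0)
  old <- graphics::par(mfrow = c(np, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  n <- nrow(x$means)
  if ("voltage" %in% which_panels) {
    graphics::plot(x$time, x$trace$v_mV[seq_len(n)], type = "l",
                   col = "tomato", xlab = "time (ms)", ylab = "V (mV)")
    graphics::lines(x$time, fitted(x), col = "black")
    graphics::legend("topright", c("observed", "estimated"),
                     col = c("tomato", "black"), lty = 1, bty = "n")
  }
  if ("parameters" %in% which_panels && length(x$track)) {
    graphics::matplot(x$time, x$tracked, type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "tracked parameter")
    graphics::legend("topright", x$track, col = seq_along(x$track),
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' Forward-simulate the fitted model
#'
#' Runs the model variant of the fit forward from its terminal posterior
#' state, with tracked parameters frozen at their terminal estimates, and
#' returns noisy synthetic traces -- the model's account of what a
#' continuation of the recording would look like.
#'
#' @param object a \code{"ukf_fit"} for a single-cell variant.
#' @param nsim number of traces.
#' @param seed RNG seed.
#' @param duration simulated time (ms).
#' @param ... unused.
#' @return data frame of time_ms plus one \code{sim_*} column per
#'   replicate.
#' @export
simulate.ukf_fit <- function(object, nsim = 1, seed = 1, duration = 200, ...) {
  if (object$model == "pair") stop("simulate() supports single-cell fits")
  params <- object$params
  est <- coef(object)
  for (nm in names(est)) {
    if (nm %in% names(params$env)) params$env[[nm]] <- est[[nm]]
    else if (nm %in% names(params$cell)) params$cell[[nm]] <- est[[nm]]
  }
  x0 <- object$means[nrow(object$means), seq_along(.state_names_single)]
  names(x0) <- .state_names_single
  x0["K_o"] <- max(x0["K_o"], 0.5)
  x0["Na_i"] <- min(max(x0["Na_i"], 5), 38)
  alpha_m <- if ("alpha_m" %in% names(est)) est[["alpha_m"]] else 1
  traj <- simulate_neuron(params, duration = duration, dt = object$dt,
                          init = x0, mode = switch(object$model,
                                                   pc_fixed_ions = "fixed_ions",
                                                   pc_crippled = "crippled",
                                                   "full"),
                          alpha_m_const = alpha_m, pin = object$pin,
                          record_every_ms = object$time[2] - object$time[1],
                          t0 = object$time[length(object$time)])
  out <- data.frame(time_ms = traj$time)
  set.seed(seed)
  for (i in seq_len(nsim))
    out[[paste0("sim_", i)]] <- traj$states[, "V"] +
      rnorm(nrow(traj$states), 0, sqrt(object$R))
  out
}
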