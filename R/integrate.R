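# Fixed-step integration and forward simulation.

#' Current-injection protocol
#'
#' A rectangular current pulse.  Amplitude may be given directly as a
#' density (uA/cm^2) or as a pipette current in pA, which is converted via
#' the spherical-cell area (see [current_density_from_pA()]).
#'
#' @param amplitude_pA pulse amplitude in picoamperes (used when
#'   \code{amplitude} is NULL).
#' @param amplitude pulse amplitude as a current density (uA/cm^2).
#' @param onset pulse onset (ms).
#' @param duration pulse duration (ms), >= 0.
#' @param radius_um radius of the sphere whose area converts pA to
#'   density.  The default 18.6 um corresponds to an effective electrical
#'   membrane area of ~4300 um^2 -- much larger than the 7 um sphere used
#'   for the intracellular volume in [gamma_from_geometry()], because the
#'   pipette current spreads over soma plus proximal dendrites.  It
#'   places the model's rheobase near 96 pA, in the range measured for
#'   CA1 pyramidal cells, so a 100 pA pulse is "a small current" just
#'   above rheobase and elicits moderate repetitive spiking rather than
#'   a hyper-driven discharge.
#' @return An object of class \code{"stimulus_protocol"}.
#' @export
stimulus_protocol <- function(amplitude_pA = 100, amplitude = NULL,
                              onset = 0, duration = 1000, radius_um = 18.6) {
  if (duration < 0) stop("duration must be >= 0")
  if (is.null(amplitude))
    amplitude <- current_density_from_pA(amplitude_pA, radius_um)
  structure(list(amplitude = amplitude, onset = onset, duration = duration),
            class = "stimulus_protocol")
}

protocol_current <- function(protocol, t) {
  if (is.null(protocol)) return(0)
  ifelse(t >= protocol$onset & t < protocol$onset + protocol$duration,
         protocol$amplitude, 0)
}

#' Fixed-step 4th-order Runge-Kutta integration
#'
#' Deterministic classical RK4 over a uniform grid.  Used directly for
#' small reference computations; long simulations go through the compiled
#' path in [simulate_neuron()] / [simulate_pair()], which implements the
#' identical scheme.
#'
#' @param rhs function(t, state, ...) returning dstate/dt.
#' @param init initial state (named numeric).
#' @param duration integration time (ms).
#' @param dt step (ms), > 0.
#' @param t0 initial time (ms).
#' @param record_every record every this many steps.
#' @param ... passed to \code{rhs}.
#' @return List with \code{time} (ms) and \code{states} (matrix, one row
#'   per recorded point, first row = initial state).  Divergence
#'   (non-finite state or |V| > 150 mV when a V component exists) aborts
#'   with an error carrying the last valid time.
#' @export
integrate_fixed <- function(rhs, init, duration, dt, t0 = 0,
                            record_every = 1L, ...) {
  if (dt <= 0) stop("dt must be positive")
  n_steps <- round(duration / dt)
  x <- init
  f0 <- rhs(t0, x, ...)
  if (any(!is.finite(f0))) stop("rhs not finite at the initial state")
  n_rec <- n_steps %/% record_every + 1L
  out <- matrix(NA_real_, n_rec, length(init),
                dimnames = list(NULL, names(init)))
  out[1, ] <- x
  times <- t0 + seq(0, n_steps, by = record_every) * dt
  row <- 2L
  vi <- match("V", names(init))
  for (k in seq_len(n_steps)) {
    t <- t0 + (k - 1) * dt
    k1 <- rhs(t, x, ...)
    k2 <- rhs(t + dt / 2, x + dt / 2 * k1, ...)
    k3 <- rhs(t + dt / 2, x + dt / 2 * k2, ...)
    k4 <- rhs(t + dt, x + dt * k3, ...)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x)) || (!is.na(vi) && abs(x[vi]) > 150))
      stop("integration diverged at t = ", format(t + dt), " ms")
    if (k %% record_every == 0) {
      out[row, ] <- x
      row <- row + 1L
    }
  }
  list(time = times[seq_len(row - 1L)], states = out[seq_len(row - 1L), , drop = FALSE])
}

.mode_code <- function(mode) {
  match(match.arg(mode, c("full", "fixed_ions", "crippled")),
        c("full", "fixed_ions", "crippled")) - 1L
}

#' Simulate a single neuron (compiled fixed-step RK4)
#'
#' @param params a [neuron_params()] bundle.
#' @param duration simulated time (ms).
#' @param dt integration step (ms), default 0.01.
#' @param init initial state; defaults to an approximate resting state.
#' @param protocol optional [stimulus_protocol()].
#' @param mode model variant, see [rhs_single_cell()].
#' @param alpha_m_const,pin variant settings, see [rhs_single_cell()].
#' @param record_every_ms recording interval (ms); must be a multiple of dt.
#' @param t0 initial time (ms).
#' @return A trajectory: list with \code{time}, \code{states} (columns
#'   V, m, h, n, Ca_i, K_o, Na_i), \code{dt}, \code{params}.
#' @export
simulate_neuron <- function(params = neuron_params(), duration = 1000,
                            dt = 0.01, init = NULL, protocol = NULL,
                            mode = "full", alpha_m_const = 1,
                            pin = c(K_o = 4, Na_i = 18),
                            record_every_ms = 0.1, t0 = 0) {
  rec <- check_interval(record_every_ms, dt)
  if (is.null(init)) {
    init <- c(V = -65, gating_steady_state(-65), Ca_i = 0.01,
              K_o = params$env$K_bath, Na_i = 18)
    names(init) <- .state_names_single
  }
  pc <- pack_cell_pars(params$cell, params$env, alpha_m = alpha_m_const,
                       pin_K_o = pin[["K_o"]], pin_Na_i = pin[["Na_i"]])
  stim <- pack_stim(protocol, base_pc = params$cell$I_stim)
  res <- cpp_simulate(as.numeric(init[.state_names_single]), pc, pc,
                      pack_syn_pars(synapse_params()), 0L, .mode_code(mode),
                      t0, dt, round(duration / dt), rec, stim)
  if (!res$ok)
    stop("simulation diverged at t = ",
         format(t0 + res$steps_done * dt), " ms")
  colnames(res$states) <- .state_names_single
  list(time = t0 + seq(0, nrow(res$states) - 1) * record_every_ms,
       states = res$states, dt = dt, params = params, protocol = protocol,
       mode = mode)
}

#' Simulate the coupled PC-IN pair (compiled fixed-step RK4)
#'
#' @param params a [pair_params()] bundle.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param init named 18-vector; defaults to both cells near rest with
#'   silent synapses.
#' @param protocol_pc,protocol_in optional stimulus protocols (the two
#'   pulses share onset/duration; only amplitudes may differ).
#' @param record_every_ms recording interval (ms).
#' @param t0 initial time (ms).
#' @return Trajectory list as in [simulate_neuron()], with 18 state
#'   columns.
#' @export
simulate_pair <- function(params = pair_params(), duration = 1000, dt = 0.01,
                          init = NULL, protocol_pc = NULL, protocol_in = NULL,
                          record_every_ms = 0.1, t0 = 0) {
  rec <- check_interval(record_every_ms, dt)
  if (is.null(init)) {
    rest <- c(V = -65, gating_steady_state(-65), Ca_i = 0.01, K_o = 3,
              Na_i = 18)
    init <- c(rest, rest, 0, 0, 0, 0)
    names(init) <- .state_names_pair
    init["pc_K_o"] <- params$pc$env$K_bath
    init["in_K_o"] <- params$int$env$K_bath
  }
  ppc <- pack_cell_pars(params$pc$cell, params$pc$env)
  pin <- pack_cell_pars(params$int$cell, params$int$env)
  psn <- pack_syn_pars(params$syn, delta = params$pc$env$delta)
  stim <- pack_stim(protocol_pc, protocol_in, base_pc = params$pc$cell$I_stim,
                    base_in = params$int$cell$I_stim)
  res <- cpp_simulate(as.numeric(init[.state_names_pair]), ppc, pin, psn,
                      1L, 0L, t0, dt, round(duration / dt), rec, stim)
  if (!res$ok)
    stop("simulation diverged at t = ",
         format(t0 + res$steps_done * dt), " ms")
  colnames(res$states) <- .state_names_pair
  list(time = t0 + seq(0, nrow(res$states) - 1) * record_every_ms,
       states = res$states, dt = dt, params = params,
       protocol_pc = protocol_pc, protocol_in = protocol_in)
}

pack_stim <- function(protocol_pc = NULL, protocol_in = NULL,
                      base_pc = 0, base_in = 0) {
  p <- if (is.null(protocol_pc)) list(amplitude = 0, onset = 0, duration = 0)
       else protocol_pc
  amp_in <- if (is.null(protocol_in)) 0 else protocol_in$amplitude
  c(p$amplitude, p$onset, p$duration, amp_in, base_pc, base_in)
}

check_interval <- function(interval_ms, dt) {
  rec <- interval_ms / dt
  if (abs(rec - round(rec)) > 1e-8)
    stop("interval (", interval_ms, " ms) must be an integer multiple of dt (",
         dt, " ms)")
  as.integer(round(rec))
}
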