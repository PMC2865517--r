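# Synthetic-recording generators for twin experiments.  Each fixture
# simulates the model, subsamples the membrane potential at the recording
# interval, adds Gaussian measurement noise, and keeps every hidden state
# as a truth column so recovery can be scored.

#' Subsample a trajectory into a noisy voltage trace
#'
#' @param traj trajectory from [simulate_neuron()] / [simulate_pair()].
#' @param interval_ms observation interval (ms); must be an integer
#'   multiple of the trajectory's recording interval.
#' @param noise_sd Gaussian measurement noise SD (mV).
#' @param seed RNG seed for the noise.
#' @param observe state column observed as \code{v_mV} ("V" for a single
#'   cell; "pc_V" or "in_V" for the pair).
#' @return Trace data frame: \code{time_ms}, \code{v_mV}, plus one
#'   \code{true_*} column per state variable; attributes noise_sd, seed,
#'   dt.
#' @export
make_observations <- function(traj, interval_ms = 0.1, noise_sd = 0.5,
                              seed = 1, observe = NULL) {
  rec_ms <- traj$time[2] - traj$time[1]
  stride <- check_interval(interval_ms, rec_ms)
  idx <- seq(1, length(traj$time), by = stride)
  if (is.null(observe))
    observe <- if ("V" %in% colnames(traj$states)) "V" else "pc_V"
  truth <- traj$states[idx, , drop = FALSE]
  v_true <- truth[, observe]
  noise <- if (noise_sd > 0) {
    set.seed(seed)
    rnorm(length(idx), 0, noise_sd)
  } else 0
  out <- data.frame(time_ms = traj$time[idx], v_mV = v_true + noise)
  truth_df <- as.data.frame(truth)
  names(truth_df) <- paste0("true_", colnames(truth))
  out <- cbind(out, truth_df)
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  attr(out, "dt") <- traj$dt
  attr(out, "observe") <- observe
  out
}

#' Current-injected spiking pyramidal cell
#'
#' Single PC in a physiological microenvironment (K_bath = 3 mM, normal
#' pump and glia), driven by a 100 pA, 1 s current pulse; produces
#' repetitive spiking during the pulse and returns to rest afterwards.
#' Voltage is observed every 0.1 ms with Gaussian noise.
#'
#' @param seed noise seed.
#' @param noise_sd observation noise SD (mV), default 0.5.
#' @param duration total simulated time (ms); the pulse starts at
#'   \code{onset} and lasts \code{pulse_ms}.
#' @param onset,pulse_ms pulse timing (ms).
#' @param dt integration step (ms).
#' @param params optional [neuron_params()] override.
#' @return List with \code{trajectory}, \code{trace} (see
#'   [make_observations()]), \code{protocol} and \code{params}.
#' @export
spiking_pc_fixture <- function(seed = 1, noise_sd = 0.5, duration = 1300,
                               onset = 100, pulse_ms = 1000, dt = 0.01,
                               params = NULL) {
  if (is.null(params)) params <- neuron_params()
  protocol <- stimulus_protocol(amplitude_pA = 100, onset = onset,
                                duration = pulse_ms)
  traj <- simulate_neuron(params, duration = duration, dt = dt,
                          init = resting_state(params),
                          protocol = protocol, record_every_ms = 0.1)
  trace <- make_observations(traj, interval_ms = 0.1, noise_sd = noise_sd,
                             seed = seed)
  list(trajectory = traj, trace = trace, protocol = protocol, params = params)
}

#' Microenvironment override producing spontaneous seizure-like episodes
#'
#' Reduced glial buffering and reservoir coupling at physiological bath
#' potassium push the single PC into a slow relaxation oscillation:
#' episodes of sustained high-frequency firing during which extracellular
#' potassium rises well above baseline, separated by quiescent intervals
#' in which K_o returns toward K_bath.  The values were chosen by a coarse
#' scan over (G_glia, eps) -- see [scan_seizure_regime()] -- selecting a
#' regime whose episodes peak near 7 mM K_o from a 3 mM baseline with an
#' inter-event period above 10 s.
#'
#' @return A [neuron_params()] bundle.
#' @export
seizure_preset <- function() {
  neuron_params(cell = cell_params("PC", I_stim = 1.8),
                env = microenv_params(G_glia = 40, eps = 2.0, K_bath = 3))
}

#' Late inter-ictal state of the seizure regime
#'
#' The seizure regime is a slow relaxation oscillation whose full cycle
#' (episode + recovery) lasts well over 100 s; the recovery phase is a
#' slow drainage of intracellular sodium.  To keep desk runs short the
#' fixture starts from this state, late in the recovery with Na_i just
#' above the ignition threshold, so a window of a few tens of seconds
#' contains quiet baseline, one complete episode, and the post-ictal
#' return to baseline.
#'
#' @param params the seizure-regime parameter bundle.
#' @return Named 7-vector.
#' @export
seizure_init_state <- function(params = seizure_preset()) {
  x <- c(V = -58, gating_steady_state(-58), Ca_i = 0.001,
         K_o = params$env$K_bath + 0.05, Na_i = 19)
  names(x) <- .state_names_single
  x
}

#' Spontaneous seizure-like episode fixture
#'
#' Simulates the seizure regime (default [seizure_preset()]) and checks
#' that at least one complete episode is present: sustained fast firing
#' with K_o rising then falling back toward baseline.  Raises a
#' "no-seizure regime" error otherwise.
#'
#' @param params override bundle; defaults to [seizure_preset()].
#' @param duration simulated time (ms).
#' @param seed noise seed.
#' @param noise_sd observation noise SD (mV).
#' @param dt integration step (ms).
#' @param init optional initial state.
#' @return List with \code{trajectory}, \code{trace}, \code{episodes}
#'   (data frame from [detect_episodes()]) and \code{params}.
#' @export
seizure_fixture <- function(params = seizure_preset(), duration = 20000,
                            seed = 1, noise_sd = 0.5, dt = 0.01,
                            init = seizure_init_state(params)) {
  traj <- simulate_neuron(params, duration = duration, dt = dt, init = init,
                          record_every_ms = 0.1)
  ep <- detect_episodes(traj$states[, "V"], traj$time)
  if (nrow(ep) == 0)
    stop("no-seizure regime: no episode detected in ", duration, " ms")
  trace <- make_observations(traj, interval_ms = 0.1, noise_sd = noise_sd,
                             seed = seed)
  list(trajectory = traj, trace = trace, episodes = ep, params = params)
}

#' Parameter bundle for the interacting PC-IN pair
#'
#' The interneuron side carries weaker glial buffering than the pyramidal
#' side, so during an episode its extracellular potassium rises further,
#' driving it through high-frequency firing into depolarization block;
#' the block gate chi(eta_i) then collapses the inhibition onto the PC,
#' which responds with intense firing.
#'
#' @return A [pair_params()] bundle.
#' @export
pair_preset <- function() {
  pair_params(
    pc = neuron_params(cell = cell_params("PC", I_stim = 1.8),
                       env = microenv_params(G_glia = 40, eps = 2.0,
                                             K_bath = 3)),
    int = neuron_params(cell = cell_params("IN", I_stim = 1.0),
                        env = microenv_params(G_glia = 5, eps = 0.3,
                                              K_bath = 3)),
    syn = synapse_params())
}

#' Coupled PC-IN fixture with interneuron depolarization block
#'
#' Simulates the coupled pair (default [pair_preset()]) and checks for
#' the firing interplay: an interval in which eta_i is high, the block
#' gate chi(eta_i) is below 0.05, and the PC fires above its baseline
#' rate.
#'
#' @param params override bundle; defaults to [pair_preset()].
#' @param duration simulated time (ms).
#' @param seed noise seed.
#' @param noise_sd observation noise SD (mV).
#' @param dt integration step (ms).
#' @param init optional initial 18-vector; defaults to both cells at the
#'   late inter-ictal state of [seizure_init_state()] with silent synapses.
#' @param require_block error if the interneuron never reaches
#'   depolarization block (disable for decoupled control runs).
#' @return List with \code{trajectory}, \code{trace_pc}, \code{trace_in},
#'   \code{block} (logical index of the block interval on the recording
#'   grid) and \code{params}.
#' @export
coupled_pair_fixture <- function(params = pair_preset(), duration = 12000,
                                 seed = 1, noise_sd = 0.5, dt = 0.01,
                                 init = NULL, require_block = TRUE) {
  if (is.null(init)) {
    rest <- seizure_init_state(params$pc)
    init <- c(rest, rest, 0, 0, 0, 0)
    names(init) <- .state_names_pair
  }
  traj <- simulate_pair(params, duration = duration, dt = dt, init = init,
                        record_every_ms = 0.1)
  chi_i <- synaptic_gate_chi(traj$states[, "eta_i"], params$syn)
  block <- chi_i < 0.05
  if (require_block && !any(block))
    stop("no-seizure regime: interneuron never reaches depolarization block")
  trace_pc <- make_observations(traj, noise_sd = noise_sd, seed = seed,
                                observe = "pc_V")
  trace_in <- make_observations(traj, noise_sd = noise_sd, seed = seed + 1,
                                observe = "in_V")
  list(trajectory = traj, trace_pc = trace_pc, trace_in = trace_in,
       block = block, params = params)
}

#' Detect seizure-like episodes from a voltage trace
#'
#' Thresholds the windowed firing rate with hysteresis: an episode starts
#' when the rate exceeds \code{rate_hi} and ends when it drops below
#' \code{rate_lo}.  Spikes are upward crossings of \code{spike_thr}.
#'
#' @param v membrane potential (mV) on a uniform grid.
#' @param time time grid (ms).
#' @param spike_thr spike detection threshold (mV).
#' @param window rate-estimation window (ms).
#' @param rate_hi,rate_lo hysteresis thresholds (spikes/s).
#' @return Data frame with one row per complete episode: onset, offset
#'   (ms), duration, peak firing rate.
#' @export
detect_episodes <- function(v, time, spike_thr = -20, window = 500,
                            rate_hi = 15, rate_lo = 3) {
  dt <- time[2] - time[1]
  spikes <- spike_times(v, time, spike_thr)
  n <- length(time)
  counts <- numeric(n)
  if (length(spikes)) {
    idx <- findInterval(spikes, time)
    half <- round(window / 2 / dt)
    inc <- tabulate(idx, nbins = n)
    counts <- stats::filter(inc, rep(1, 2 * half + 1), sides = 2)
    counts[is.na(counts)] <- 0
  }
  rate <- counts / (window / 1000)
  inside <- FALSE
  onset <- numeric(0); offset <- numeric(0); peak <- numeric(0)
  cur_peak <- 0
  for (i in seq_len(n)) {
    if (!inside && rate[i] >= rate_hi) {
      inside <- TRUE; onset <- c(onset, time[i]); cur_peak <- rate[i]
    } else if (inside) {
      cur_peak <- max(cur_peak, rate[i])
      if (rate[i] <= rate_lo) {
        inside <- FALSE; offset <- c(offset, time[i]); peak <- c(peak, cur_peak)
      }
    }
  }
  k <- min(length(onset), length(offset))
  data.frame(onset = onset[seq_len(k)], offset = offset[seq_len(k)],
             duration = offset[seq_len(k)] - onset[seq_len(k)],
             peak_rate = peak[seq_len(k)])
}

#' Spike times as upward threshold crossings
#' @param v voltage (mV), uniform grid.
#' @param time time grid (ms).
#' @param thr threshold (mV).
#' @return numeric vector of crossing times (ms).
#' @export
spike_times <- function(v, time, thr = 0) {
  up <- which(v[-1] >= thr & v[-length(v)] < thr)
  time[up + 1]
}

#' Coarse scan for the spontaneous-episode regime
#'
#' Simulates the single PC over a grid of (G_glia, eps) at fixed
#' physiological K_bath and reports, for each combination, whether
#' episodes occur, the K_o baseline/peak and the inter-event period.
#' This is the scan used to choose [seizure_preset()].
#'
#' @param G_glia_grid,eps_grid parameter grids.
#' @param K_bath reservoir potassium (mM).
#' @param duration simulated time per combination (ms).
#' @param dt integration step (ms); the default is coarser than the
#'   production step since only the regime class is needed.
#' @return Data frame with one row per combination.
#' @export
scan_seizure_regime <- function(G_glia_grid = c(5, 10, 20, 40),
                                eps_grid = c(0.3, 0.6, 1.2), K_bath = 3,
                                duration = 40000, dt = 0.05) {
  grid <- expand.grid(G_glia = G_glia_grid, eps = eps_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    par <- neuron_params(env = microenv_params(G_glia = grid$G_glia[i],
                                               eps = grid$eps[i],
                                               K_bath = K_bath))
    traj <- tryCatch(simulate_neuron(par, duration = duration, dt = dt,
                                     record_every_ms = 1),
                     error = function(e) NULL)
    if (is.null(traj))
      return(data.frame(grid[i, ], n_episodes = NA, K_o_base = NA,
                        K_o_peak = NA, period_s = NA))
    ep <- detect_episodes(traj$states[, "V"], traj$time)
    ko <- traj$states[, "K_o"]
    data.frame(grid[i, ], n_episodes = nrow(ep),
               K_o_base = min(ko[traj$time > 2000]),
               K_o_peak = max(ko),
               period_s = if (nrow(ep) >= 2) mean(diff(ep$onset)) / 1000 else NA)
  })
  do.call(rbind, rows)
}
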