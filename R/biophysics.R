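# Reference (pure-R) implementation of the model equations.  The compiled
# code in src/ mirrors these routines for speed; tests assert agreement.

#' Voltage-dependent gating rate constants
#'
#' The six Hodgkin-Huxley rate constants alpha/beta for the sodium
#' activation (m), sodium inactivation (h) and potassium activation (n)
#' gates.  The ratio-form rates alpha_m and alpha_n have removable
#' singularities (at -30 mV and -34 mV) which are evaluated at their
#' analytic limits.
#'
#' @param V membrane potential (mV), scalar.
#' @return Named numeric vector
#'   \code{c(alpha_m, beta_m, alpha_h, beta_h, alpha_n, beta_n)} (1/ms).
#' @export
gating_rate_functions <- function(V) {
  if (!is.finite(V)) stop("V must be finite")
  ratio <- function(u, scale, k) {
    if (abs(u) < 1e-7) scale * k else scale * u / (-expm1(-u / k))
  }
  c(alpha_m = ratio(V + 30, 0.1, 10),
    beta_m  = 4 * exp(-(V + 55) / 18),
    alpha_h = 0.07 * exp(-(V + 44) / 20),
    beta_h  = 1 / (1 + exp(-0.1 * (V + 14))),
    alpha_n = ratio(V + 34, 0.01, 10),
    beta_n  = 0.125 * exp(-(V + 44) / 80))
}

#' Steady-state gating values x_inf(V) = alpha/(alpha+beta)
#' @param V membrane potential (mV).
#' @return Named vector \code{c(m, h, n)}.
#' @export
gating_steady_state <- function(V) {
  r <- gating_rate_functions(V)
  c(m = unname(r["alpha_m"] / (r["alpha_m"] + r["beta_m"])),
    h = unname(r["alpha_h"] / (r["alpha_h"] + r["beta_h"])),
    n = unname(r["alpha_n"] / (r["alpha_n"] + r["beta_n"])))
}

#' Time derivatives of the gating variables
#'
#' dx/dt = phi * (alpha_x(V) (1 - x) - beta_x(V) x) for x in {m, h, n}.
#'
#' @param V membrane potential (mV).
#' @param gating named vector or list with elements m, h, n in [0, 1].
#' @param phi dimensionless time-constant factor.
#' @return Named vector \code{c(m, h, n)} of derivatives (1/ms).
#' @export
gating_derivatives <- function(V, gating, phi = 3) {
  g <- unlist(gating)[c("m", "h", "n")]
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
    stop("gating variables must lie in [0, 1]")
  r <- gating_rate_functions(V)
  a <- r[c("alpha_m", "alpha_h", "alpha_n")]
  b <- r[c("beta_m", "beta_h", "beta_n")]
  setNames(phi * (a * (1 - g) - b * g), c("m", "h", "n"))
}

#' Potassium and sodium concentrations slaved to Na_i
#'
#' Bulk electroneutrality ties the intracellular potassium concentration to
#' the intracellular sodium concentration, K_i = 140 + (18 - Na_i), and
#' conservation of sodium across the two compartments gives
#' Na_o = 144 - beta_vol (Na_i - 18), where 140/18/144 mM are the normal
#' resting concentrations.
#'
#' @param Na_i intracellular sodium (mM), > 0.
#' @param beta_vol intra/extracellular volume ratio.
#' @return Named vector \code{c(K_i, Na_o)} (mM).
#' @export
dependent_concentrations <- function(Na_i, beta_vol = 7) {
  Na_i <- unname(Na_i)
  if (any(Na_i <= 0)) stop("Na_i must be positive")
  K_i <- 140 + (18 - Na_i)
  Na_o <- 144 - beta_vol * (Na_i - 18)
  if (any(K_i <= 0) || any(Na_o <= 0))
    warning("derived concentration non-positive: state outside model validity")
  c(K_i = K_i, Na_o = Na_o)
}

#' Nernst reversal potentials
#'
#' E_X = therm_mV * ln([X]_out / [X]_in) for K+ and Na+ (with K_i and Na_o
#' derived via [dependent_concentrations()]), and
#' E_Cl = therm_mV * ln(Cl_i / Cl_o) for the anion.
#'
#' @param ions list/vector with K_o and Na_i (mM).
#' @param cell a [cell_params()] object (chloride concentrations).
#' @param env a [microenv_params()] object (beta_vol, therm_mV).
#' @return Named vector \code{c(E_Na, E_K, E_Cl)} (mV).
#' @export
nernst_reversals <- function(ions, cell = cell_params(),
                             env = microenv_params()) {
  io <- as.list(ions)
  if (io$K_o <= 0 || io$Na_i <= 0) stop("concentrations must be positive")
  dep <- dependent_concentrations(io$Na_i, env$beta_vol)
  if (dep["K_i"] <= 0 || dep["Na_o"] <= 0)
    stop("derived concentrations must be positive")
  c(E_Na = env$therm_mV * log(dep[["Na_o"]] / io$Na_i),
    E_K  = env$therm_mV * log(io$K_o / dep[["K_i"]]),
    E_Cl = env$therm_mV * log(cell$Cl_i / cell$Cl_o))
}

#' Membrane currents
#'
#' Ionic currents of the modified Hodgkin-Huxley membrane:
#' I_Na = (g_Na m^3 h + g_NaL)(V - E_Na);
#' I_K = (g_K n^4 + g_AHP Ca/(1+Ca) + g_KL)(V - E_K) where the
#' calcium-gated after-hyperpolarization term exists only in the PC;
#' leak has potassium, sodium and chloride components.
#'
#' @param V membrane potential (mV).
#' @param gating named m, h, n.
#' @param reversals named E_Na, E_K, E_Cl from [nernst_reversals()].
#' @param Ca_i intracellular calcium (arbitrary units).
#' @param cell a [cell_params()] object.
#' @return Named vector with I_Na, I_K, I_AHP, I_L and the three leak
#'   components (uA/cm^2); I_Na and I_K include their leak parts, matching
#'   the currents that drive the ion-concentration equations.
#' @export
membrane_currents <- function(V, gating, reversals, Ca_i, cell = cell_params()) {
  g <- as.list(gating); rv <- as.list(reversals)
  I_AHP <- cell$g_AHP * Ca_i / (1 + Ca_i) * (V - rv$E_K)
  leak_K <- cell$g_KL * (V - rv$E_K)
  leak_Na <- cell$g_NaL * (V - rv$E_Na)
  leak_Cl <- cell$g_ClL * (V - rv$E_Cl)
  c(I_Na = cell$g_Na * g$m^3 * g$h * (V - rv$E_Na) + leak_Na,
    I_K = (cell$g_K * g$n^4) * (V - rv$E_K) + I_AHP + leak_K,
    I_AHP = I_AHP,
    I_L = leak_K + leak_Na + leak_Cl,
    leak_K = leak_K, leak_Na = leak_Na, leak_Cl = leak_Cl)
}

#' Na-K pump rate
#'
#' Product of two saturating sigmoids in intracellular sodium and
#' extracellular potassium, scaled by the maximal pump strength rho.
#'
#' @param Na_i intracellular sodium (mM), > 0.
#' @param K_o extracellular potassium (mM), > 0.
#' @param rho maximal pump strength (mM/s), >= 0.
#' @return pump rate (mM/s), in [0, rho].
#' @export
pump_flux <- function(Na_i, K_o, rho = 1.25) {
  if (rho < 0) stop("rho must be >= 0")
  if (any(Na_i <= 0) || any(K_o <= 0)) stop("concentrations must be positive")
  rho / ((1 + exp((25 - Na_i) / 3)) * (1 + exp(5.5 - K_o)))
}

#' Glial potassium uptake rate
#'
#' Single saturating sigmoid in extracellular potassium with maximal
#' buffering strength G_glia.
#'
#' @param K_o extracellular potassium (mM), > 0.
#' @param G_glia maximal buffering strength (mM/s).
#' @return uptake rate (mM/s), in [0, G_glia].
#' @export
glial_flux <- function(K_o, G_glia = 66) {
  if (any(K_o <= 0)) stop("K_o must be positive")
  G_glia / (1 + exp((18 - K_o) / 2.5))
}

#' Diffusive potassium flux to the reservoir (Fick's law)
#'
#' @param K_o extracellular potassium (mM).
#' @param K_bath reservoir potassium (mM).
#' @param eps diffusion coefficient (1/s).
#' @return removal rate eps * (K_o - K_bath) (mM/s); positive when K_o
#'   exceeds the reservoir.
#' @export
bath_flux <- function(K_o, K_bath = 3, eps = 1.2) {
  if (eps < 0) stop("eps must be >= 0")
  eps * (K_o - K_bath)
}

#' Ion-concentration derivatives
#'
#' dK_o/dt combines the gamma*beta_vol-scaled membrane potassium current,
#' pump uptake (factor 2 beta_vol), glial buffering, reservoir diffusion
#' and an optional lateral-diffusion coupling term; dNa_i/dt combines the
#' gamma-scaled sodium current and pump extrusion (factor 3); the 3:2
#' pump factors are the electrogenic stoichiometry.  Intracellular calcium
#' relaxes with an 80 ms time constant against a voltage-gated influx.
#' Rates are converted from per-second to per-millisecond so the whole
#' system shares the membrane time base.
#'
#' @param state named vector V, m, h, n, Ca_i, K_o, Na_i.
#' @param cell a [cell_params()] object.
#' @param env a [microenv_params()] object.
#' @param coupling_term lateral-diffusion contribution to dK_o/dt (mM/s);
#'   0 for a single cell.
#' @return Named vector \code{c(K_o, Na_i, Ca_i)} of derivatives (mM/ms,
#'   Ca in a.u./ms).
#' @export
ion_derivatives <- function(state, cell = cell_params(),
                            env = microenv_params(), coupling_term = 0) {
  s <- as.list(state)
  if (s$K_o <= 0 || s$Na_i <= 0 || s$Ca_i < 0)
    stop("concentrations must be positive")
  rev <- nernst_reversals(c(K_o = s$K_o, Na_i = s$Na_i), cell, env)
  cur <- membrane_currents(s$V, s[c("m", "h", "n")], rev, s$Ca_i, cell)
  pump <- pump_flux(s$Na_i, s$K_o, env$rho)
  glia <- glial_flux(s$K_o, env$G_glia)
  diff <- bath_flux(s$K_o, env$K_bath, env$eps)
  dK_o <- (env$gamma * env$beta_vol * cur[["I_K"]] -
             2 * env$beta_vol * pump - glia - diff + coupling_term) / 1000
  dNa_i <- (-env$gamma * cur[["I_Na"]] - 3 * pump) / 1000
  dCa_i <- -0.002 * cell$g_Ca * (s$V - cell$E_Ca) /
    (1 + exp(-(s$V + 25) / 2.5)) - s$Ca_i / 80
  c(K_o = dK_o, Na_i = dNa_i, Ca_i = dCa_i)
}

#' Depolarization-block gate
#'
#' chi(eta) = 1 / (1 + exp((eta - eta_c)/sigma_chi)): near 1 for eta = 0
#' (no block), monotonically decreasing, and approaching 0 as the slow
#' depolarization integrator eta grows large.
#'
#' @param eta depolarization integrator, >= 0 (vectorized).
#' @param syn a [synapse_params()] object (gate shape).
#' @return chi in (0, 1].
#' @export
synaptic_gate_chi <- function(eta, syn = synapse_params()) {
  if (any(eta < 0)) stop("eta must be >= 0")
  1 / (1 + exp((eta - syn$eta_c) / syn$sigma_chi))
}

#' Synaptic currents and synaptic-state derivatives
#'
#' The inhibitory current into the PC scales with g_inh * s_i * chi(eta_i)
#' and the excitatory current into the IN with g_exc * s_p * chi(eta_p).
#' Each synaptic gate s relaxes toward a sigmoid of its presynaptic voltage
#' with time constant tau_e (PC output) or tau_i (IN output); each eta
#' relaxes toward a slow depolarization sigmoid with time constant tau_eta.
#'
#' @param V_pc,V_in membrane potentials of the PC and IN (mV).
#' @param syn_state named vector s_p, eta_p, s_i, eta_i.
#' @param syn a [synapse_params()] object.
#' @return List with \code{I_syn_pc}, \code{I_syn_in} (uA/cm^2) and
#'   \code{derivs} (named vector of ds_p, deta_p, ds_i, deta_i).
#' @export
synaptic_dynamics <- function(V_pc, V_in, syn_state, syn = synapse_params()) {
  ss <- as.list(syn_state)
  if (ss$s_p < 0 || ss$s_p > 1 || ss$s_i < 0 || ss$s_i > 1)
    stop("synaptic gates must lie in [0, 1]")
  if (ss$eta_p < 0 || ss$eta_i < 0) stop("eta must be >= 0")
  sig <- function(V) 1 / (1 + exp(-(V - syn$s_theta) / syn$s_slope))
  sig_eta <- function(V) 1 / (1 + exp(-(V - syn$eta_theta) / syn$eta_slope))
  I_syn_pc <- -syn$g_inh * ss$s_i * synaptic_gate_chi(ss$eta_i, syn) *
    (V_pc - syn$E_inh)
  I_syn_in <- -syn$g_exc * ss$s_p * synaptic_gate_chi(ss$eta_p, syn) *
    (V_in - syn$E_exc)
  derivs <- c(s_p = (sig(V_pc) - ss$s_p) / syn$tau_e,
              eta_p = (sig_eta(V_pc) - ss$eta_p) / syn$tau_eta,
              s_i = (sig(V_in) - ss$s_i) / syn$tau_i,
              eta_i = (sig_eta(V_in) - ss$eta_i) / syn$tau_eta)
  list(I_syn_pc = I_syn_pc, I_syn_in = I_syn_in, derivs = derivs)
}

#' Lateral extracellular-potassium diffusion between the two cells
#'
#' @param K_o_pc,K_o_in extracellular potassium near each cell (mM).
#' @param delta lateral diffusion coefficient (1/s), >= 0.
#' @return Named vector \code{c(pc, int)}: the exchange term added to each
#'   cell's dK_o/dt (mM/s).  The two terms are exact negatives, so the
#'   pair sum of K_o is conserved by this term.
#' @export
lateral_K_diffusion <- function(K_o_pc, K_o_in, delta = 0.278) {
  if (delta < 0) stop("delta must be >= 0")
  term <- delta * (K_o_in - K_o_pc)
  c(pc = term, int = -term)
}

#' Full single-cell right-hand side
#'
#' Complete coupled derivative of the 7-dimensional single-cell state
#' (V, m, h, n, Ca_i, K_o, Na_i).  Variants: \code{"full"};
#' \code{"fixed_ions"} pins K_o and Na_i at configured values and forces
#' their derivatives to zero (the model without ion-concentration
#' dynamics); \code{"crippled"} replaces the voltage-dependent rate
#' constant alpha_m(V) by a supplied constant.
#'
#' @param state named 7-vector.
#' @param params a [neuron_params()] bundle.
#' @param t time (ms), used to evaluate the stimulus.
#' @param mode "full", "fixed_ions" or "crippled".
#' @param protocol optional [stimulus_protocol()].
#' @param alpha_m_const constant alpha_m for \code{"crippled"} (1/ms).
#' @param pin pinned concentrations for \code{"fixed_ions"}, named
#'   \code{c(K_o=, Na_i=)}; defaults to physiologically normal 4 and 18 mM.
#' @param coupling_term lateral-diffusion contribution to dK_o/dt (mM/s).
#' @param I_syn synaptic current into this cell (uA/cm^2).
#' @return Named 7-vector of derivatives.
#' @export
rhs_single_cell <- function(state, params = neuron_params(), t = 0,
                            mode = c("full", "fixed_ions", "crippled"),
                            protocol = NULL, alpha_m_const = NULL,
                            pin = c(K_o = 4, Na_i = 18),
                            coupling_term = 0, I_syn = 0) {
  mode <- match.arg(mode)
  s <- as.list(state)
  cell <- params$cell; env <- params$env
  ions <- if (mode == "fixed_ions") as.list(pin) else s[c("K_o", "Na_i")]
  rev <- nernst_reversals(ions, cell, env)
  cur <- membrane_currents(s$V, s[c("m", "h", "n")], rev, s$Ca_i, cell)
  I_app <- cell$I_stim + I_syn +
    if (is.null(protocol)) 0 else protocol_current(protocol, t)
  dV <- (-cur[["I_Na"]] - cur[["I_K"]] - cur[["leak_Cl"]] + I_app) / cell$C_m

  r <- gating_rate_functions(s$V)
  if (mode == "crippled") {
    if (is.null(alpha_m_const)) stop("crippled mode needs alpha_m_const")
    r["alpha_m"] <- alpha_m_const
  }
  a <- r[c("alpha_m", "alpha_h", "alpha_n")]
  b <- r[c("beta_m", "beta_h", "beta_n")]
  g <- unlist(s[c("m", "h", "n")])
  dg <- cell$phi * (a * (1 - g) - b * g)

  dCa <- -0.002 * cell$g_Ca * (s$V - cell$E_Ca) /
    (1 + exp(-(s$V + 25) / 2.5)) - s$Ca_i / 80
  if (mode == "fixed_ions") {
    dK <- 0; dNa <- 0
  } else {
    pump <- pump_flux(s$Na_i, s$K_o, env$rho)
    glia <- glial_flux(s$K_o, env$G_glia)
    diff <- bath_flux(s$K_o, env$K_bath, env$eps)
    dK <- (env$gamma * env$beta_vol * cur[["I_K"]] -
             2 * env$beta_vol * pump - glia - diff + coupling_term) / 1000
    dNa <- (-env$gamma * cur[["I_Na"]] - 3 * pump) / 1000
  }
  c(V = unname(dV), m = unname(dg[1]), h = unname(dg[2]), n = unname(dg[3]),
    Ca_i = unname(dCa), K_o = unname(dK), Na_i = unname(dNa))
}

#' Coupled PC-IN right-hand side
#'
#' Per-cell single-cell dynamics plus synaptic currents plus lateral
#' extracellular-potassium diffusion; the lateral exchange conserves the
#' pair sum of K_o exactly.
#'
#' @param state named 18-vector (pc_*, in_*, s_p, eta_p, s_i, eta_i).
#' @param params a [pair_params()] bundle.
#' @param t time (ms).
#' @param protocol_pc,protocol_in optional [stimulus_protocol()]s.
#' @return Named 18-vector of derivatives.
#' @export
rhs_coupled_pair <- function(state, params = pair_params(), t = 0,
                             protocol_pc = NULL, protocol_in = NULL) {
  s <- as.list(state)
  syn_state <- unlist(s[c("s_p", "eta_p", "s_i", "eta_i")])
  sd <- synaptic_dynamics(s$pc_V, s$in_V, syn_state, params$syn)
  lat <- lateral_K_diffusion(s$pc_K_o, s$in_K_o, params$pc$env$delta)
  pick <- function(prefix) {
    v <- unlist(s[paste0(prefix, .state_names_single)])
    names(v) <- .state_names_single
    v
  }
  d_pc <- rhs_single_cell(pick("pc_"), params$pc, t, protocol = protocol_pc,
                          coupling_term = lat[["pc"]], I_syn = sd$I_syn_pc)
  d_in <- rhs_single_cell(pick("in_"), params$int, t, protocol = protocol_in,
                          coupling_term = lat[["int"]], I_syn = sd$I_syn_in)
  out <- c(d_pc, d_in, sd$derivs)
  names(out) <- .state_names_pair
  out
}

#' Resting state of the single cell
#'
#' Locates the resting fixed point of the full model by relaxation
#' followed by damped Newton refinement on the right-hand side.
#'
#' @param params a [neuron_params()] bundle.
#' @param relax_ms relaxation time before refinement (ms).
#' @return Named 7-vector at which the derivative norm is ~0.
#' @export
resting_state <- function(params = neuron_params(), relax_ms = 20000) {
  x <- c(V = -65, gating_steady_state(-65), Ca_i = 0.01, K_o = params$env$K_bath,
         Na_i = 18)
  names(x) <- .state_names_single
  traj <- simulate_neuron(params, duration = relax_ms, dt = 0.05, init = x,
                          record_every_ms = relax_ms)
  x <- drop(tail(traj$states, 1))
  names(x) <- .state_names_single
  f <- function(z) rhs_single_cell(setNames(z, .state_names_single), params)
  for (i in 1:50) {
    fx <- f(x)
    if (sqrt(sum(fx^2)) < 1e-12) break
    J <- numeric_jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) break
    xn <- x - step
    if (any(!is.finite(xn)) || xn["K_o"] <= 0 || xn["Na_i"] <= 0) break
    x <- xn
  }
  x
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dx <- x
    h <- eps * max(1, abs(x[j]))
    dx[j] <- dx[j] + h
    J[, j] <- (f(dx) - f0) / h
  }
  J
}
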