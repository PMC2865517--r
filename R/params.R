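#' @useDynLib neurokf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm sd median cor setNames coef predict residuals
#'   simulate fitted acf quantile
#' @importFrom utils head tail modifyList write.table read.table packageVersion
NULL

# canonical slot orders shared with the compiled code (see src/neurokf.cpp)
.cell_par_names <- c(
  "C_m", "g_Na", "g_K", "g_AHP", "g_KL", "g_NaL", "g_ClL", "phi",
  "g_Ca", "E_Ca", "Cl_i", "Cl_o",
  "rho", "G_glia", "eps", "K_bath", "beta_vol", "gamma",
  "therm_mV", "alpha_m", "pin_K_o", "pin_Na_i"
)
.syn_par_names <- c(
  "g_inh", "g_exc", "tau_e", "tau_i", "E_exc", "E_inh",
  "s_theta", "s_slope", "eta_theta", "eta_slope", "tau_eta",
  "delta", "eta_c", "sigma_chi"
)
.state_names_single <- c("V", "m", "h", "n", "Ca_i", "K_o", "Na_i")
.state_names_pair <- c(
  paste0("pc_", .state_names_single), paste0("in_", .state_names_single),
  "s_p", "eta_p", "s_i", "eta_i"
)

#' Membrane and channel parameters of one cell
#'
#' Hodgkin-Huxley-type membrane parameters for a CA1 pyramidal cell (PC) or
#' an OLM interneuron (IN).  Conductances are in mS/cm^2, capacitance in
#' uF/cm^2, potentials in mV, chloride concentrations in mM.  The
#' after-hyperpolarization conductance \code{g_AHP} is only present in the
#' pyramidal cell, where it produces spike-frequency adaptation; for
#' \code{cell_type = "IN"} it is forced to zero.
#'
#' @param cell_type "PC" or "IN".
#' @param C_m membrane capacitance (uF/cm^2).
#' @param g_Na,g_K,g_AHP,g_KL,g_NaL,g_ClL,g_Ca maximal conductances
#'   (mS/cm^2).
#' @param phi dimensionless time-constant factor of the gating kinetics.
#' @param E_Ca fixed calcium reversal potential (mV); intracellular calcium
#'   is carried in arbitrary units so its reversal is not computed from a
#'   Nernst equation.
#' @param Cl_i,Cl_o intra/extracellular chloride (mM), fixed.
#' @param I_stim baseline applied current density (uA/cm^2); transient
#'   pulses are supplied separately via [stimulus_protocol()].
#' @return An object of class \code{"cell_params"} (a named list).
#' @seealso [microenv_params()], [synapse_params()], [neuron_params()]
#' @export
cell_params <- function(cell_type = c("PC", "IN"), C_m = 1, g_Na = 100,
                        g_K = 40, g_AHP = if (cell_type[1] == "PC") 0.01 else 0,
                        g_KL = 0.05, g_NaL = 0.0175, g_ClL = 0.05, phi = 3,
                        g_Ca = 0.1, E_Ca = 120, Cl_i = 6, Cl_o = 130,
                        I_stim = 0) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "IN" && g_AHP != 0)
    stop("g_AHP must be 0 for interneurons (no adaptation current)")
  p <- list(cell_type = cell_type, C_m = C_m, g_Na = g_Na, g_K = g_K,
            g_AHP = g_AHP, g_KL = g_KL, g_NaL = g_NaL, g_ClL = g_ClL,
            phi = phi, g_Ca = g_Ca, E_Ca = E_Ca, Cl_i = Cl_i, Cl_o = Cl_o,
            I_stim = I_stim)
  cond <- c("C_m", "g_Na", "g_K", "g_AHP", "g_KL", "g_NaL", "g_ClL", "g_Ca")
  bad <- cond[vapply(p[cond], function(x) !is.finite(x) || x < 0, logical(1))]
  if (length(bad)) stop("negative or non-finite conductance/capacitance: ",
                        paste(bad, collapse = ", "))
  if (p$C_m <= 0) stop("C_m must be positive")
  if (p$Cl_i <= 0 || p$Cl_o <= 0) stop("chloride concentrations must be positive")
  structure(p, class = "cell_params")
}

#' Ion-microenvironment parameters
#'
#' Parameters of the extracellular potassium microenvironment: the Na-K
#' exchange pump, glial buffering, diffusive coupling to a distant reservoir
#' (the bath in a slice preparation, the vasculature in vivo) and lateral
#' diffusion toward a neighbouring cell.
#'
#' @param rho maximal pump strength (mM/s).
#' @param G_glia maximal glial buffering strength (mM/s).
#' @param eps diffusion coefficient to the reservoir (1/s), Fick's-law
#'   construction; see [eps_from_geometry()].
#' @param K_bath reservoir potassium concentration (mM); 3 mM under
#'   physiological conditions.
#' @param beta_vol intracellular-to-extracellular volume ratio
#'   (dimensionless).
#' @param gamma current-to-concentration conversion factor
#'   (mM cm^2 / ucoul) for a spherical cell; see [gamma_from_geometry()].
#' @param delta lateral extracellular-potassium diffusion coefficient
#'   between neighbouring cells (1/s); see [delta_from_geometry()].
#' @param therm_mV thermal voltage used by the Nernst equation (mV).
#' @return An object of class \code{"microenv_params"}.
#' @export
microenv_params <- function(rho = 1.25, G_glia = 66, eps = 1.2, K_bath = 3,
                            beta_vol = 7, gamma = 0.0445, delta = 0.278,
                            therm_mV = 26.64) {
  p <- list(rho = rho, G_glia = G_glia, eps = eps, K_bath = K_bath,
            beta_vol = beta_vol, gamma = gamma, delta = delta,
            therm_mV = therm_mV)
  bad <- names(p)[vapply(p, function(x) !is.finite(x) || x < 0, logical(1))]
  if (length(bad)) stop("microenvironment parameters must be finite and >= 0: ",
                        paste(bad, collapse = ", "))
  structure(p, class = "microenv_params")
}

#' Synaptic-coupling parameters of the PC-IN pair
#'
#' GABAergic (IN to PC) and AMPAergic (PC to IN) coupling, first-order
#' synaptic gating kinetics, and the depolarization-block gate chi(eta)
#' that shuts a cell's synaptic output off when its membrane potential
#' stays depolarized (the loss of the "inhibitory veto").
#'
#' @param g_inh,g_exc inhibitory/excitatory synaptic strengths
#'   (mS/cm^2); defaults 0.84 and 0.17.
#' @param tau_e,tau_i excitatory/inhibitory synaptic time constants (ms).
#' @param E_exc,E_inh synaptic reversal potentials (mV).
#' @param s_theta,s_slope half-activation (mV) and slope (mV) of the
#'   presynaptic-voltage sigmoid driving the synaptic gate s.
#' @param eta_theta,eta_slope,tau_eta half-activation (mV), slope (mV) and
#'   time constant (ms) of the slow depolarization integrator eta; eta
#'   relaxes toward a sigmoid of presynaptic voltage, so brief spikes leave
#'   it near 0 while sustained depolarization drives it toward 1.
#' @param eta_c,sigma_chi midpoint and steepness of the logistic block gate
#'   chi(eta) = 1/(1 + exp((eta - eta_c)/sigma_chi)).
#' @return An object of class \code{"synapse_params"}.
#' @export
synapse_params <- function(g_inh = 0.84, g_exc = 0.17, tau_e = 4, tau_i = 8,
                           E_exc = 0, E_inh = -80, s_theta = -20, s_slope = 3,
                           eta_theta = -40, eta_slope = 3, tau_eta = 1000,
                           eta_c = 0.5, sigma_chi = 0.05) {
  if (g_inh < 0 || g_exc < 0) stop("synaptic strengths must be >= 0")
  if (tau_e <= 0 || tau_i <= 0 || tau_eta <= 0)
    stop("synaptic time constants must be positive")
  structure(list(g_inh = g_inh, g_exc = g_exc, tau_e = tau_e, tau_i = tau_i,
                 E_exc = E_exc, E_inh = E_inh, s_theta = s_theta,
                 s_slope = s_slope, eta_theta = eta_theta,
                 eta_slope = eta_slope, tau_eta = tau_eta, eta_c = eta_c,
                 sigma_chi = sigma_chi),
            class = "synapse_params")
}

#' Bundle of cell + microenvironment parameters for a single neuron
#'
#' @param cell a [cell_params()] object.
#' @param env a [microenv_params()] object.
#' @return An object of class \code{"neuron_params"}.
#' @export
neuron_params <- function(cell = cell_params(), env = microenv_params()) {
  stopifnot(inherits(cell, "cell_params"), inherits(env, "microenv_params"))
  structure(list(cell = cell, env = env), class = "neuron_params")
}

#' Parameter bundle for the coupled PC-IN pair
#'
#' Microenvironment parameters are per cell so that, for example, weaker
#' glial buffering in the interneuron layer can be expressed.
#'
#' @param pc,int [neuron_params()] bundles for the pyramidal cell and the
#'   interneuron.
#' @param syn a [synapse_params()] object.
#' @return An object of class \code{"pair_params"}.
#' @export
pair_params <- function(pc = neuron_params(),
                        int = neuron_params(cell = cell_params("IN")),
                        syn = synapse_params()) {
  stopifnot(inherits(pc, "neuron_params"), inherits(int, "neuron_params"),
            inherits(syn, "synapse_params"))
  if (int$cell$cell_type != "IN") stop("`int` must have cell_type 'IN'")
  structure(list(pc = pc, int = int, syn = syn), class = "pair_params")
}

# ---- geometry helpers ------------------------------------------------------

#' Current-to-concentration factor from spherical-cell geometry
#'
#' gamma = A / (F * Vol) = 3 / (F * r) for a sphere of radius r converts a
#' membrane current density (uA/cm^2) into an intracellular concentration
#' rate of change (mM/s).  With the default 7 um radius this gives
#' ~0.0445 mM cm^2/ucoul; multiplied by the volume ratio beta_vol = 7 it
#' yields the ~0.3 factor scaling the potassium current in the
#' extracellular-potassium equation.
#'
#' @param radius_um cell radius in micrometres.
#' @return gamma in mM cm^2 / ucoul.
#' @export
gamma_from_geometry <- function(radius_um = 7) {
  3 / (96485 * radius_um * 1e-4)
}

#' Reservoir diffusion coefficient from Fick's law
#'
#' eps = 2 D / dx^2, with D the potassium diffusion constant in neocortex
#' and dx the average distance to the nearest capillary.
#'
#' @param D_cm2s potassium diffusion constant (cm^2/s).
#' @param dx_um capillary distance (um).
#' @return eps in 1/s.
#' @export
eps_from_geometry <- function(D_cm2s = 2.5e-6, dx_um = 20) {
  2 * D_cm2s / (dx_um * 1e-4)^2
}

#' Lateral diffusion coefficient between neighbouring cells
#'
#' delta = D / dx^2 with dx the PC-IN separation.
#'
#' @param D_cm2s potassium diffusion constant (cm^2/s).
#' @param dx_um cell separation (um).
#' @return delta in 1/s.
#' @export
delta_from_geometry <- function(D_cm2s = 2.5e-6, dx_um = 30) {
  D_cm2s / (dx_um * 1e-4)^2
}

#' Current density equivalent of an injected current
#'
#' Converts a pipette current in picoamperes to a current density in
#' uA/cm^2 using the spherical-cell area implied by \code{radius_um} (the
#' same geometry that sets \code{gamma}).  100 pA over a 7 um sphere gives
#' about 16.2 uA/cm^2.
#'
#' @param pA injected current (pA).
#' @param radius_um cell radius (um).
#' @return current density in uA/cm^2.
#' @export
current_density_from_pA <- function(pA, radius_um = 7) {
  area_cm2 <- 4 * pi * (radius_um * 1e-4)^2
  pA * 1e-6 / area_cm2
}

# ---- packing for the compiled code ----------------------------------------

pack_cell_pars <- function(cell, env, alpha_m = 1, pin_K_o = 4, pin_Na_i = 18) {
  v <- c(cell$C_m, cell$g_Na, cell$g_K, cell$g_AHP, cell$g_KL, cell$g_NaL,
         cell$g_ClL, cell$phi, cell$g_Ca, cell$E_Ca, cell$Cl_i, cell$Cl_o,
         env$rho, env$G_glia, env$eps, env$K_bath, env$beta_vol, env$gamma,
         env$therm_mV, alpha_m, pin_K_o, pin_Na_i)
  names(v) <- .cell_par_names
  v
}

pack_syn_pars <- function(syn, delta = 0) {
  v <- c(syn$g_inh, syn$g_exc, syn$tau_e, syn$tau_i, syn$E_exc, syn$E_inh,
         syn$s_theta, syn$s_slope, syn$eta_theta, syn$eta_slope, syn$tau_eta,
         delta, syn$eta_c, syn$sigma_chi)
  names(v) <- .syn_par_names
  v
}

# resolve user-facing tracked-parameter names ("G_glia", "in.eps",
# "syn.g_inh", ...) to 0-based indices into the concatenated
# [pc | in | syn] parameter vector used by the compiled filter
resolve_tracked <- function(track, model) {
  if (!length(track)) return(integer(0))
  idx <- vapply(track, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) parts <- c("pc", parts)
    block <- parts[1]
    base <- parts[2]
    if (block == "syn") {
      j <- match(base, .syn_par_names)
      if (is.na(j)) stop("unknown synaptic parameter: ", base)
      return(2L * length(.cell_par_names) + j - 1L)
    }
    j <- match(base, .cell_par_names)
    if (is.na(j)) stop("unknown parameter: ", base)
    off <- switch(block, pc = 0L, "in" = length(.cell_par_names),
                  stop("unknown parameter block: ", block))
    off + j - 1L
  }, integer(1))
  if (anyDuplicated(idx)) stop("duplicate tracked parameters")
  unname(idx)
}

# parameters that live on a positive scale get a log transform by default
.log_scale_pars <- c("C_m", "g_Na", "g_K", "g_AHP", "g_KL", "g_NaL", "g_ClL",
                     "phi", "g_Ca", "Cl_i", "Cl_o", "rho", "G_glia", "eps",
                     "K_bath", "beta_vol", "gamma", "therm_mV", "alpha_m",
                     "pin_K_o", "pin_Na_i", "g_inh", "g_exc", "tau_e",
                     "tau_i", "tau_eta", "delta", "sigma_chi")

default_transforms <- function(track) {
  vapply(track, function(nm) {
    base <- sub("^(pc|in|syn)\\.", "", nm)
    if (base %in% .log_scale_pars) "log" else "identity"
  }, character(1))
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>", x$cell$cell_type, "\n")
  cat("  cell:", paste(sprintf("%s=%g", setdiff(names(x$cell), "cell_type"),
                               unlist(x$cell[setdiff(names(x$cell), "cell_type")])),
                       collapse = ", "), "\n")
  cat("  env: ", paste(sprintf("%s=%g", names(x$env), unlist(x$env)),
                       collapse = ", "), "\n")
  invisible(x)
}
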