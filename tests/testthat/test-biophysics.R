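test_that("gating rates match direct formula evaluation and handle singularities", {
  for (V in c(-100, -81.3, -65, -42.7, 0, 35)) {
    expect_equal(gating_rate_functions(V), rates_direct(V), tolerance = 1e-12)
  }
  # removable singularities evaluate to the analytic limits
  expect_equal(gating_rate_functions(-30)[["alpha_m"]], 1.0, tolerance = 1e-9)
  expect_equal(gating_rate_functions(-34)[["alpha_n"]], 0.1, tolerance = 1e-9)
  # continuity across the singular voltages
  expect_equal(gating_rate_functions(-30 + 1e-9)[["alpha_m"]],
               gating_rate_functions(-30 - 1e-9)[["alpha_m"]],
               tolerance = 1e-6)
  expect_error(gating_rate_functions(NaN), "finite")
})

test_that("rates are non-negative and steady states lie in (0,1) on a voltage grid", {
  for (V in seq(-100, 50, by = 2.5)) {
    r <- gating_rate_functions(V)
    expect_true(all(r >= 0))
    ss <- gating_steady_state(V)
    expect_true(all(ss > 0 & ss < 1))
  }
})

test_that("gating derivatives vanish at steady state and are positive at the floor", {
  for (V in c(-80, -65, -30, 0)) {
    ss <- gating_steady_state(V)
    expect_equal(unname(gating_derivatives(V, ss)), c(0, 0, 0),
                 tolerance = 1e-12)
    d0 <- gating_derivatives(V, c(m = 0, h = 0, n = 0), phi = 3)
    r <- gating_rate_functions(V)
    expect_equal(unname(d0),
                 unname(3 * r[c("alpha_m", "alpha_h", "alpha_n")]),
                 tolerance = 1e-12)
    expect_true(all(d0 > 0))
  }
  # compositional check at mid-range gating
  d <- gating_derivatives(-65, c(m = .5, h = .5, n = .5), phi = 3)
  r <- gating_rate_functions(-65)
  expect_equal(d[["m"]], 3 * (r[["alpha_m"]] * .5 - r[["beta_m"]] * .5),
               tolerance = 1e-12)
  expect_error(gating_derivatives(-65, c(m = 1.2, h = .5, n = .5)), "\\[0, 1\\]")
})

test_that("dependent concentrations implement electroneutrality and sodium conservation", {
  expect_equal(dependent_concentrations(18), c(K_i = 140, Na_o = 144))
  expect_equal(dependent_concentrations(10)[["K_i"]], 148)
  expect_equal(dependent_concentrations(20, beta_vol = 7)[["Na_o"]], 130)
  # identities hold exactly for arbitrary Na_i
  for (nai in c(5, 12.34, 25.7)) {
    dep <- dependent_concentrations(nai)
    expect_equal(dep[["K_i"]] + nai, 158, tolerance = 1e-13)
    expect_equal(dep[["Na_o"]] + 7 * nai, 144 + 18 * 7, tolerance = 1e-13)
  }
  expect_error(dependent_concentrations(-1), "positive")
  expect_warning(dependent_concentrations(160), "validity")
})

test_that("Nernst reversals have the physiological signs and closed-form values", {
  env <- microenv_params()
  # K_o = 4 with K_i = 140 requires Na_i = 18 (then K_i = 140 exactly)
  rv <- nernst_reversals(c(K_o = 4, Na_i = 18))
  expect_equal(rv[["E_K"]], 26.64 * log(4 / 140), tolerance = 1e-12)
  expect_equal(rv[["E_Na"]], 26.64 * log(144 / 18), tolerance = 1e-12)
  expect_lt(rv[["E_K"]], 0)
  expect_gt(rv[["E_Na"]], 0)
  expect_equal(rv[["E_Cl"]], 26.64 * log(6 / 130), tolerance = 1e-12)
  # equal concentrations give a zero reversal
  cl_eq <- cell_params(Cl_i = 10, Cl_o = 10)
  expect_equal(nernst_reversals(c(K_o = 4, Na_i = 18), cl_eq)[["E_Cl"]], 0)
  expect_error(nernst_reversals(c(K_o = -1, Na_i = 18)), "positive")
})

test_that("membrane currents decompose term by term", {
  cell <- cell_params()
  st <- random_cell_state(7)
  rv <- nernst_reversals(st[c("K_o", "Na_i")], cell)
  cur <- membrane_currents(st[["V"]], st[c("m", "h", "n")], rv, st[["Ca_i"]],
                           cell)
  V <- st[["V"]]
  expect_equal(cur[["I_Na"]],
               100 * st[["m"]]^3 * st[["h"]] * (V - rv[["E_Na"]]) +
                 0.0175 * (V - rv[["E_Na"]]), tolerance = 1e-12)
  expect_equal(cur[["I_K"]],
               (40 * st[["n"]]^4 + 0.01 * st[["Ca_i"]] / (1 + st[["Ca_i"]])) *
                 (V - rv[["E_K"]]) + 0.05 * (V - rv[["E_K"]]),
               tolerance = 1e-12)
  expect_equal(cur[["I_L"]],
               cur[["leak_K"]] + cur[["leak_Na"]] + cur[["leak_Cl"]],
               tolerance = 1e-12)
  # null conductances kill all currents
  dead <- cell_params(g_Na = 0, g_K = 0, g_AHP = 0, g_KL = 0, g_NaL = 0,
                      g_ClL = 0, g_Ca = 0)
  cur0 <- membrane_currents(-40, c(m = .3, h = .5, n = .4), rv, 0.2, dead)
  expect_true(all(abs(cur0) < 1e-15))
  # interneurons carry no AHP current
  cin <- cell_params("IN")
  expect_identical(membrane_currents(-40, c(m = .3, h = .5, n = .4), rv, 5,
                                     cin)[["I_AHP"]], 0)
})

test_that("pump flux saturates at rho and is monotone in both substrates", {
  expect_identical(pump_flux(18, 4, rho = 0), 0)
  expect_gt(pump_flux(60, 30), 1.25 * 0.99)       # saturation
  expect_equal(pump_flux(18, 4),
               1.25 / ((1 + exp((25 - 18) / 3)) * (1 + exp(5.5 - 4))),
               tolerance = 1e-12)
  na_grid <- seq(5, 40, by = 2.5)
  expect_true(all(diff(pump_flux(na_grid, 4)) > 0))
  ko_grid <- seq(1, 20, by = 1)
  expect_true(all(diff(pump_flux(18, ko_grid)) > 0))
  expect_true(all(pump_flux(na_grid, 4) >= 0 & pump_flux(na_grid, 4) <= 1.25))
  expect_error(pump_flux(18, 4, rho = -1), ">= 0")
})

test_that("glial and bath fluxes follow their closed forms", {
  expect_identical(glial_flux(4, G_glia = 0), 0)
  expect_gt(glial_flux(60), 66 * 0.99)
  expect_equal(glial_flux(4), 66 / (1 + exp((18 - 4) / 2.5)), tolerance = 1e-12)
  ko <- seq(1, 30, by = 1)
  expect_true(all(diff(glial_flux(ko)) > 0))
  expect_identical(bath_flux(3, 3), 0)
  expect_equal(bath_flux(7, 3, eps = 1), 4)
  expect_equal(bath_flux(11, 3), 2 * bath_flux(7, 3))   # linearity
})

test_that("ion derivatives compose the tested fluxes with 3:2 pump stoichiometry", {
  cell <- cell_params()
  env <- microenv_params()
  st <- random_cell_state(11)
  d <- ion_derivatives(st, cell, env, coupling_term = 1.5)
  rv <- nernst_reversals(st[c("K_o", "Na_i")], cell, env)
  cur <- membrane_currents(st[["V"]], st[c("m", "h", "n")], rv, st[["Ca_i"]],
                           cell)
  pump <- pump_flux(st[["Na_i"]], st[["K_o"]])
  expect_equal(d[["K_o"]],
               (env$gamma * 7 * cur[["I_K"]] - 2 * 7 * pump -
                  glial_flux(st[["K_o"]]) - bath_flux(st[["K_o"]]) + 1.5) / 1000,
               tolerance = 1e-12)
  expect_equal(d[["Na_i"]], (-env$gamma * cur[["I_Na"]] - 3 * pump) / 1000,
               tolerance = 1e-12)
  # pump-only configuration isolates the electrogenic ratio exactly
  dead <- cell_params(g_Na = 0, g_K = 0, g_AHP = 0, g_KL = 0, g_NaL = 0,
                      g_ClL = 0, g_Ca = 0)
  off <- microenv_params(G_glia = 0, eps = 0, K_bath = 3)
  dp <- ion_derivatives(c(V = -65, m = 0, h = 0, n = 0, Ca_i = 0, K_o = 5,
                          Na_i = 20), dead, off)
  expect_equal(dp[["Na_i"]] / (dp[["K_o"]] / off$beta_vol), 3 / 2,
               tolerance = 1e-14)
  expect_error(ion_derivatives(c(V = -65, m = 0, h = 0, n = 0, Ca_i = 0,
                                 K_o = -1, Na_i = 20), cell, env), "positive")
})

test_that("the depolarization-block gate is a monotone unit-interval switch", {
  syn <- synapse_params()
  expect_gte(synaptic_gate_chi(0), 0.99)
  expect_lte(synaptic_gate_chi(5), 0.01)
  eta <- seq(0, 3, by = 0.05)
  chi <- synaptic_gate_chi(eta)
  expect_true(all(diff(chi) <= 0))
  expect_true(all(chi > 0 & chi <= 1))
  expect_error(synaptic_gate_chi(-0.1), ">= 0")
})

test_that("synaptic dynamics gate currents and admit voltage-dependent fixed points", {
  syn0 <- synapse_params(g_inh = 0, g_exc = 0)
  sd0 <- synaptic_dynamics(-60, -60, c(s_p = .5, eta_p = .1, s_i = .5,
                                       eta_i = .1), syn0)
  expect_identical(sd0$I_syn_pc, 0)
  expect_identical(sd0$I_syn_in, 0)
  # blocked interneuron silences the inhibition onto the PC
  syn <- synapse_params()
  open <- synaptic_dynamics(-60, -60, c(s_p = .5, eta_p = 0, s_i = .5,
                                        eta_i = 0), syn)
  blocked <- synaptic_dynamics(-60, -60, c(s_p = .5, eta_p = 0, s_i = .5,
                                           eta_i = 3), syn)
  expect_lt(abs(blocked$I_syn_pc), 0.01 * abs(open$I_syn_pc))
  # s at its voltage-dependent steady state has zero derivative
  sig <- function(V) 1 / (1 + exp(-(V - syn$s_theta) / syn$s_slope))
  sd_fp <- synaptic_dynamics(-30, -52, c(s_p = sig(-30), eta_p = .2,
                                         s_i = sig(-52), eta_i = .2), syn)
  expect_equal(sd_fp$derivs[["s_p"]], 0, tolerance = 1e-12)
  expect_equal(sd_fp$derivs[["s_i"]], 0, tolerance = 1e-12)
})

test_that("lateral potassium diffusion is symmetric and conservative", {
  expect_identical(unname(lateral_K_diffusion(4, 4, 1)), c(0, 0))
  expect_equal(lateral_K_diffusion(3, 9, 1)[["pc"]], 6)
  for (seed in 1:5) {
    set.seed(seed)
    kk <- runif(2, 1, 20)
    lat <- lateral_K_diffusion(kk[1], kk[2], runif(1, 0, 2))
    expect_identical(sum(lat), 0)
  }
  expect_error(lateral_K_diffusion(3, 9, -1), ">= 0")
})

test_that("single-cell RHS variants honour their contracts", {
  par <- neuron_params()
  rest <- resting_state(par)
  expect_lt(sqrt(sum(rhs_single_cell(rest, par)^2)), 1e-8)
  st <- random_cell_state(3)
  # fixed-ion mode pins the ion derivatives at zero identically
  dfix <- rhs_single_cell(st, par, mode = "fixed_ions")
  expect_identical(dfix[["K_o"]], 0)
  expect_identical(dfix[["Na_i"]], 0)
  # crippled mode with the true rate constant reduces to the full model
  a_true <- gating_rate_functions(st[["V"]])[["alpha_m"]]
  expect_equal(rhs_single_cell(st, par, mode = "crippled",
                               alpha_m_const = a_true),
               rhs_single_cell(st, par), tolerance = 1e-12)
  expect_error(rhs_single_cell(st, par, mode = "nonsense"), "arg")
})

test_that("coupled-pair RHS decouples, conserves potassium and composes", {
  par0 <- pair_params(pc = neuron_params(env = microenv_params(delta = 0)),
                      int = neuron_params(cell = cell_params("IN"),
                                          env = microenv_params(delta = 0)),
                      syn = synapse_params(g_inh = 0, g_exc = 0))
  st <- c(random_cell_state(5), random_cell_state(6),
          s_p = .2, eta_p = .1, s_i = .3, eta_i = .2)
  names(st) <- c(paste0("pc_", names(random_cell_state(1))),
                 paste0("in_", names(random_cell_state(1))),
                 "s_p", "eta_p", "s_i", "eta_i")
  d <- rhs_coupled_pair(st, par0)
  single_names <- c("V", "m", "h", "n", "Ca_i", "K_o", "Na_i")
  pc_state <- setNames(st[paste0("pc_", single_names)], single_names)
  in_state <- setNames(st[paste0("in_", single_names)], single_names)
  expect_equal(unname(d[paste0("pc_", single_names)]),
               unname(rhs_single_cell(pc_state, par0$pc)), tolerance = 1e-12)
  expect_equal(unname(d[paste0("in_", single_names)]),
               unname(rhs_single_cell(in_state, par0$int)), tolerance = 1e-12)
  # coupled: lateral exchange cancels in the pair sum of K_o derivatives
  par <- pair_params()
  for (seed in 1:4) {
    stc <- st
    stc["pc_K_o"] <- runif(1, 2, 10)
    stc["in_K_o"] <- runif(1, 2, 10)
    dc <- rhs_coupled_pair(stc, par)
    # remove every non-lateral contribution using a delta = 0 reference
    par_nolat <- par
    par_nolat$pc$env$delta <- 0
    d0 <- rhs_coupled_pair(stc, par_nolat)
    lat_pc <- dc[["pc_K_o"]] - d0[["pc_K_o"]]
    lat_in <- dc[["in_K_o"]] - d0[["in_K_o"]]
    expect_equal(lat_pc + lat_in, 0, tolerance = 1e-15)
  }
})

test_that("compiled right-hand sides agree with the R reference", {
  par <- neuron_params()
  pc <- neurokf:::pack_cell_pars(par$cell, par$env)
  for (seed in 1:8) {
    st <- random_cell_state(seed)
    expect_equal(unname(rhs_single_cell(st, par)),
                 as.numeric(neurokf:::cpp_rhs_single(unname(st), pc, 0L, 0, 0)),
                 tolerance = 1e-12)
  }
  # crippled and fixed-ion variants
  st <- random_cell_state(42)
  expect_equal(unname(rhs_single_cell(st, par, mode = "crippled",
                                      alpha_m_const = 0.7)),
               as.numeric(neurokf:::cpp_rhs_single(
                 unname(st),
                 neurokf:::pack_cell_pars(par$cell, par$env, alpha_m = 0.7),
                 2L, 0, 0)), tolerance = 1e-12)
  expect_equal(unname(rhs_single_cell(st, par, mode = "fixed_ions",
                                      pin = c(K_o = 4, Na_i = 18))),
               as.numeric(neurokf:::cpp_rhs_single(unname(st), pc, 1L, 0, 0)),
               tolerance = 1e-12)
  # coupled pair
  pp <- pair_params()
  st18 <- c(random_cell_state(1), random_cell_state(2),
            s_p = .2, eta_p = .1, s_i = .3, eta_i = .2)
  names(st18) <- neurokf:::.state_names_pair
  expect_equal(unname(rhs_coupled_pair(st18, pp)),
               as.numeric(neurokf:::cpp_rhs_pair(
                 unname(st18),
                 neurokf:::pack_cell_pars(pp$pc$cell, pp$pc$env),
                 neurokf:::pack_cell_pars(pp$int$cell, pp$int$env),
                 neurokf:::pack_syn_pars(pp$syn, delta = pp$pc$env$delta),
                 0, 0)), tolerance = 1e-12)
})

test_that("geometry helpers reproduce the configured constants", {
  expect_equal(gamma_from_geometry(7), 0.0445, tolerance = 0.01)
  expect_equal(eps_from_geometry(), 1.25, tolerance = 1e-12)
  expect_equal(current_density_from_pA(100, 7), 16.2, tolerance = 0.01)
})
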