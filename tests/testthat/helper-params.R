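# Small helper parameter sets used across tests. These are NOT the
# reference set: they are simple kinetics for which analytic results
# are easy to state.

# all-linear decay-only kinetics (no production, no binding)
decay_params <- function(dP = 0.3, dF = 0.2, dT = 0.5, dC = 0.1) {
  model_parameters(rho_P = 0, sigma_P = 0, n_hill = 2, K_hill = 1,
                   rho_F = 0, rho_T = 0,
                   delta_P = dP, delta_F = dF, delta_T = dT, delta_C = dC,
                   k_on = 0, k_off = 0, k_b = 0, k_u = 1, R_tot = 1,
                   beta = 0, gamma = 0, D_F = 0, D_T = 0, D_C = 0)
}

# generic mildly nonlinear set with every process active; not tuned to
# any instability, used for steady-state/jacobian consistency checks
generic_params <- function() {
  model_parameters(rho_P = 1.2, sigma_P = 0.05, n_hill = 2, K_hill = 1,
                   rho_F = 0.4, rho_T = 0.3,
                   delta_P = 0.5, delta_F = 0.3, delta_T = 0.4,
                   delta_C = 0.1, k_on = 2, k_off = 0.5, k_b = 1,
                   k_u = 0.4, R_tot = 1.5, beta = 2, gamma = 1,
                   D_F = 0.1, D_T = 0.05, D_C = 1)
}

ref_params <- function() reference_parameters()

uniform_state <- function(v, geometry) {
  v <- as.numeric(v)
  turingov:::state_from_scalars(
    c(P = v[1], F = v[2], T = v[3], C = v[4], B = v[5]), geometry)
}
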