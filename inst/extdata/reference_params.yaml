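# Reference parameter set of the Pax6/Fst/Tgfb2 reaction-diffusion model.
# Located by a documented parameter sweep (see the methods vignette):
# the uniform Pax6-positive state is stable without diffusion,
# Turing-unstable with fast complex diffusion (D_C >> D_F), stable again
# when D_C is lowered to D_F, and the fastest-growing mode is
# stationary and anti-phase in the receptor signal (a Pax6 pole flanked
# by receptor-signalling poles). Units of space, time and concentration
# are arbitrary but internally consistent. Dominant pattern wavelength
# approximately 38 length units.
rho_P: 2.2
sigma_P: 0.44
n_hill: 2.0
K_hill: 1.0
rho_F: 0.05
rho_T: 0.022
delta_P: 0.1
delta_F: 0.06
delta_T: 0.05
delta_C: 0.04
k_on: 1.6
k_off: 0.055
k_b: 0.125
k_u: 0.285
R_tot: 2.2
beta: 320.0
gamma: 1.0
D_F: 0.1
D_T: 0.0
D_C: 30.0
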