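# Secondary parameter set: the wave-instability (oscillatory Turing)
# corner of the model. The fastest-growing mode at beta = 44.3 is
# complex (a rotating, production-dominated mode, in-phase in the
# receptor signal); increasing the negative feedback on Pax6 by 2%
# (beta = 45.2) makes the fastest-growing mode stationary (turing
# classification). Receptor kinetics are slow (k_b, k_u) -- a
# structural requirement of the rotating mode in this network.
rho_P: 0.284
sigma_P: 0.000966
n_hill: 2.0
K_hill: 1.0
rho_F: 0.0935
rho_T: 0.0597
delta_P: 0.0224
delta_F: 0.345
delta_T: 1.216
delta_C: 0.01726
k_on: 2.786
k_off: 1.904
k_b: 0.01049
k_u: 0.006313
R_tot: 2.248
beta: 44.3
gamma: 1.0
D_F: 0.04904
D_T: 0.0
D_C: 30.0
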