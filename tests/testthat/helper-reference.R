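# Shared objects for the reference-set tests: computed once per session.
ref_cache <- new.env()

ref_disp <- function() {
  if (is.null(ref_cache$disp))
    ref_cache$disp <- dispersion_relation(reference_parameters())
  ref_cache$disp
}

ref_ss <- function() {
  if (is.null(ref_cache$ss))
    ref_cache$ss <- homogeneous_steady_state(reference_parameters())
  ref_cache$ss
}

# de-novo run on a periodic ring of `mult` pattern wavelengths
denovo_run <- function(mult, seed, dx = 0.25, t_end = 10000) {
  p <- reference_parameters()
  lam <- ref_disp()$lambda_pattern
  n <- round(mult * lam / dx)
  g <- grid_1d(n, dx, "periodic")
  ic <- noisy_homogeneous_ic(ref_ss(), g, 0.05, seed)
  integrate_model(p, ic, g, variant = "B",
                  settings = solver_settings(t_end, t_end / 120, seed = seed))
}
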