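#' Kinetic, diffusion and coupling constants of the Pax6/Fst/Tgfb2 network
#'
#' Constructs a validated parameter set for the five-species
#' reaction-diffusion model of optic-vesicle patterning. The species are
#' Pax6 (`P`, a non-diffusing transcription factor), free Follistatin
#' (`F`), free Tgfb2 (`T`), the Fst:Tgfb2 complex (`C`) and the activated
#' Tgfb2:receptor complex (`B`, membrane bound, non-diffusing). Units of
#' space, time and concentration are arbitrary but must be used
#' consistently.
#'
#' @param rho_P maximal Pax6 autoregulatory production rate (conc/time).
#' @param sigma_P basal Pax6 production rate (conc/time).
#' @param n_hill Hill coefficient of Pax6 autoregulation (>= 1).
#' @param K_hill half-maximal Pax6 activity of the autoregulation (conc).
#' @param rho_F,rho_T Fst and Tgfb2 production rates per unit Pax6
#'   activity (1/time).
#' @param delta_P,delta_F,delta_T,delta_C first-order decay rates
#'   (1/time). Decay of the complex destroys both constituents; free
#'   ligand is released only by dissociation (`k_off`).
#' @param k_on Fst--Tgfb2 association rate (1/(conc time)).
#' @param k_off Fst:Tgfb2 dissociation rate (1/time).
#' @param k_b Tgfb2--receptor binding rate (1/(conc time)).
#' @param k_u receptor-complex unbinding rate (1/time).
#' @param R_tot total receptor concentration per grid point (conc, > 0).
#' @param beta strength of the inhibition of Pax6 transcriptional
#'   activity by receptor signalling (1/conc).
#' @param gamma strength of the transcriptional suppression of Pax6 by
#'   Shh (1/conc).
#' @param D_F,D_T,D_C diffusion coefficients of free Fst, free Tgfb2 and
#'   the Fst:Tgfb2 complex (length^2/time).
#'
#' @return An object of class `ov_params`: a named list with the fields
#'   above.
#'
#' @details The reference set (see [reference_parameters()]) satisfies
#' `D_C > D_F`: lateral transport of Tgfb2 is carried by the
#' fast-diffusing ligand:antagonist complex while Fst monomers disperse
#' slowly, the condition under which local inhibition and lateral
#' activation of Tgfb signalling arise.
#'
#' @seealso [reference_parameters()], [apply_lof()], [read_parameters()]
#' @export
model_parameters <- function(rho_P, sigma_P, n_hill, K_hill,
                             rho_F, rho_T,
                             delta_P, delta_F, delta_T, delta_C,
                             k_on, k_off, k_b, k_u, R_tot,
                             beta, gamma,
                             D_F, D_T, D_C) {
  p <- list(rho_P = rho_P, sigma_P = sigma_P, n_hill = n_hill,
            K_hill = K_hill, rho_F = rho_F, rho_T = rho_T,
            delta_P = delta_P, delta_F = delta_F, delta_T = delta_T,
            delta_C = delta_C, k_on = k_on, k_off = k_off,
            k_b = k_b, k_u = k_u, R_tot = R_tot,
            beta = beta, gamma = gamma,
            D_F = D_F, D_T = D_T, D_C = D_C)
  validate_parameters(p)
  structure(p, class = "ov_params")
}

validate_parameters <- function(p) {
  nm <- c("rho_P", "sigma_P", "n_hill", "K_hill", "rho_F", "rho_T",
          "delta_P", "delta_F", "delta_T", "delta_C", "k_on", "k_off",
          "k_b", "k_u", "R_tot", "beta", "gamma", "D_F", "D_T", "D_C")
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  for (n in nm) {
    v <- p[[n]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", n, "' must be a single finite number")
    if (v < 0)
      stop("parameter '", n, "' must be non-negative")
  }
  if (p$R_tot <= 0) stop("R_tot must be > 0")
  if (p$n_hill < 1) stop("n_hill must be >= 1")
  if (p$K_hill <= 0) stop("K_hill must be > 0")
  invisible(p)
}

#' @export
print.ov_params <- function(x, ...) {
  cat("Pax6/Fst/Tgfb2 model parameters\n")
  v <- unlist(x)
  for (i in seq_along(v))
    cat(sprintf("  %-8s %g\n", names(v)[i], v[i]))
  invisible(x)
}

#' Reference parameter set
#'
#' Returns the package's reference parameter set, read from the
#' version-pinned configuration shipped in `inst/extdata/`. The set was
#' located by a parameter sweep over the kinetic and diffusion constants
#' subject to the qualitative constraints the model must satisfy: the
#' spatially uniform state is stable without diffusion, Turing-unstable
#' with the shipped diffusion coefficients (`D_C > D_F`), stable again
#' when complex and Fst diffusion are equalised, and the fastest-growing
#' mode is oscillatory (a wave instability) at the reference feedback
#' strength `beta` but stationary when `beta` is increased (see
#' [dispersion_relation()]).
#'
#' @return An `ov_params` object.
#' @export
reference_parameters <- function() {
  read_parameters(system.file("extdata", "reference_params.yaml",
                              package = "turingov", mustWork = TRUE))
}

#' Secondary parameter set: the wave-instability corner
#'
#' A documented parameter set from the oscillatory corner of the model:
#' the fastest-growing mode is complex (`oscillatory_turing`
#' classification, a rotating mode whose receptor signal lags Pax6),
#' and a 2 percent increase of the feedback strength `beta` (44.3 to
#' 45.2) makes the fastest-growing mode stationary (`turing`) —
#' increasing the negative feedback that Tgfb signalling exerts on Pax6
#' suppresses the tendency to oscillate. Rotating modes in this network
#' require slow receptor kinetics and are production-dominated, hence
#' in-phase: they do not reproduce the anti-phase receptor pattern of
#' the reference set (see the methods vignette for the structural
#' argument).
#'
#' @return An `ov_params` object.
#' @seealso [reference_parameters()]
#' @export
oscillatory_parameters <- function() {
  read_parameters(system.file("extdata", "oscillatory_params.yaml",
                              package = "turingov", mustWork = TRUE))
}

#' Read or write a parameter set as a flat YAML file
#'
#' Parameter files are flat key-value YAML; every key is named exactly as
#' the corresponding [model_parameters()] field.
#'
#' @param path file path.
#' @return `read_parameters()` returns an `ov_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  p <- yaml::read_yaml(path)
  do.call(model_parameters, p)
}

#' @rdname read_parameters
#' @param params an `ov_params` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "ov_params"))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(path)
}

#' In-silico loss-of-function perturbations
#'
#' Maps the pharmacological perturbations of the patterning experiments
#' onto the model couplings: blocking Smad3 (SIS3) removes the
#' inhibition of Pax6 by Tgfb receptor signalling (`beta = 0`);
#' blocking Shh signalling (cyclopamine) removes the suppression of
#' Pax6 by the Shh gradient (`gamma = 0`); the double perturbation zeroes
#' both.
#'
#' @param params an `ov_params` object.
#' @param which one of `"tgfb_lof"`, `"shh_lof"`, `"double_lof"`.
#' @return A copy of `params` with only the targeted coupling(s) zeroed.
#' @export
apply_lof <- function(params, which = c("tgfb_lof", "shh_lof", "double_lof")) {
  stopifnot(inherits(params, "ov_params"))
  which <- match.arg(which)
  out <- params
  if (which %in% c("tgfb_lof", "double_lof")) out$beta <- 0
  if (which %in% c("shh_lof", "double_lof")) out$gamma <- 0
  out
}
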