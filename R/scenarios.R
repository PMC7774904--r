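#' Noisy homogeneous initial condition
#'
#' The de-novo patterning initial condition: Pax6 starts at its uniform
#' steady-state value modulated by multiplicative uniform noise,
#' `P = P* (1 + eps(x))` with `eps ~ U(-a, a)`; all other species start
#' exactly at steady state (only Pax6 is initially noisy).
#'
#' @param steady_state named vector from [homogeneous_steady_state()].
#' @param geometry an `ov_grid` or `ov_mask`.
#' @param noise_amplitude relative amplitude `a`, in (0, 0.2].
#' @param seed integer RNG seed (required; runs must be reproducible).
#' @return An `ov_state`.
#' @export
noisy_homogeneous_ic <- function(steady_state, geometry,
                                 noise_amplitude = 0.05, seed) {
  if (!is.numeric(noise_amplitude) || noise_amplitude <= 0 ||
      noise_amplitude > 0.2)
    stop("noise_amplitude must lie in (0, 0.2]")
  if (missing(seed)) stop("a seed is required")
  base <- state_from_scalars(steady_state, geometry)
  set.seed(as.integer(seed))
  eps <- stats::runif(length(base$P), -noise_amplitude, noise_amplitude)
  P <- base$P * (1 + eps)
  if (any(P < 0)) stop("noise amplitude produced negative Pax6")
  dim(P) <- dim(base$P)
  base$P <- P
  base
}

#' Graded Pax6 pre-pattern initial condition
#'
#' The explant initial condition: Pax6 graded from `high_value` at the
#' "distal" end to `low_value` at the other, along the requested domain
#' axis. For the explant the distal end sits on the SHORT axis: explant
#' collapse shortens the former proximal-distal dimension, so the
#' initial polarity runs perpendicular to the long axis. Other species
#' are set to their local quasi-steady values given the local Pax6
#' (clamped receptor/sequestration balance from the uniform steady-state
#' solver evaluated per level).
#'
#' @param geometry an `ov_grid` or `ov_mask`.
#' @param params an `ov_params` (used for the quasi-steady slaving).
#' @param high_value,low_value Pax6 at the two ends
#'   (`high_value > low_value >= 0`).
#' @param axis `"short"` or `"long"` (2D); 1D geometries use the single
#'   axis and reject `"long"` only when meaningless is requested... For a
#'   1D grid the gradient runs along x regardless.
#' @param profile `"linear"` or `"step"`.
#' @param noise_amplitude relative multiplicative noise applied to the
#'   graded Pax6 field (uniform, seeded). Expression is never perfectly
#'   graded in tissue, and a deterministic symmetric profile would
#'   leave every transverse mode unseeded; the default 2% floor is
#'   below the 5% de-novo noise level.
#' @param seed integer RNG seed for the noise floor (required when
#'   `noise_amplitude > 0`).
#' @return An `ov_state`.
#' @export
prepattern_ic <- function(geometry, params, high_value, low_value,
                          axis = c("short", "long"),
                          profile = c("linear", "step"),
                          noise_amplitude = 0.02, seed = NULL) {
  axis <- match.arg(axis)
  profile <- match.arg(profile)
  if (!(high_value > low_value) || low_value < 0)
    stop("need high_value > low_value >= 0")
  if (inherits(geometry, "ov_grid")) {
    u <- (geometry$x - min(geometry$x)) /
      (max(geometry$x) - min(geometry$x))
  } else if (inherits(geometry, "ov_mask")) {
    co <- if (axis == "long") geometry$xc else geometry$yc
    u <- (co - min(co[geometry$mask])) /
      (max(co[geometry$mask]) - min(co[geometry$mask]))
    u <- pmin(pmax(u, 0), 1)
  } else stop("unknown geometry")
  # distal (high) end at u = 1
  P <- if (profile == "step") ifelse(u >= 0.5, high_value, low_value)
       else low_value + u * (high_value - low_value)
  slave <- quasi_steady_slaves(params, c(low_value, high_value))
  frac <- if (profile == "step") as.numeric(u >= 0.5) else u
  st <- list(P = P)
  for (nm in c("F", "T", "C", "B"))
    st[[nm]] <- slave[[nm]][1] + frac * (slave[[nm]][2] - slave[[nm]][1])
  if (noise_amplitude > 0) {
    if (is.null(seed)) stop("a seed is required for the noise floor")
    set.seed(as.integer(seed))
    st$P <- st$P * (1 + stats::runif(length(st$P),
                                     -noise_amplitude, noise_amplitude))
  }
  if (inherits(geometry, "ov_mask"))
    for (nm in species_names()) dim(st[[nm]]) <- dim(geometry$mask)
  field_state(st$P, st$F, st$T, st$C, st$B)
}

# quasi-steady F,T,C,B for fixed Pax6 levels (P held, not solved)
quasi_steady_slaves <- function(params, P_levels) {
  out <- list(F = numeric(0), T = numeric(0), C = numeric(0), B = numeric(0))
  for (P in P_levels) {
    pfix <- params
    # solve the F/T/C/B subsystem with Pax6 activity fixed at P (beta
    # feedback folded in by iterating the activity)
    a <- P
    for (i in 1:200) {
      s <- steady_slaves_given_activity(pfix, a)
      a_new <- P / (1 + pfix$beta * s[["B"]])
      if (abs(a_new - a) < 1e-12 * (1 + a)) { a <- a_new; break }
      a <- a + 0.6 * (a_new - a)
    }
    s <- steady_slaves_given_activity(pfix, a)
    for (nm in names(out)) out[[nm]] <- c(out[[nm]], s[[nm]])
  }
  out
}

steady_slaves_given_activity <- function(p, a) {
  q <- if (p$k_off + p$delta_C > 0) p$delta_C / (p$k_off + p$delta_C) else 0
  if (a <= 0) {
    return(c(F = 0, T = 0, C = 0, B = 0))
  }
  Thi <- p$rho_T * a / p$delta_T + 1e-12
  g <- function(Tv) {
    Fv <- p$rho_F * a / (p$delta_F + p$k_on * q * Tv)
    p$rho_T * a - p$k_on * q * Fv * Tv - p$delta_T * Tv
  }
  Tv <- stats::uniroot(g, c(0, Thi), tol = 1e-15)$root
  Fv <- p$rho_F * a / (p$delta_F + p$k_on * q * Tv)
  Bv <- p$R_tot * p$k_b * Tv / (p$k_b * Tv + p$k_u + (p$k_b * Tv + p$k_u == 0))
  Cv <- if (p$k_off + p$delta_C > 0) p$k_on * Fv * Tv / (p$k_off + p$delta_C) else 0
  c(F = Fv, T = Tv, C = Cv, B = unname(Bv))
}

#' Static Shh gradient field
#'
#' A monotone ventral-high to dorsal-low Shh activity profile on the
#' geometry: linear from `peak` to 0, or exponential with decay length
#' half the domain extent along the gradient axis. `inverted = TRUE`
#' flips the ends (gradient-reversal experiment); `peak = 0` yields the
#' identically-zero field (Shh loss of function on a compatible
#' geometry).
#'
#' @param geometry an `ov_grid` or `ov_mask`.
#' @param peak Shh activity at the ventral end (>= 0).
#' @param form `"linear"` or `"exponential"`.
#' @param axis axis the gradient runs along: `"long"` or `"short"`
#'   (2D masks; 1D grids use their single axis).
#' @param inverted flip the gradient end-to-end.
#' @return An `ov_shh`.
#' @export
shh_gradient <- function(geometry, peak, form = c("linear", "exponential"),
                         axis = c("long", "short"), inverted = FALSE) {
  form <- match.arg(form)
  axis <- match.arg(axis)
  if (peak < 0) stop("peak must be >= 0")
  if (inherits(geometry, "ov_grid")) {
    u <- (geometry$x - min(geometry$x)) / (max(geometry$x) - min(geometry$x))
    ext <- geometry$length
  } else if (inherits(geometry, "ov_mask")) {
    co <- if (axis == "long") geometry$xc else geometry$yc
    u <- (co - min(co[geometry$mask])) /
      (max(co[geometry$mask]) - min(co[geometry$mask]))
    u <- pmin(pmax(u, 0), 1)
    ext <- if (axis == "long") geometry$long_axis else geometry$short_axis
  } else stop("unknown geometry")
  if (inverted) u <- 1 - u
  # ventral (peak) end at u = 0
  S <- if (form == "linear") peak * (1 - u)
       else peak * exp(-u * ext / (ext / 2))
  S[S < 0] <- 0
  shh_field(S, direction = paste0(axis, if (inverted) " (inverted)" else ""),
            inverted = inverted)
}

#' Scenario configuration
#'
#' A self-contained description of one simulation: model variant,
#' geometry, initial condition, Shh input, loss-of-function tag, seed
#' and run length. Configurations round-trip through YAML and fully
#' determine a run together with the package defaults.
#'
#' @param variant `"A"`, `"B"`, `"C"` or `"D"`.
#' @param geometry list: either `list(type = "grid1d", n_points, dx,
#'   boundary)` or `list(type = "explant", long_axis, short_axis, dx,
#'   shape)`.
#' @param ic list: `list(type = "noisy_homogeneous", noise_amplitude)`,
#'   `list(type = "distal_high_prepattern", high_value, low_value, axis,
#'   profile)` or `list(type = "fixed_pax6_source", high_value,
#'   low_value)` (variant A's frozen regional pattern).
#' @param shh list or `NULL`: `list(peak, form, axis, inverted)`.
#' @param lof `NULL`, `"tgfb_lof"`, `"shh_lof"` or `"double_lof"`.
#' @param seed integer RNG seed.
#' @param t_end,snapshot_interval run length and snapshot spacing
#'   (`NULL` = package defaults for the variant).
#' @param params an `ov_params` or `NULL` for the reference set.
#' @return An object of class `ov_config`.
#' @export
scenario_config <- function(variant, geometry, ic, shh = NULL, lof = NULL,
                            seed = 1L, t_end = NULL,
                            snapshot_interval = NULL, params = NULL) {
  variant <- match.arg(variant, c("A", "B", "C", "D"))
  if (variant == "A" && !identical(ic$type, "fixed_pax6_source"))
    stop("variant A requires the fixed_pax6_source initial condition")
  if (variant == "D" && is.null(shh))
    stop("variant D requires an Shh specification")
  if (!is.null(lof))
    lof <- match.arg(lof, c("tgfb_lof", "shh_lof", "double_lof"))
  structure(list(variant = variant, geometry = geometry, ic = ic,
                 shh = shh, lof = lof, seed = as.integer(seed),
                 t_end = t_end, snapshot_interval = snapshot_interval,
                 params = params),
            class = "ov_config")
}

#' Read or write a scenario configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns an `ov_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- if (!is.null(y$params)) do.call(model_parameters, y$params)
  scenario_config(variant = y$variant, geometry = y$geometry, ic = y$ic,
                  shh = y$shh, lof = y$lof, seed = y$seed %||% 1L,
                  t_end = y$t_end, snapshot_interval = y$snapshot_interval,
                  params = params)
}

#' @rdname read_config
#' @param config an `ov_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ov_config"))
  y <- unclass(config)
  if (!is.null(y$params)) y$params <- lapply(unclass(y$params), as.numeric)
  y <- Filter(Negate(is.null), y)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Canonical scenario configurations
#'
#' Returns one of the nine scenario configurations shipped with the
#' package, covering the four model variants and their perturbations:
#'
#' \describe{
#'   \item{modelA_prepattern}{variant A, 1D, Pax6 frozen as a regional
#'     (distal-high) pattern.}
#'   \item{modelB_denovo}{variant B, 1D, noisy homogeneous Pax6: de-novo
#'     polarisation at the baseline tissue size.}
#'   \item{modelB_denovo_large}{as modelB_denovo on a larger domain:
#'     multiple poles.}
#'   \item{modelC_explant}{variant B kinetics on a 2:1 capsule explant
#'     with a short-axis distal-high pre-pattern: repolarisation along
#'     the long axis.}
#'   \item{modelD_shh}{variant D on the explant with a ventral-high Shh
#'     gradient along the long axis.}
#'   \item{modelD_shh_inverted}{gradient reversed.}
#'   \item{modelD_tgfb_lof}{variant D with `beta = 0` (Smad3 block).}
#'   \item{modelD_shh_lof}{variant D with `gamma = 0` (Shh block).}
#'   \item{modelD_double_lof}{both couplings removed.}
#' }
#'
#' @param name configuration name (see above).
#' @return An `ov_config`.
#' @export
canonical_config <- function(name) {
  path <- system.file("configs", paste0(name, ".yaml"), package = "turingov")
  if (path == "") stop("unknown canonical config '", name, "'")
  read_config(path)
}

#' @rdname canonical_config
#' @export
canonical_config_names <- function() {
  c("modelA_prepattern", "modelB_denovo", "modelB_denovo_large",
    "modelC_explant", "modelD_shh", "modelD_shh_inverted",
    "modelD_tgfb_lof", "modelD_shh_lof", "modelD_double_lof")
}

#' Build an integrate-ready bundle from a configuration
#'
#' Materialises the geometry, parameter set (with any loss-of-function
#' tag applied), initial state and Shh field described by a scenario
#' configuration.
#'
#' @param config an `ov_config`.
#' @return A list with elements `params`, `initial`, `geometry`, `shh`,
#'   `variant`, `settings`, `config`.
#' @export
build_scenario <- function(config) {
  stopifnot(inherits(config, "ov_config"))
  params <- config$params %||% reference_parameters()
  if (!is.null(config$lof)) params <- apply_lof(params, config$lof)

  g <- config$geometry
  geometry <- switch(g$type,
    grid1d = grid_1d(g$n_points, g$dx, g$boundary %||% "zero_flux"),
    explant = explant_mask(g$long_axis, g$short_axis, g$dx,
                           g$shape %||% "capsule"),
    stop("unknown geometry type '", g$type, "'"))

  shh <- NULL
  if (!is.null(config$shh)) {
    shh <- shh_gradient(geometry, peak = config$shh$peak,
                        form = config$shh$form %||% "linear",
                        axis = config$shh$axis %||% "long",
                        inverted = isTRUE(config$shh$inverted))
  } else if (config$variant == "D") {
    stop("variant D requires an Shh specification")
  }

  # steady state used for ICs: solved with the LOF-adjusted parameters,
  # at zero Shh (the gradient is a spatial perturbation, not a base level)
  ss <- homogeneous_steady_state(params)
  ic <- config$ic
  initial <- switch(ic$type,
    noisy_homogeneous = noisy_homogeneous_ic(ss, geometry,
      noise_amplitude = ic$noise_amplitude %||% 0.05, seed = config$seed),
    distal_high_prepattern = prepattern_ic(geometry, params,
      high_value = ic$high_value, low_value = ic$low_value,
      axis = ic$axis %||% "short", profile = ic$profile %||% "linear",
      noise_amplitude = ic$noise_amplitude %||% 0.02, seed = config$seed),
    fixed_pax6_source = prepattern_ic(geometry, params,
      high_value = ic$high_value, low_value = ic$low_value,
      axis = ic$axis %||% "short", profile = ic$profile %||% "step",
      noise_amplitude = ic$noise_amplitude %||% 0, seed = config$seed),
    stop("unknown initial-condition type '", ic$type, "'"))

  t_end <- config$t_end %||% default_t_end(params)
  settings <- solver_settings(
    t_end = t_end,
    snapshot_interval = config$snapshot_interval %||% (t_end / 120),
    seed = config$seed)

  list(params = params, initial = initial, geometry = geometry, shh = shh,
       variant = config$variant, settings = settings, config = config)
}

# default run length: long enough for the fastest-growing mode of the
# reference regime to amplify 5% noise to saturation (and for LOF
# variants, to relax); fixed per parameter set, not adaptive
default_t_end <- function(params) {
  disp <- try(dispersion_relation(params), silent = TRUE)
  if (!inherits(disp, "try-error") &&
      disp$classification %in% c("turing", "oscillatory_turing") &&
      disp$growth_at_kmax > 0)
    return(round(14 / disp$growth_at_kmax))
  # stable kinetics: relax over several slowest decay times
  5 / min(params$delta_P, params$delta_F, params$delta_T + params$delta_C)
}

#' Run a scenario configuration end to end
#'
#' Convenience wrapper: [build_scenario()] then [integrate_model()].
#'
#' @param config an `ov_config` or canonical config name.
#' @return An `ov_result`.
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- canonical_config(config)
  b <- build_scenario(config)
  integrate_model(b$params, b$initial, b$geometry, shh = b$shh,
                  variant = b$variant, settings = b$settings)
}
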