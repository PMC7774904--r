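#' Concentration fields of the five model species
#'
#' Bundles the five concentration fields on a common spatial grid:
#' Pax6 (`P`), free Follistatin (`F`), free Tgfb2 (`T`), the Fst:Tgfb2
#' complex (`C`) and the activated Tgfb2:receptor complex (`B`). Fields
#' are numeric vectors (1D grids) or matrices (2D masked domains) and
#' must share one shape.
#'
#' @param P,F,T,C,B numeric arrays of identical shape, non-negative.
#' @return An object of class `ov_state` (a named list of the five
#'   fields).
#' @export
field_state <- function(P, F, T, C, B) {
  s <- list(P = P, F = F, T = T, C = C, B = B)
  d0 <- dim(P) %||% length(P)
  for (n in names(s)) {
    f <- s[[n]]
    if (!is.numeric(f)) stop("field '", n, "' must be numeric")
    if (!identical(dim(f) %||% length(f), d0))
      stop("field '", n, "' does not match the shape of P")
    if (any(f < -1e-9, na.rm = TRUE))
      stop("field '", n, "' has negative entries beyond tolerance")
  }
  structure(s, class = "ov_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

species_names <- function() c("P", "F", "T", "C", "B")

#' @export
print.ov_state <- function(x, ...) {
  d <- dim(x$P)
  cat("field state on a", if (is.null(d)) paste0("1D grid (", length(x$P),
      " points)") else paste0("2D raster (", d[1], " x ", d[2], ")"), "\n")
  for (n in species_names())
    cat(sprintf("  %s: [%.4g, %.4g]\n", n, min(x[[n]]), max(x[[n]])))
  invisible(x)
}

#' Static Shh activity field
#'
#' A non-negative Shh activity per grid point together with descriptive
#' metadata. `S` identically zero encodes Shh loss of function on any
#' geometry.
#'
#' @param S numeric array of Shh activity (>= 0).
#' @param direction label of the axis the gradient runs along
#'   (informational).
#' @param inverted logical; whether the gradient has been flipped
#'   end-to-end.
#' @return An object of class `ov_shh`.
#' @export
shh_field <- function(S, direction = "none", inverted = FALSE) {
  if (any(S < 0, na.rm = TRUE)) stop("Shh activity must be non-negative")
  structure(list(S = S, direction = direction, inverted = inverted),
            class = "ov_shh")
}

#' Effective Pax6 transcriptional activity under Tgfb signalling
#'
#' Receptor signalling acts on Pax6 protein function (Smad3 blocks
#' Pax6-DNA binding), not on its transcription, so inhibition is applied
#' to the activity that enters every transcription term, including
#' Pax6's own autoregulation: `P* = P / (1 + beta * B)`.
#'
#' @param P Pax6 concentration field.
#' @param B activated receptor-complex field, same shape as `P`.
#' @param beta inhibition strength (1/conc, >= 0).
#' @return The effective activity field `P*`, pointwise `<= P`, equal to
#'   `P` wherever `B = 0`.
#' @export
pax6_activity <- function(P, B, beta) {
  if (!identical(dim(P) %||% length(P), dim(B) %||% length(B)))
    stop("P and B must have the same shape")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("beta must be a single non-negative number")
  P / (1 + beta * B)
}

#' Pointwise reaction rates of the network
#'
#' Evaluates the reaction part of the model (no diffusion) at every grid
#' point. With `P* = pax6_activity(P, B, beta)` and Shh attenuation
#' `h = 1 / (1 + gamma * S)` the governing forms are
#' \deqn{dP/dt = h (\rho_P P^{*n} / (K^n + P^{*n}) + \sigma_P) - \delta_P P}
#' \deqn{dF/dt = \rho_F P^* - k_{on} F T + k_{off} C - \delta_F F}
#' \deqn{dT/dt = \rho_T P^* - k_{on} F T + k_{off} C - k_b T (R_{tot} - B)
#'   + k_u B - \delta_T T}
#' \deqn{dC/dt = k_{on} F T - k_{off} C - \delta_C C}
#' \deqn{dB/dt = k_b T (R_{tot} - B) - k_u B}
#'
#' Model variants: `"A"` freezes Pax6 (`dP/dt = 0`; Pax6 is a prescribed
#' regional pattern) and ignores Shh; `"B"` and `"C"` use the full Pax6
#' dynamics with no Shh input (`h = 1`); `"D"` couples the full system to
#' a static Shh field. Variant `"C"` is variant `"B"` run on an
#' explant-shaped 2D domain; the kinetics are identical.
#'
#' @param state an `ov_state`.
#' @param params an `ov_params`.
#' @param shh an `ov_shh` or `NULL`. Required for variant `"D"`.
#' @param variant one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A named list of rate fields (`P`, `F`, `T`, `C`, `B`) with the
#'   shape of the state fields.
#' @export
reaction_rates <- function(state, params, shh = NULL,
                           variant = c("B", "A", "C", "D")) {
  stopifnot(inherits(state, "ov_state"), inherits(params, "ov_params"))
  variant <- match.arg(variant)
  p <- params
  P <- state$P; F <- state$F; T <- state$T; C <- state$C; B <- state$B
  S <- 0
  if (variant == "D") {
    if (is.null(shh)) stop("variant D requires an Shh field")
    S <- shh$S
    if (!identical(dim(S) %||% length(S), dim(P) %||% length(P)))
      stop("Shh field shape does not match the state")
  }
  a <- pax6_activity(P, B, p$beta)
  h <- 1 / (1 + p$gamma * S)
  hill <- p$rho_P * a^p$n_hill / (p$K_hill^p$n_hill + a^p$n_hill)
  seq_net <- p$k_on * F * T - p$k_off * C
  rec_net <- p$k_b * T * (p$R_tot - B) - p$k_u * B
  dP <- if (variant == "A") P * 0 else h * (hill + p$sigma_P) - p$delta_P * P
  list(P = dP,
       F = p$rho_F * a - seq_net - p$delta_F * F,
       T = p$rho_T * a - seq_net - rec_net - p$delta_T * T,
       C = seq_net - p$delta_C * C,
       B = rec_net)
}

state_from_scalars <- function(v, geometry = NULL) {
  shape_one <- function(x) {
    if (is.null(geometry)) return(x)
    if (inherits(geometry, "ov_grid")) return(rep(x, geometry$n_points))
    if (inherits(geometry, "ov_mask"))
      return(matrix(x, nrow(geometry$mask), ncol(geometry$mask)))
    stop("unknown geometry")
  }
  field_state(shape_one(v[["P"]]), shape_one(v[["F"]]), shape_one(v[["T"]]),
              shape_one(v[["C"]]), shape_one(v[["B"]]))
}

#' Spatially uniform steady state of the reaction kinetics
#'
#' Solves the reaction system (no diffusion) for a uniform steady state,
#' returning the Pax6-positive branch when it exists. The solver reduces
#' the problem to a damped fixed-point iteration on the effective Pax6
#' activity: given an activity `a`, free Tgfb2 follows from a bracketed
#' root solve, receptor occupancy from the binding isotherm
#' `B* = R_tot k_b T* / (k_b T* + k_u)`, and the Pax6 balance returns an
#' updated activity.
#'
#' @param params an `ov_params`.
#' @param variant model variant tag (kinetics are shared; retained for
#'   interface symmetry with [reaction_rates()]).
#' @param shh_level uniform Shh activity entering the Pax6 attenuation
#'   (0 for variants A--C).
#' @param tol residual tolerance on the reaction rates.
#' @return Named numeric vector `c(P, F, T, C, B)` with attribute
#'   `"residual"`, the max-norm of the reaction rates.
#' @export
homogeneous_steady_state <- function(params, variant = "B", shh_level = 0,
                                     tol = 1e-10) {
  stopifnot(inherits(params, "ov_params"))
  p <- params
  h <- 1 / (1 + p$gamma * shh_level)
  q <- if (p$k_off + p$delta_C > 0) p$delta_C / (p$k_off + p$delta_C) else 0
  solve_FT <- function(a) {
    if (a <= 0 || p$rho_T * a == 0) {
      Fv <- if (p$delta_F > 0) p$rho_F * a / p$delta_F else 0
      return(c(F = Fv, T = 0))
    }
    Thi <- p$rho_T * a / p$delta_T + 1e-12
    g <- function(Tv) {
      Fv <- p$rho_F * a / (p$delta_F + p$k_on * q * Tv)
      p$rho_T * a - p$k_on * q * Fv * Tv - p$delta_T * Tv
    }
    Tv <- stats::uniroot(g, c(0, Thi), tol = 1e-15)$root
    Fv <- p$rho_F * a / (p$delta_F + p$k_on * q * Tv)
    c(F = Fv, T = Tv)
  }
  a <- h * (p$rho_P + p$sigma_P) / max(p$delta_P, 1e-12)
  Pv <- a; FT <- solve_FT(a); Bv <- 0
  for (i in seq_len(2000)) {
    FT <- solve_FT(a)
    Tv <- FT[["T"]]
    Bv <- p$R_tot * p$k_b * Tv / (p$k_b * Tv + p$k_u + (p$k_b * Tv + p$k_u == 0))
    hillprod <- p$rho_P * a^p$n_hill / (p$K_hill^p$n_hill + a^p$n_hill)
    Pv <- h * (hillprod + p$sigma_P) / max(p$delta_P, 1e-12)
    a_new <- Pv / (1 + p$beta * Bv)
    if (abs(a_new - a) < 1e-14 * (1 + abs(a))) { a <- a_new; break }
    a <- a + 0.6 * (a_new - a)
  }
  FT <- solve_FT(a)
  Tv <- FT[["T"]]; Fv <- FT[["F"]]
  Bv <- p$R_tot * p$k_b * Tv / (p$k_b * Tv + p$k_u + (p$k_b * Tv + p$k_u == 0))
  Cv <- if (p$k_off + p$delta_C > 0) p$k_on * Fv * Tv / (p$k_off + p$delta_C) else 0
  hillprod <- p$rho_P * a^p$n_hill / (p$K_hill^p$n_hill + a^p$n_hill)
  Pv <- h * (hillprod + p$sigma_P) / max(p$delta_P, 1e-12)
  s <- c(P = Pv, F = Fv, T = Tv, C = Cv, B = unname(Bv))
  shh <- if (shh_level > 0) shh_field(shh_level) else NULL
  res <- max(abs(unlist(reaction_rates(state_from_scalars(s), params,
                                       shh = shh,
                                       variant = if (shh_level > 0) "D" else "B"))))
  if (!is.finite(res) || res > tol * max(1, max(abs(s))) * 100 && res > 1e-8)
    stop("steady-state solver did not converge (residual ", format(res), ")")
  attr(s, "residual") <- res
  s
}
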