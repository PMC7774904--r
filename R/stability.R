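#' Jacobian of the reaction kinetics at a uniform state
#'
#' Analytic linearisation of the reaction part (no diffusion) of the
#' model about a spatially uniform state, ordered (P, F, T, C, B).
#' Entry (i, j) is the derivative of species i's rate with respect to
#' species j's concentration.
#'
#' @param params an `ov_params`.
#' @param steady_state named numeric vector `c(P, F, T, C, B)`; its
#'   reaction residual must be below `resid_tol`.
#' @param variant model variant; variant `"A"` zeroes the Pax6 row.
#' @param shh_level uniform Shh activity (variant `"D"`).
#' @param resid_tol maximum admissible reaction residual.
#' @return 5 x 5 numeric matrix.
#' @export
reaction_jacobian <- function(params, steady_state, variant = "B",
                              shh_level = 0, resid_tol = 1e-8) {
  stopifnot(inherits(params, "ov_params"))
  p <- params
  s <- steady_state
  shh <- if (shh_level > 0) shh_field(shh_level) else NULL
  use_variant <- if (shh_level > 0) "D" else variant
  if (use_variant == "A" && variant == "A") use_variant <- "A"
  res <- max(abs(unlist(reaction_rates(state_from_scalars(s), params,
                                       shh = shh, variant = use_variant))))
  if (res > resid_tol)
    stop("state is not a steady state (residual ", format(res), ")")
  P <- s[["P"]]; Fv <- s[["F"]]; Tv <- s[["T"]]; Cv <- s[["C"]]; B <- s[["B"]]
  h <- 1 / (1 + p$gamma * shh_level)
  w <- 1 / (1 + p$beta * B)
  a <- P * w
  n <- p$n_hill; K <- p$K_hill
  hill_slope <- if (a <= 0 && n > 1) 0 else
    p$rho_P * n * a^(n - 1) * K^n / (K^n + a^n)^2
  da_dP <- w
  da_dB <- -p$beta * P * w^2
  J <- matrix(0, 5, 5,
              dimnames = list(species_names(), species_names()))
  if (variant != "A") {
    J["P", "P"] <- h * hill_slope * da_dP - p$delta_P
    J["P", "B"] <- h * hill_slope * da_dB
  }
  J["F", "P"] <- p$rho_F * da_dP
  J["F", "F"] <- -p$k_on * Tv - p$delta_F
  J["F", "T"] <- -p$k_on * Fv
  J["F", "C"] <- p$k_off
  J["F", "B"] <- p$rho_F * da_dB
  J["T", "P"] <- p$rho_T * da_dP
  J["T", "F"] <- -p$k_on * Tv
  J["T", "T"] <- -p$k_on * Fv - p$k_b * (p$R_tot - B) - p$delta_T
  J["T", "C"] <- p$k_off
  J["T", "B"] <- p$rho_T * da_dB + p$k_b * Tv + p$k_u
  J["C", "F"] <- p$k_on * Tv
  J["C", "T"] <- p$k_on * Fv
  J["C", "C"] <- -p$k_off - p$delta_C
  J["B", "T"] <- p$k_b * (p$R_tot - B)
  J["B", "B"] <- -p$k_b * Tv - p$k_u
  J
}

#' Dispersion relation and Turing classification
#'
#' For each wavenumber `k` the growth rate is the largest real part of
#' the eigenvalues of `J - k^2 diag(0, D_F, D_T, D_C, 0)` (Pax6 and the
#' receptor complex do not diffuse). Classification, with a numerical
#' dead-band of `1e-9` around zero:
#' \itemize{
#'   \item `stable`: growth rate below the dead-band for all sampled `k`;
#'   \item `turing`: stable at `k = 0`, unstable at finite `k` with a
#'     real leading eigenvalue at the fastest-growing wavenumber;
#'   \item `oscillatory_turing`: as `turing` but the unstable mode at
#'     `k_max` has a nonzero imaginary part (a wave instability);
#'   \item `hopf`: unstable at `k = 0` with nonzero frequency.
#' }
#'
#' @param params an `ov_params`.
#' @param steady_state uniform state; computed with
#'   [homogeneous_steady_state()] when `NULL`.
#' @param k_values sampled wavenumbers (sorted, >= 0). Default: 0 plus a
#'   log-spaced grid from `2 pi / (10 L)` to `2 pi / (2 dx)` for
#'   `L = 600, dx = 1` in model length units, which brackets all
#'   resolvable modes of the shipped scenarios.
#' @param variant model variant.
#' @param shh_level uniform Shh activity.
#' @return An object of class `ov_dispersion`: list with `k_values`,
#'   `growth_rates`, `frequencies` (|Im| of the leading eigenvalue),
#'   `classification`, `k_max`, `lambda_pattern`, `growth_at_kmax`.
#' @export
dispersion_relation <- function(params, steady_state = NULL, k_values = NULL,
                                variant = "B", shh_level = 0) {
  stopifnot(inherits(params, "ov_params"))
  if (is.null(steady_state))
    steady_state <- homogeneous_steady_state(params, variant = variant,
                                             shh_level = shh_level)
  if (is.null(k_values))
    k_values <- c(0, exp(seq(log(2 * pi / 6000), log(pi), length.out = 240)))
  if (is.unsorted(k_values) || any(k_values < 0))
    stop("k_values must be sorted and non-negative")
  J <- reaction_jacobian(params, steady_state, variant = variant,
                         shh_level = shh_level)
  Ddiag <- c(0, params$D_F, params$D_T, params$D_C, 0)
  lead <- vapply(k_values, function(k) {
    ev <- eigen(J - k^2 * diag(Ddiag), only.values = TRUE)$values
    if (any(!is.finite(ev))) stop("non-finite eigenvalues at k = ", k)
    i <- which.max(Re(ev))
    c(Re(ev[i]), abs(Im(ev[i])))
  }, numeric(2))
  growth <- lead[1, ]
  freq <- lead[2, ]
  tol <- 1e-9
  ev0 <- eigen(J, only.values = TRUE)$values
  i0 <- which.max(Re(ev0))
  re0 <- Re(ev0[i0]); im0 <- abs(Im(ev0[i0]))
  imax <- which.max(growth)
  classification <-
    if (re0 > tol) {
      if (im0 > tol) "hopf" else "unstable"
    } else if (growth[imax] <= tol) {
      "stable"
    } else if (freq[imax] > tol) {
      "oscillatory_turing"
    } else {
      "turing"
    }
  k_max <- if (classification %in% c("turing", "oscillatory_turing"))
    k_values[imax] else NA_real_
  structure(list(k_values = k_values, growth_rates = growth,
                 frequencies = freq, classification = classification,
                 k_max = k_max,
                 lambda_pattern = if (is.na(k_max) || k_max == 0) NA_real_
                                  else 2 * pi / k_max,
                 growth_at_kmax = growth[imax],
                 freq_at_kmax = freq[imax],
                 growth_at_zero = re0, freq_at_zero = im0),
            class = "ov_dispersion")
}

#' @export
print.ov_dispersion <- function(x, ...) {
  cat(sprintf("dispersion: %s", x$classification))
  if (!is.na(x$k_max))
    cat(sprintf(" | k_max = %.4g, lambda = %.4g, growth = %.4g, |Im| = %.4g",
                x$k_max, x$lambda_pattern, x$growth_at_kmax, x$freq_at_kmax))
  cat("\n")
  invisible(x)
}

#' Predicted number of expression poles for a domain size
#'
#' Mode selection in a confined domain is approximate: the expected
#' pole count is the rounded number of pattern wavelengths fitting in
#' the domain, returned as an inclusive `+/- 1` range. Under zero-flux
#' boundaries the stationary modes are half-wavelength cosines, and a
#' half-pole at a boundary reads out as a full pole, so boundary modes
#' are covered by the same count.
#'
#' @param domain_length domain length `L`.
#' @param dispersion an `ov_dispersion` with a Turing-type
#'   classification.
#' @param boundary boundary condition tag (recorded; the range is the
#'   same for both).
#' @return Integer vector `c(lo, hi)`, with `lo >= 0`.
#' @export
predicted_pole_count <- function(domain_length, dispersion,
                                 boundary = c("zero_flux", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(dispersion, "ov_dispersion"))
  if (!dispersion$classification %in% c("turing", "oscillatory_turing"))
    stop("pole count prediction requires a Turing-type classification, got '",
         dispersion$classification, "'")
  m <- round(domain_length / dispersion$lambda_pattern)
  c(max(0L, m - 1L), m + 1L)
}

#' Measure the growth rate of a single spatial mode by simulation
#'
#' Perturbs the uniform steady state with a small single-mode pattern of
#' wavenumber `k` (a cosine on a periodic 1D grid holding an integer
#' number of wavelengths), integrates while the perturbation stays in
#' the linear regime, and fits the growth rate of the mode amplitude.
#' The amplitude is extracted by projecting the per-species cosine
#' coefficients onto the invariant subspace of the leading eigenpair of
#' `J - k^2 D`, so oscillatory (complex) modes yield a clean exponential
#' envelope.
#'
#' @param params an `ov_params`.
#' @param k target wavenumber; realised as the nearest wavenumber
#'   `2 pi m / L` on the chosen grid.
#' @param amplitude initial relative perturbation of Pax6 (default
#'   1e-4 of steady state).
#' @param amp_limit stop once the Pax6 deviation exceeds this fraction
#'   of steady state (default 0.01; the linear-regime guard).
#' @param n_periods number of pattern wavelengths on the grid.
#' @param points_per_wavelength spatial resolution.
#' @param t_span integration horizon in units of `1/|growth rate|`
#'   (default 4).
#' @param variant model variant.
#' @return List with `rate` (fitted exponential growth rate of the
#'   mode), `predicted` (growth rate from the dispersion relation at the
#'   realised `k`), `k` (realised wavenumber), `n_snapshots`.
#' @export
measure_mode_growth <- function(params, k, amplitude = 1e-4,
                                amp_limit = 0.01, n_periods = 1L,
                                points_per_wavelength = 16L,
                                t_span = 4, variant = "B") {
  ss <- homogeneous_steady_state(params, variant = variant)
  lam <- 2 * pi / k
  n <- as.integer(n_periods * points_per_wavelength)
  dx <- n_periods * lam / n
  g <- grid_1d(n, dx, "periodic")
  k_real <- 2 * pi * n_periods / g$length
  J <- reaction_jacobian(params, ss, variant = variant)
  Ddiag <- c(0, params$D_F, params$D_T, params$D_C, 0)
  M <- J - k_real^2 * diag(Ddiag)
  eg <- eigen(M)
  ilead <- which.max(Re(eg$values))
  lambda <- eg$values[ilead]
  # left eigenvector for the projection
  egL <- eigen(t(M))
  jlead <- which.min(abs(egL$values - Conj(lambda)))
  wvec <- Conj(egL$vectors[, jlead])
  cosx <- cos(k_real * g$x)
  st <- state_from_scalars(ss, g)
  st$P <- st$P + amplitude * ss[["P"]] * cosx
  rate_guess <- abs(Re(lambda))
  t_end <- t_span / max(rate_guess, 1e-6)
  settings <- solver_settings(t_end = t_end, snapshot_interval = t_end / 60,
                              rtol = 1e-10, atol = 1e-12)
  res <- integrate_model(params, st, g, variant = variant,
                         settings = settings)
  # complex mode amplitude at each snapshot
  amps <- vapply(res$snapshots, function(s) {
    u <- vapply(species_names(), function(nm)
      2 * mean((s[[nm]] - ss[[nm]]) * cosx), numeric(1))
    Mod(sum(wvec * u))
  }, numeric(1))
  # linear-regime guard on Pax6 deviation
  relP <- vapply(res$snapshots, function(s)
    max(abs(s$P - ss[["P"]])) / ss[["P"]], numeric(1))
  keep <- which(relP <= amp_limit & amps > 0)
  keep <- keep[keep > 1L]
  if (length(keep) < 5L) stop("too few linear-regime snapshots")
  fit <- stats::lm(log(amps[keep]) ~ res$times[keep])
  list(rate = unname(stats::coef(fit)[2]), predicted = Re(lambda),
       k = k_real, n_snapshots = length(keep))
}
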