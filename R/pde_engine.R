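#' Discrete Laplacian on a 1D grid
#'
#' Second-order central difference on a cell-centred grid. Zero-flux
#' boundaries use ghost-cell reflection (the ghost value equals the
#' boundary cell), making the flux across each domain face exactly zero
#' and the operator mass-conserving; periodic boundaries wrap.
#'
#' @param field numeric vector (length >= 3).
#' @param dx grid spacing.
#' @param boundary `"zero_flux"` or `"periodic"`.
#' @return The discrete Laplacian of `field`.
#' @export
laplacian_1d <- function(field, dx, boundary = c("zero_flux", "periodic")) {
  boundary <- match.arg(boundary)
  n <- length(field)
  if (n < 3L) stop("field must have at least 3 points")
  if (boundary == "periodic") {
    fp <- c(field[-1L], field[1L])
    fm <- c(field[n], field[-n])
  } else {
    fp <- c(field[-1L], field[n])
    fm <- c(field[1L], field[-n])
  }
  (fp + fm - 2 * field) / dx^2
}

#' Discrete Laplacian on a masked 2D domain
#'
#' Five-point stencil restricted to the mask. A neighbour lying outside
#' the mask is mirrored (ghost reflection: it takes the centre value),
#' so the normal flux across the mask edge is exactly zero; the output
#' is zero outside the mask. The operator is symmetric, hence total mass
#' is conserved under pure diffusion.
#'
#' @param field numeric matrix on the mask's bounding box.
#' @param dx grid spacing.
#' @param mask an `ov_mask` or a logical matrix.
#' @return Matrix of the same shape; zero outside the mask.
#' @export
laplacian_2d_masked <- function(field, dx, mask) {
  m <- if (inherits(mask, "ov_mask")) mask$mask else mask
  if (!identical(dim(field), dim(m)))
    stop("field must match the mask bounding box")
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(f, di, dj) {
    out <- matrix(0, nr, nc)
    si <- seq_len(nr) + di; sj <- seq_len(nc) + dj
    keep_i <- si >= 1L & si <= nr; keep_j <- sj >= 1L & sj <= nc
    out[keep_i, keep_j] <- f[si[keep_i], sj[keep_j]]
    out
  }
  acc <- matrix(0, nr, nc)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb_in <- shift(m, d[1], d[2])          # 1 where the neighbour is tissue
    nb_val <- shift(field, d[1], d[2])
    acc <- acc + nb_in * (nb_val - field)
  }
  out <- acc / dx^2
  out[!m] <- 0
  out
}

#' Time-integration settings
#'
#' @param t_end final time.
#' @param snapshot_interval spacing of stored snapshots (time units).
#' @param integrator `"lsoda"` (adaptive, stiff-capable; the default) or
#'   `"euler"` (fixed-step explicit Euler). The explicit integrator
#'   enforces the diffusive stability bound `dt <= dx^2 / (4 max D)`.
#' @param dt explicit-Euler time step (ignored by `"lsoda"` except to
#'   seed the adaptive stepper's initial step).
#' @param rtol,atol relative/absolute tolerances for `"lsoda"`.
#' @param seed integer RNG seed recorded with the run (the integrator
#'   itself is deterministic; the seed documents the scenario noise).
#' @return An object of class `ov_settings`.
#' @export
solver_settings <- function(t_end, snapshot_interval = t_end / 100,
                            integrator = c("lsoda", "euler"),
                            dt = NULL, rtol = 1e-6, atol = 1e-8,
                            seed = NA_integer_) {
  integrator <- match.arg(integrator)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (snapshot_interval <= 0 || snapshot_interval > t_end)
    stop("snapshot_interval must lie in (0, t_end]")
  if (integrator == "euler" && is.null(dt))
    stop("explicit Euler requires dt")
  structure(list(t_end = t_end, snapshot_interval = snapshot_interval,
                 integrator = integrator, dt = dt, rtol = rtol, atol = atol,
                 seed = seed),
            class = "ov_settings")
}

#' Integrate the reaction-diffusion model
#'
#' Method-of-lines integration of the five-species system on a 1D grid
#' or a masked 2D domain. Pax6 (`P`) and the receptor complex (`B`) do
#' not diffuse; free Fst, free Tgfb2 and the Fst:Tgfb2 complex diffuse
#' with `D_F`, `D_T`, `D_C`. The default integrator is the adaptive
#' stiff-capable `lsoda` family (via \pkg{deSolve}, `ode.1D`/`ode.2D`);
#' a fixed-step explicit Euler loop is available for auditing and
#' convergence checks and refuses to run if `dt` violates the diffusive
#' stability bound.
#'
#' Fields are clamped to zero if an excursion below `-1e-9` ... `0`
#' occurs (counted in the result's `clamped` field; the reference
#' parameter set never triggers clamping).
#'
#' @param params an `ov_params`.
#' @param initial an `ov_state` matching the geometry.
#' @param geometry an `ov_grid` or `ov_mask`.
#' @param shh an `ov_shh` or `NULL` (required for variant `"D"`).
#' @param variant model variant (`"A"`--`"D"`); see [reaction_rates()].
#' @param settings an `ov_settings`.
#' @return An object of class `ov_result`: list with `times`, `snapshots`
#'   (list of `ov_state`), `params`, `geometry`, `shh`, `variant`,
#'   `settings`, `clamped`.
#' @export
integrate_model <- function(params, initial, geometry, shh = NULL,
                            variant = c("B", "A", "C", "D"),
                            settings) {
  stopifnot(inherits(params, "ov_params"), inherits(initial, "ov_state"),
            inherits(settings, "ov_settings"))
  variant <- match.arg(variant)
  is1d <- inherits(geometry, "ov_grid")
  if (!is1d && !inherits(geometry, "ov_mask")) stop("unknown geometry")
  if (variant == "D" && is.null(shh)) stop("variant D requires an Shh field")

  dx <- geometry$dx
  npt <- if (is1d) geometry$n_points else length(geometry$mask)
  dims <- if (is1d) NULL else dim(geometry$mask)
  for (nm in species_names())
    if (!identical(dim(initial[[nm]]) %||% length(initial[[nm]]),
                   dims %||% npt))
      stop("initial state does not match the geometry")

  D <- c(P = 0, F = params$D_F, T = params$D_T, C = params$D_C, B = 0)
  lap <- if (is1d) {
    bnd <- geometry$boundary
    function(f) laplacian_1d(f, dx, bnd)
  } else {
    msk <- geometry$mask
    function(f) laplacian_2d_masked(f, dx, msk)
  }

  pack <- function(state) unlist(lapply(species_names(), function(nm) state[[nm]]),
                                 use.names = FALSE)
  unpack <- function(y) {
    out <- vector("list", 5L); names(out) <- species_names()
    for (i in seq_len(5L)) {
      f <- unname(y[((i - 1L) * npt + 1L):(i * npt)])
      if (!is1d) dim(f) <- dims
      out[[i]] <- f
    }
    structure(out, class = "ov_state")
  }
  deriv <- function(state) {
    r <- reaction_rates(state, params, shh = shh, variant = variant)
    for (nm in c("F", "T", "C"))
      if (D[[nm]] > 0) r[[nm]] <- r[[nm]] + D[[nm]] * lap(state[[nm]])
    r
  }

  # flat-vector right-hand side for the adaptive solver: same kinetics
  # as reaction_rates() (pinned together by the integrator tests),
  # written without per-call list/class construction
  pp <- params
  S_flat <- if (variant == "D") as.numeric(shh$S) else 0
  h_flat <- 1 / (1 + pp$gamma * S_flat)
  i1 <- seq_len(npt); i2 <- i1 + npt; i3 <- i2 + npt; i4 <- i3 + npt
  i5 <- i4 + npt
  lap_flat <- if (is1d) {
    if (geometry$boundary == "periodic") {
      ip <- c(2:npt, 1L); im <- c(npt, 1:(npt - 1L)); idx2 <- dx^2
      function(f) (f[ip] + f[im] - 2 * f) / idx2
    } else {
      ip <- c(2:npt, npt); im <- c(1L, 1:(npt - 1L)); idx2 <- dx^2
      function(f) (f[ip] + f[im] - 2 * f) / idx2
    }
  } else {
    msk <- geometry$mask
    function(f) { dim(f) <- dims; as.numeric(laplacian_2d_masked(f, dx, msk)) }
  }
  rhs_flat <- function(t, y, parms) {
    P <- y[i1]; Fv <- y[i2]; Tv <- y[i3]; Cv <- y[i4]; B <- y[i5]
    a <- P / (1 + pp$beta * B)
    hill <- pp$rho_P * a^pp$n_hill / (pp$K_hill^pp$n_hill + a^pp$n_hill)
    seq_net <- pp$k_on * Fv * Tv - pp$k_off * Cv
    rec_net <- pp$k_b * Tv * (pp$R_tot - B) - pp$k_u * B
    dP <- if (variant == "A") 0 * P
          else h_flat * (hill + pp$sigma_P) - pp$delta_P * P
    dF <- pp$rho_F * a - seq_net - pp$delta_F * Fv
    dT <- pp$rho_T * a - seq_net - rec_net - pp$delta_T * Tv
    dC <- seq_net - pp$delta_C * Cv
    dB <- rec_net
    if (pp$D_F > 0) dF <- dF + pp$D_F * lap_flat(Fv)
    if (pp$D_T > 0) dT <- dT + pp$D_T * lap_flat(Tv)
    if (pp$D_C > 0) dC <- dC + pp$D_C * lap_flat(Cv)
    list(c(dP, dF, dT, dC, dB))
  }

  times <- seq(0, settings$t_end, by = settings$snapshot_interval)
  if (times[length(times)] < settings$t_end)
    times <- c(times, settings$t_end)

  clamped <- 0L
  clamp <- function(state) {
    for (nm in species_names()) {
      f <- state[[nm]]
      neg <- f < 0
      if (any(neg)) {
        if (any(f < -1e-9))
          stop("field '", nm, "' fell below -1e-9; integration unstable")
        clamped <<- clamped + sum(neg)
        f[neg] <- 0
        state[[nm]] <- f
      }
    }
    state
  }

  if (settings$integrator == "euler") {
    dtmax_diff <- dx^2 / (4 * max(D))
    if (settings$dt > dtmax_diff)
      stop("dt violates the diffusive stability bound dx^2/(4 max D) = ",
           format(dtmax_diff))
    state <- initial
    snapshots <- vector("list", length(times))
    snapshots[[1L]] <- state
    t <- 0; isnap <- 2L
    dt <- settings$dt
    while (isnap <= length(times)) {
      t_target <- times[isnap]
      nstep <- ceiling((t_target - t) / dt - 1e-12)
      dt_loc <- (t_target - t) / nstep
      for (k in seq_len(nstep)) {
        r <- deriv(state)
        for (nm in species_names())
          state[[nm]] <- state[[nm]] + dt_loc * r[[nm]]
        state <- clamp(state)
      }
      t <- t_target
      if (any(!vapply(state, function(f) all(is.finite(f)), TRUE)))
        stop("non-finite field values at t = ", t)
      snapshots[[isnap]] <- state
      isnap <- isnap + 1L
    }
  } else {
    y0 <- pack(initial)
    # sparse BDF with numerically estimated Jacobian structure: handles
    # the periodic wrap-around and the masked-domain stencil alike
    sol <- deSolve::lsodes(y0, times, rhs_flat, parms = NULL,
                           sparsetype = "sparseint",
                           rtol = settings$rtol, atol = settings$atol,
                           lrw = 250L * length(y0) + 20000L,
                           maxsteps = 100000)
    if (nrow(sol) < length(times) ||
        any(!is.finite(sol[nrow(sol), -1L])))
      stop("integration failed at t = ", sol[nrow(sol), 1L],
           " (non-finite values or solver abort)")
    snapshots <- lapply(seq_len(nrow(sol)), function(i)
      clamp(unpack(sol[i, -1L])))
  }

  structure(list(times = times, snapshots = snapshots, params = params,
                 geometry = geometry, shh = shh, variant = variant,
                 settings = settings, clamped = clamped,
                 version = as.character(utils::packageVersion("turingov"))),
            class = "ov_result")
}

#' @export
print.ov_result <- function(x, ...) {
  cat(sprintf("simulation result: variant %s, %d snapshots, t in [0, %g]%s\n",
              x$variant, length(x$snapshots), max(x$times),
              if (x$clamped > 0) sprintf(" (%d clamped values)", x$clamped) else ""))
  invisible(x)
}

#' Final state of a simulation result
#'
#' @param result an `ov_result`.
#' @return The last snapshot (`ov_state`).
#' @export
final_state <- function(result) {
  stopifnot(inherits(result, "ov_result"))
  result$snapshots[[length(result$snapshots)]]
}
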