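#' Count expression poles in a concentration field
#'
#' Thresholds the field at `min + threshold_frac (max - min)` over the
#' domain and counts connected supra-threshold components (runs in 1D,
#' 4-connected components in 2D by default). A no-contrast dead-band
#' separates numerical ripple from pattern: if the relative range
#' `(max - min) / max` is below `contrast_min` the count is zero.
#' Components touching the domain edge count as full poles (half a pole
#' at a boundary, i.e. a gradient, is a meaningful outcome). On periodic
#' 1D grids, runs touching both ends are merged.
#'
#' @param field non-negative numeric vector (1D) or matrix (2D).
#' @param geometry an `ov_grid` or `ov_mask`.
#' @param threshold_frac threshold position within the field range,
#'   in (0, 1).
#' @param connectivity 4 or 8 (2D only).
#' @param contrast_min the no-contrast dead-band (default 0.05).
#' @return A list with `count` (integer) and `centroids`
#'   (intensity-weighted component centroids; matrix with columns x, y
#'   in length units, or a vector of x positions in 1D).
#' @export
count_poles <- function(field, geometry, threshold_frac = 0.5,
                        connectivity = 4L, contrast_min = 0.05) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)")
  if (any(field < 0, na.rm = TRUE)) stop("field must be non-negative")
  if (inherits(geometry, "ov_grid")) {
    vals <- field
    lo <- min(vals); hi <- max(vals)
    if (hi <= 0 || (hi - lo) / hi < contrast_min)
      return(list(count = 0L, centroids = numeric(0)))
    thr <- lo + threshold_frac * (hi - lo)
    above <- vals > thr
    r <- rle(above)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    comp <- which(r$values)
    segs <- lapply(comp, function(j) idx_start[j]:idx_end[j])
    if (geometry$boundary == "periodic" && length(segs) > 1L &&
        above[1L] && above[length(above)]) {
      segs[[1L]] <- c(segs[[length(segs)]], segs[[1L]])
      segs[[length(segs)]] <- NULL
    }
    centroids <- vapply(segs, function(ix) {
      stats::weighted.mean(geometry$x[ix], vals[ix])
    }, numeric(1))
    return(list(count = length(segs), centroids = centroids))
  }
  if (!inherits(geometry, "ov_mask")) stop("unknown geometry")
  m <- geometry$mask
  if (!any(m)) stop("empty mask")
  vals <- field[m]
  lo <- min(vals); hi <- max(vals)
  if (hi <= 0 || (hi - lo) / hi < contrast_min)
    return(list(count = 0L, centroids = matrix(numeric(0), 0, 2)))
  thr <- lo + threshold_frac * (hi - lo)
  above <- (field > thr) & m
  lab <- label_components(above, connectivity = as.integer(connectivity))
  ncomp <- max(lab)
  if (ncomp == 0L) return(list(count = 0L, centroids = matrix(numeric(0), 0, 2)))
  cx <- cy <- numeric(ncomp)
  for (j in seq_len(ncomp)) {
    sel <- lab == j
    w <- field[sel]
    cx[j] <- sum(geometry$xc[sel] * w) / sum(w)
    cy[j] <- sum(geometry$yc[sel] * w) / sum(w)
  }
  list(count = ncomp, centroids = cbind(x = cx, y = cy))
}

#' Polarisation index and angle of a field
#'
#' The polarisation index is the normalised offset of the
#' intensity-weighted centroid from the unweighted domain centroid:
#' `|r_cm - r_geo| / R_max`, with `R_max` the largest distance from the
#' domain centroid to any domain point (in 1D, `L / 2`). The angle is
#' the direction of the offset, in degrees from the +x axis. A uniform
#' field has index 0 and undefined (`NA`) angle.
#'
#' On a periodic 1D grid the linear centroid is not translation
#' invariant (a pole wrapping the domain boundary would read as
#' unpolarised), so the index is the magnitude of the first circular
#' moment of the intensity, `|sum w exp(2 pi i x / L)| / sum w`, and the
#' angle is the circular position of the intensity centroid in degrees
#' around the ring.
#'
#' @param field non-negative field with nonzero total mass.
#' @param geometry an `ov_grid` or `ov_mask`.
#' @return List with `index` in \[0, 1\] and `angle` (degrees; `NA` if
#'   the offset is numerically zero).
#' @export
polarisation_index <- function(field, geometry) {
  if (any(field < 0, na.rm = TRUE)) stop("field must be non-negative")
  if (inherits(geometry, "ov_grid")) {
    w <- field
    if (sum(w) <= 0) stop("field has zero mass")
    if (geometry$boundary == "periodic") {
      z <- sum(w * exp(2i * pi * geometry$x / geometry$length)) / sum(w)
      idx <- Mod(z)
      ang <- if (idx < 1e-12) NA_real_ else (Arg(z) * 180 / pi) %% 360
      return(list(index = min(idx, 1), angle = ang))
    }
    r_cm <- sum(geometry$x * w) / sum(w)
    r_geo <- mean(geometry$x)
    off <- r_cm - r_geo
    idx <- abs(off) / (geometry$length / 2)
    ang <- if (abs(off) < 1e-12 * geometry$length) NA_real_
           else if (off > 0) 0 else 180
    return(list(index = min(idx, 1), angle = ang))
  }
  stopifnot(inherits(geometry, "ov_mask"))
  m <- geometry$mask
  w <- field[m]
  if (sum(w) <= 0) stop("field has zero mass")
  x <- geometry$xc[m]; y <- geometry$yc[m]
  r_cm <- c(sum(x * w), sum(y * w)) / sum(w)
  r_geo <- c(mean(x), mean(y))
  off <- r_cm - r_geo
  R_max <- sqrt(max((x - r_geo[1])^2 + (y - r_geo[2])^2))
  idx <- sqrt(sum(off^2)) / R_max
  ang <- if (sqrt(sum(off^2)) < 1e-12 * R_max) NA_real_
         else atan2(off[2], off[1]) * 180 / pi
  list(index = min(idx, 1), angle = ang)
}

#' Pearson correlation between two fields over the domain
#'
#' The phase relation between the Pax6 pattern and the activated
#' receptor pattern: strongly negative values mean out-of-phase (a Pax6
#' pole flanked by receptor-signalling poles).
#'
#' @param field_a,field_b fields of identical shape.
#' @param geometry an `ov_grid` or `ov_mask`.
#' @return Pearson correlation over in-domain points.
#' @export
phase_correlation <- function(field_a, field_b, geometry) {
  if (inherits(geometry, "ov_mask")) {
    a <- field_a[geometry$mask]; b <- field_b[geometry$mask]
  } else {
    a <- field_a; b <- field_b
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("phase correlation undefined: a field has zero variance")
  stats::cor(a, b)
}

#' Field profile along the long axis of a masked domain
#'
#' Averages the field across the short axis in bins of width `dx` along
#' the long (principal) axis — the 1D readout used to compare explant
#' simulations with profile plots.
#'
#' @param field numeric matrix on the mask bounding box.
#' @param mask an `ov_mask`.
#' @return A data frame with columns `s` (position along the long axis,
#'   bin centres) and `value` (mean field in the bin).
#' @export
axis_profile <- function(field, mask) {
  stopifnot(inherits(mask, "ov_mask"))
  pa <- principal_axes(mask, mask$dx)
  m <- mask$mask
  if (sum(m) < 4L) stop("mask too thin to bin")
  x <- mask$xc[m]; y <- mask$yc[m]
  s <- (x - pa$centroid[1]) * pa$v1[1] + (y - pa$centroid[2]) * pa$v1[2]
  vals <- field[m]
  nb <- ceiling(mask$long_axis / mask$dx)
  edges <- seq(min(s) - 1e-9, max(s) + 1e-9, length.out = nb + 1L)
  bin <- cut(s, edges, include.lowest = TRUE, labels = FALSE)
  data.frame(s = (edges[-1] + edges[-(nb + 1)]) / 2,
             value = as.numeric(tapply(vals, factor(bin, levels = seq_len(nb)),
                                       mean)))
}

#' Classify a simulation outcome
#'
#' `uniform` if no pole is detected, `polarised` for exactly one pole,
#' `multipolar` for two or more.
#'
#' @param pole_count integer >= 0.
#' @return One of `"uniform"`, `"polarised"`, `"multipolar"`.
#' @export
classify_outcome <- function(pole_count) {
  if (pole_count == 0) "uniform" else if (pole_count == 1) "polarised"
  else "multipolar"
}

#' Detect oscillation in a probe time series
#'
#' Flags a series as oscillating if, after detrending (subtracting a
#' centred moving average), it shows at least `min_extrema` alternating
#' local extrema whose prominence exceeds `prominence_frac` of the
#' series range. The period estimate is the mean peak-to-peak interval.
#'
#' @param times snapshot times (>= 20 values).
#' @param values probe values at those times.
#' @param min_extrema minimum number of alternating extrema (default 3).
#' @param prominence_frac prominence threshold as a fraction of the
#'   series range (default 0.05).
#' @param flat_tol a series whose relative range
#'   `diff(range) / max(|values|)` is below this is numerically constant
#'   and reported as not oscillating (guards against solver-tolerance
#'   ripple on a locked pattern).
#' @return List with `oscillating` (logical), `period` (`NA` when not
#'   oscillating), `n_extrema`.
#' @export
detect_oscillation <- function(times, values, min_extrema = 3L,
                               prominence_frac = 0.05, flat_tol = 1e-4) {
  n <- length(values)
  if (n < 20L) stop("need at least 20 snapshots")
  stopifnot(length(times) == n)
  if (diff(range(values)) <= flat_tol * max(abs(values), 1e-300))
    return(list(oscillating = FALSE, period = NA_real_, n_extrema = 0L))
  # detrend with a centred moving average (window ~ a fifth of the series)
  w <- max(5L, round(n / 5))
  if (w %% 2L == 0L) w <- w + 1L
  kern <- rep(1 / w, w)
  trend <- stats::filter(values, kern, sides = 2)
  pad <- which(is.na(trend))
  trend[pad] <- values[pad]
  det <- values - as.numeric(trend)
  rng <- diff(range(values))
  if (rng == 0) return(list(oscillating = FALSE, period = NA_real_,
                            n_extrema = 0L))
  # local extrema of the detrended series
  d <- diff(det)
  sgn <- sign(d)
  sgn[sgn == 0] <- 1
  turns <- which(diff(sgn) != 0) + 1L
  if (length(turns) < 2L)
    return(list(oscillating = FALSE, period = NA_real_, n_extrema = 0L))
  # prominence: half distance to neighbouring opposite extrema
  ext_vals <- det[turns]
  keep <- logical(length(turns))
  for (i in seq_along(turns)) {
    lo <- if (i > 1L) ext_vals[i - 1L] else det[1L]
    hi <- if (i < length(turns)) ext_vals[i + 1L] else det[n]
    keep[i] <- min(abs(ext_vals[i] - lo), abs(ext_vals[i] - hi)) >
      prominence_frac * rng
  }
  turns <- turns[keep]
  if (length(turns) < 2L)
    return(list(oscillating = FALSE, period = NA_real_, n_extrema = 0L))
  # alternating maxima/minima by construction of sign changes; after
  # prominence filtering, enforce alternation
  kinds <- det[turns] > 0
  alt <- c(TRUE, diff(kinds) != 0)
  turns <- turns[alt]
  n_ext <- length(turns)
  osc <- n_ext >= min_extrema
  per <- NA_real_
  peaks <- turns[det[turns] > 0]
  if (length(peaks) >= 2L) per <- mean(diff(times[peaks]))
  list(oscillating = osc, period = per, n_extrema = n_ext)
}

#' Summary metrics of a simulation result
#'
#' Computes the outcome metrics of one snapshot (default: the final
#' state): pole count and centroids, polarisation index and angle,
#' Pax6/receptor phase correlation, outcome class and mean Pax6.
#'
#' @param result an `ov_result`.
#' @param snapshot snapshot index (default: last).
#' @param threshold_frac,contrast_min passed to [count_poles()].
#' @return An object of class `ov_summary` (also a plain list).
#' @export
pattern_summary <- function(result, snapshot = length(result$snapshots),
                            threshold_frac = 0.5, contrast_min = 0.05) {
  stopifnot(inherits(result, "ov_result"))
  st <- result$snapshots[[snapshot]]
  g <- result$geometry
  poles <- count_poles(st$P, g, threshold_frac = threshold_frac,
                       contrast_min = contrast_min)
  pol <- polarisation_index(st$P, g)
  corr <- tryCatch(phase_correlation(st$P, st$B, g), error = function(e) NA_real_)
  meanP <- if (inherits(g, "ov_mask")) mean(st$P[g$mask]) else mean(st$P)
  structure(list(time = result$times[snapshot],
                 pole_count = poles$count,
                 pole_centroids = poles$centroids,
                 polarisation_index = pol$index,
                 polarisation_angle = pol$angle,
                 pax6_receptor_correlation = corr,
                 outcome_class = classify_outcome(poles$count),
                 mean_P = meanP),
            class = "ov_summary")
}

#' @export
print.ov_summary <- function(x, ...) {
  cat(sprintf(paste0("t = %g: %s (%d pole%s), polarisation %.3f",
                     " at %.1f deg, corr(P,B) = %.3f, mean P = %.4g\n"),
              x$time, x$outcome_class, x$pole_count,
              if (x$pole_count == 1) "" else "s",
              x$polarisation_index,
              if (is.na(x$polarisation_angle)) NaN else x$polarisation_angle,
              x$pax6_receptor_correlation, x$mean_P))
  invisible(x)
}

#' Per-snapshot metric time series of a result
#'
#' One row per snapshot: time, pole count, polarisation index and
#' angle, Pax6/receptor correlation and per-species means — the sidecar
#' table written next to persisted results.
#'
#' @param result an `ov_result`.
#' @return A data frame.
#' @export
metrics_table <- function(result) {
  stopifnot(inherits(result, "ov_result"))
  g <- result$geometry
  rows <- lapply(seq_along(result$snapshots), function(i) {
    s <- pattern_summary(result, snapshot = i)
    st <- result$snapshots[[i]]
    sel <- function(f) if (inherits(g, "ov_mask")) mean(f[g$mask]) else mean(f)
    data.frame(time = s$time, pole_count = s$pole_count,
               polarisation_index = s$polarisation_index,
               polarisation_angle = s$polarisation_angle,
               pax6_receptor_correlation = s$pax6_receptor_correlation,
               outcome_class = s$outcome_class,
               mean_P = sel(st$P), mean_F = sel(st$F), mean_T = sel(st$T),
               mean_C = sel(st$C), mean_B = sel(st$B))
  })
  do.call(rbind, rows)
}
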