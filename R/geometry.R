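#' One-dimensional simulation grid
#'
#' A uniform 1D grid of cell-centred nodes: node `i` sits at
#' `x = (i - 1/2) dx`, so the domain is `[0, L]` with `L = n_points * dx`.
#'
#' @param n_points number of grid points (>= 3).
#' @param dx grid spacing (> 0).
#' @param boundary `"zero_flux"` (no material crosses the domain ends;
#'   models an isolated explant) or `"periodic"` (models a closed
#'   spherical organoid surface).
#' @return An object of class `ov_grid`.
#' @export
grid_1d <- function(n_points, dx, boundary = c("zero_flux", "periodic")) {
  boundary <- match.arg(boundary)
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be >= 3")
  if (!is.numeric(dx) || dx <= 0) stop("dx must be > 0")
  structure(list(n_points = n_points, dx = dx, boundary = boundary,
                 length = n_points * dx,
                 x = (seq_len(n_points) - 0.5) * dx),
            class = "ov_grid")
}

#' @export
print.ov_grid <- function(x, ...) {
  cat(sprintf("1D grid: %d points, dx = %g, L = %g, %s boundaries\n",
              x$n_points, x$dx, x$length, x$boundary))
  invisible(x)
}

#' Explant-shaped 2D domain mask
#'
#' Rasterises an explant outline onto a regular grid and returns a
#' boolean mask (`TRUE` = tissue) together with its measured principal
#' axes. The default outline is a capsule (a rectangle capped by two
#' semicircles), matching the elongated profile of a collapsed
#' optic-vesicle explant and giving an unambiguous long axis; an ellipse
#' is also available. The long axis is aligned with the raster x
#' direction (columns); coordinates are cell-centred, row-major, origin
#' at the top-left, with orientation angles measured from the +x axis.
#'
#' @param long_axis,short_axis outline dimensions (length units);
#'   `long_axis >= short_axis > 4 * dx`.
#' @param dx grid spacing.
#' @param shape `"capsule"` or `"ellipse"`.
#' @param pad number of empty raster cells added around the outline.
#' @return An object of class `ov_mask` with fields `mask` (logical
#'   matrix), `dx`, `long_axis`, `short_axis`, `angle` (long-axis
#'   orientation, degrees), and cell-centre coordinate matrices `xc`,
#'   `yc`.
#' @export
explant_mask <- function(long_axis, short_axis, dx,
                         shape = c("capsule", "ellipse"), pad = 1L) {
  shape <- match.arg(shape)
  if (short_axis > long_axis) stop("long_axis must be >= short_axis")
  if (short_axis <= 4 * dx)
    stop("resolution too coarse: short_axis must exceed 4 * dx")
  nx <- ceiling(long_axis / dx) + 2L * pad
  ny <- ceiling(short_axis / dx) + 2L * pad
  # cell centres, x along columns
  xc <- outer(rep(1, ny), (seq_len(nx) - 0.5) * dx)
  yc <- outer((seq_len(ny) - 0.5) * dx, rep(1, nx))
  cx <- nx * dx / 2
  cy <- ny * dx / 2
  a <- long_axis / 2
  b <- short_axis / 2
  if (shape == "ellipse") {
    mask <- ((xc - cx) / a)^2 + ((yc - cy) / b)^2 <= 1
  } else {
    hx <- a - b  # half-length of the straight section
    dxs <- pmax(abs(xc - cx) - hx, 0)
    mask <- dxs^2 + (yc - cy)^2 <= b^2
  }
  if (!any(mask)) stop("empty mask; check dimensions")
  if (n_components(mask) != 1L) stop("mask is not a single connected component")
  structure(list(mask = mask, dx = dx, long_axis = long_axis,
                 short_axis = short_axis, angle = 0, shape = shape,
                 xc = xc, yc = yc),
            class = "ov_mask")
}

#' @export
print.ov_mask <- function(x, ...) {
  cat(sprintf("2D %s mask: %g x %g (dx = %g), %d tissue cells, long axis at %g deg\n",
              x$shape, x$long_axis, x$short_axis, x$dx, sum(x$mask), x$angle))
  invisible(x)
}

# 4-connected component count/labels on a logical matrix (two-pass
# flood fill; masks here are small rasters, a few thousand cells)
label_components <- function(m, connectivity = 4L) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- if (connectivity == 4L)
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        ii <- ij[1] + o[1]; jj <- ij[2] + o[2]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

n_components <- function(m, connectivity = 4L) max(label_components(m, connectivity))

# principal axes of a mask (or an intensity field on it) from second
# moments; returns list(angle_deg, major, minor) with lengths as
# full extents (4 sigma equivalents are not used; extents come from
# projections onto the principal directions)
principal_axes <- function(mask, dx) {
  idx <- which(mask$mask, arr.ind = TRUE)
  x <- mask$xc[mask$mask]; y <- mask$yc[mask$mask]
  mx <- mean(x); my <- mean(y)
  cxx <- mean((x - mx)^2); cyy <- mean((y - my)^2); cxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  # canonical orientation: positive x component (positive y on ties)
  if (v1[1] < 0 || (abs(v1[1]) < 1e-12 && v1[2] < 0)) v1 <- -v1
  angle <- atan2(v1[2], v1[1]) * 180 / pi
  proj1 <- (x - mx) * v1[1] + (y - my) * v1[2]
  v2 <- ev$vectors[, 2]
  proj2 <- (x - mx) * v2[1] + (y - my) * v2[2]
  list(angle = angle,
       major = diff(range(proj1)) + dx,
       minor = diff(range(proj2)) + dx,
       centroid = c(mx, my), v1 = v1, v2 = v2)
}
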