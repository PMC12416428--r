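#' Cylindrical coordinate frame
#'
#' The cylinder axis is along z (the first coordinate); the azimuth theta is
#' measured from the +x axis toward the +y axis. This is the package's fixed
#' convention.
#'
#' @param origin point (z, y, x) on the axis; typically the image center.
#' @return object of class \code{"cyl_frame"}.
#' @export
cyl_frame <- function(origin = c(0, 0, 0)) {
  structure(list(origin = as.numeric(origin)), class = "cyl_frame")
}

# local orthonormal cylindrical basis at points (n x 3 matrix, z,y,x);
# rows of Q[[i]] are (e_r, e_theta, e_z) expressed in (z, y, x)
cyl_basis <- function(points, frame) {
  dz <- points[, 1] - frame$origin[1]
  dy <- points[, 2] - frame$origin[2]
  dx <- points[, 3] - frame$origin[3]
  r <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  list(r = r, theta = theta, z = dz)
}

#' Cartesian to cylindrical passage for points, vectors and tensors
#'
#' Converts point coordinates to (r, theta, z) and conjugates vectors and
#' tensors by the local orthonormal basis (e_r, e_theta, e_z) at each point.
#' Tensor invariants (trace, eigenvalues) are preserved to machine
#' precision, and \code{\link{from_cylindrical}} inverts the passage
#' exactly. Points on the axis have no defined azimuth and yield \code{NA}
#' components (flagged, not dropped).
#'
#' @param points n x 3 matrix of Cartesian points (z, y, x).
#' @param vectors optional n x 3 matrix of vectors (z, y, x) attached to the
#'   points.
#' @param tensors optional list (or 3x3 matrix for n = 1) of symmetric
#'   tensors attached to the points.
#' @param frame a \code{\link{cyl_frame}}.
#' @return list with \code{points} (columns r, theta, z), and when supplied
#'   \code{vectors} (columns v_r, v_theta, v_z) and \code{tensors} (list of
#'   3x3 matrices with rows/cols r, theta, z), plus \code{on_axis} flags.
#' @export
to_cylindrical <- function(points, vectors = NULL, tensors = NULL,
                           frame = cyl_frame()) {
  points <- matrix(as.numeric(points), ncol = 3)
  b <- cyl_basis(points, frame)
  on_axis <- b$r == 0
  out <- list(points = cbind(r = b$r, theta = ifelse(on_axis, NA, b$theta),
                             z = b$z),
              on_axis = on_axis)
  rot <- function(i) {
    ct <- cos(b$theta[i]); st <- sin(b$theta[i])
    # rows e_r, e_theta, e_z in (z, y, x) components
    rbind(c(0, st, ct), c(0, ct, -st), c(1, 0, 0))
  }
  if (!is.null(vectors)) {
    vectors <- matrix(as.numeric(vectors), ncol = 3)
    vc <- t(vapply(seq_len(nrow(points)), function(i) {
      if (on_axis[i]) return(rep(NA_real_, 3))
      as.numeric(rot(i) %*% vectors[i, ])
    }, numeric(3)))
    colnames(vc) <- c("v_r", "v_theta", "v_z")
    out$vectors <- vc
  }
  if (!is.null(tensors)) {
    if (is.matrix(tensors)) tensors <- list(tensors)
    out$tensors <- lapply(seq_along(tensors), function(i) {
      if (on_axis[i]) return(matrix(NA_real_, 3, 3))
      Q <- rot(i)
      Q %*% tensors[[i]] %*% t(Q)
    })
  }
  out
}

#' Cylindrical to Cartesian passage (inverse of \code{to_cylindrical})
#'
#' @param points_cyl n x 3 matrix with columns (r, theta, z).
#' @param vectors optional n x 3 matrix with components (v_r, v_theta, v_z).
#' @param tensors optional list of 3x3 tensors in the cylindrical basis.
#' @param frame a \code{\link{cyl_frame}}.
#' @return list with Cartesian \code{points} (z, y, x) and, when supplied,
#'   \code{vectors} and \code{tensors}.
#' @export
from_cylindrical <- function(points_cyl, vectors = NULL, tensors = NULL,
                             frame = cyl_frame()) {
  points_cyl <- matrix(as.numeric(points_cyl), ncol = 3)
  r <- points_cyl[, 1]; theta <- points_cyl[, 2]; z <- points_cyl[, 3]
  pts <- cbind(z = z + frame$origin[1],
               y = r * sin(theta) + frame$origin[2],
               x = r * cos(theta) + frame$origin[3])
  out <- list(points = pts)
  rot <- function(i) {
    ct <- cos(theta[i]); st <- sin(theta[i])
    rbind(c(0, st, ct), c(0, ct, -st), c(1, 0, 0))
  }
  if (!is.null(vectors)) {
    vectors <- matrix(as.numeric(vectors), ncol = 3)
    vc <- t(vapply(seq_len(nrow(pts)), function(i)
      as.numeric(t(rot(i)) %*% vectors[i, ]), numeric(3)))
    colnames(vc) <- c("z", "y", "x")
    out$vectors <- vc
  }
  if (!is.null(tensors)) {
    if (is.matrix(tensors)) tensors <- list(tensors)
    out$tensors <- lapply(seq_along(tensors), function(i) {
      Q <- rot(i)
      t(Q) %*% tensors[[i]] %*% Q
    })
  }
  out
}

#' Cartesian to spherical passage
#'
#' Spherical coordinates (rho, phi polar angle from the +z axis, theta
#' azimuth from +x toward +y) with the local orthonormal basis
#' (e_rho, e_phi, e_theta) used to conjugate vectors and tensors; the same
#' round-trip and invariant-preservation contract as the cylindrical
#' passage.
#'
#' @inheritParams to_cylindrical
#' @return list with \code{points} (columns rho, phi, theta), optional
#'   \code{vectors}/\code{tensors} in the spherical basis and \code{on_axis}
#'   flags (rho = 0 or on the polar axis).
#' @export
to_spherical <- function(points, vectors = NULL, tensors = NULL,
                         frame = cyl_frame()) {
  points <- matrix(as.numeric(points), ncol = 3)
  dz <- points[, 1] - frame$origin[1]
  dy <- points[, 2] - frame$origin[2]
  dx <- points[, 3] - frame$origin[3]
  rho <- sqrt(dz^2 + dy^2 + dx^2)
  rcyl <- sqrt(dy^2 + dx^2)
  on_axis <- rcyl == 0
  phi <- acos(ifelse(rho == 0, NA, dz / rho))
  theta <- ifelse(on_axis, NA, atan2(dy, dx))
  out <- list(points = cbind(rho = rho, phi = phi, theta = theta),
              on_axis = on_axis)
  rot <- function(i) {
    ct <- cos(theta[i]); st <- sin(theta[i])
    cp <- cos(phi[i]); sp <- sin(phi[i])
    # rows e_rho, e_phi, e_theta in (z, y, x)
    rbind(c(cp, sp * st, sp * ct),
          c(-sp, cp * st, cp * ct),
          c(0, ct, -st))
  }
  conv <- function(fun) {
    vapply(seq_len(nrow(points)), fun, numeric(3))
  }
  if (!is.null(vectors)) {
    vectors <- matrix(as.numeric(vectors), ncol = 3)
    vc <- t(conv(function(i) {
      if (on_axis[i]) return(rep(NA_real_, 3))
      as.numeric(rot(i) %*% vectors[i, ])
    }))
    colnames(vc) <- c("v_rho", "v_phi", "v_theta")
    out$vectors <- vc
  }
  if (!is.null(tensors)) {
    if (is.matrix(tensors)) tensors <- list(tensors)
    out$tensors <- lapply(seq_along(tensors), function(i) {
      if (on_axis[i]) return(matrix(NA_real_, 3, 3))
      Q <- rot(i)
      Q %*% tensors[[i]] %*% t(Q)
    })
  }
  out
}

#' Grid average of positioned scalars, vectors or tensors
#'
#' Component-wise arithmetic mean of values attached to points, per cell of
#' a Cartesian grid. Cells with fewer than \code{min_count} contributors are
#' flagged invalid (\code{NA} values), and the per-cell counts are returned.
#' The operation is linear in the values.
#'
#' @param positions n x 3 matrix of zero-based (z, y, x) coordinates.
#' @param values numeric vector (scalars) or n x k matrix (vector/tensor
#'   components).
#' @param grid a \code{\link{grid_spec}}.
#' @param extent image shape (z, y, x) defining the grid extent.
#' @param min_count minimum contributors for a valid cell.
#' @return list with \code{mean} (cells x k matrix, \code{NA} rows where
#'   invalid), \code{count} (per-cell contributors), \code{cell_index}
#'   (3-column matrix of cell coordinates, zero-based) and \code{dim}
#'   (grid dimensions).
#' @export
grid_average <- function(positions, values, grid, extent, min_count = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  positions <- matrix(as.numeric(positions), ncol = 3)
  values <- as.matrix(values)
  if (nrow(values) != nrow(positions))
    stop("values must have one row per position")
  gc <- grid_cells(grid, extent)
  cells <- point_cell_index(positions, grid, gc$n)
  ncell <- prod(gc$n)
  count <- tabulate(cells, nbins = ncell)
  sums <- matrix(0, ncell, ncol(values))
  occupied <- sort(unique(cells))
  sums[occupied, ] <- rowsum(values, cells)  # rows ordered by sorted group
  m <- sums / count
  m[count < min_count, ] <- NA_real_
  ci <- index_to_coords(seq_len(ncell), gc$n)
  colnames(ci) <- c("cz", "cy", "cx")
  list(mean = m, count = count, cell_index = ci, dim = gc$n)
}

#' Export an orthogonal cross-section of a volume as PNG
#'
#' Minimal visual check on a 3D field: extracts one slice perpendicular to
#' an axis, normalizes it to [0, 1] and writes a grayscale PNG.
#'
#' @param vol 3D array.
#' @param path output file.
#' @param axis \code{"z"}, \code{"y"} or \code{"x"}.
#' @param index one-based slice index; defaults to the middle slice.
#' @return the path, invisibly.
#' @export
export_slice_png <- function(vol, path, axis = c("z", "y", "x"),
                             index = NULL) {
  check_vol(vol)
  axis <- match.arg(axis)
  ai <- match(axis, c("z", "y", "x"))
  if (is.null(index)) index <- ceiling(dim(vol)[ai] / 2)
  sl <- switch(axis, z = vol[index, , ], y = vol[, index, ],
               x = vol[, , index])
  rng <- range(sl)
  if (diff(rng) > 0) sl <- (sl - rng[1]) / diff(rng)
  else sl <- array(0, dim = dim(sl))
  png::writePNG(sl, path)
  invisible(path)
}
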