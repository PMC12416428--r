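#' Cartesian grid specification
#'
#' Describes the tiling of an image into sub-volume cells for gridded fields
#' (liquid fraction, averaged tensors). Partial cells at the far edges are
#' kept and flagged, not discarded.
#'
#' @param cell_shape voxels per cell (z, y, x); a scalar is recycled.
#' @return object of class \code{"grid_spec"}.
#' @export
grid_spec <- function(cell_shape) {
  cell_shape <- as.integer(rep(cell_shape, length.out = 3L))
  if (any(cell_shape < 1L)) stop("cell_shape must be >= 1")
  structure(list(cell_shape = cell_shape), class = "grid_spec")
}

# per-voxel (or per-point) cell index for a given extent; zero-based coords
grid_cells <- function(grid, extent) {
  nc <- as.integer(ceiling(extent / grid$cell_shape))
  partial <- array(FALSE, dim = nc)
  if (nc[1] * grid$cell_shape[1] > extent[1]) partial[nc[1], , ] <- TRUE
  if (nc[2] * grid$cell_shape[2] > extent[2]) partial[, nc[2], ] <- TRUE
  if (nc[3] * grid$cell_shape[3] > extent[3]) partial[, , nc[3]] <- TRUE
  list(n = nc, partial = partial)
}

point_cell_index <- function(points, grid, nc) {
  cz <- pmin(floor(points[, 1] / grid$cell_shape[1]), nc[1] - 1L)
  cy <- pmin(floor(points[, 2] / grid$cell_shape[2]), nc[2] - 1L)
  cx <- pmin(floor(points[, 3] / grid$cell_shape[3]), nc[3] - 1L)
  as.integer(cz + nc[1] * (cy + nc[2] * cx)) + 1L
}

#' Liquid fraction of a phase map
#'
#' The number of liquid voxels divided by the total number of valid voxels,
#' globally or per cell of a Cartesian grid. Only voxels inside the validity
#' mask are counted; a grid cell with no valid voxel is reported as \code{NA},
#' never as 0.
#'
#' @param phase binary array, 1 = liquid; a mask attached by
#'   \code{\link{segment_phase}} is honored unless \code{mask} is given.
#' @param grid optional \code{\link{grid_spec}}; if supplied, a gridded field
#'   is returned.
#' @param mask optional binary validity array.
#' @return a scalar, or (gridded) a list with \code{phi} (3D array of cell
#'   values, \code{NA} where no valid voxel), \code{n_valid}, \code{n_total}
#'   and \code{partial} (logical array flagging clipped edge cells).
#' @export
liquid_fraction <- function(phase, grid = NULL, mask = NULL) {
  check_phase(phase)
  if (is.null(mask)) mask <- attr(phase, "mask")
  d <- dim(phase)
  valid <- if (is.null(mask)) array(TRUE, dim = d) else mask > 0
  if (is.null(grid)) {
    nv <- sum(valid)
    if (nv == 0L) return(NA_real_)
    return(sum(phase[valid]) / nv)
  }
  stopifnot(inherits(grid, "grid_spec"))
  gc <- grid_cells(grid, d)
  idx <- seq_len(prod(d))
  cells <- point_cell_index(index_to_coords(idx, d), grid, gc$n)
  ncell <- prod(gc$n)
  n_valid <- tabulate(cells[valid], nbins = ncell)
  n_liq <- tabulate(cells[valid & phase == 1L], nbins = ncell)
  phi <- n_liq / n_valid
  phi[n_valid == 0L] <- NA_real_
  list(phi = array(phi, dim = gc$n),
       n_valid = array(n_valid, dim = gc$n),
       n_total = array(tabulate(cells, nbins = ncell), dim = gc$n),
       partial = gc$partial)
}

#' Per-bubble region properties
#'
#' One row per label, ordered by ascending label: centroid (zero-based voxel
#' coordinates), volume (exact voxel count), equivalent radius
#' \eqn{R_V = (3V/4\pi)^{1/3}}, the shape tensor \code{S_*} and the shape
#' strain \code{US_*} (component order zz, zy, zx, yy, yx, xx). Bubbles whose
#' shape tensor is singular (flat regions, fewer than a few voxels) carry
#' \code{NA} strain components.
#'
#' @param labels integer label array with at least one label.
#' @return data frame of per-bubble properties.
#' @export
region_properties <- function(labels) {
  check_labels(labels)
  idx <- which(labels > 0L)
  if (!length(idx)) stop("empty label map")
  co <- index_to_coords(idx, dim(labels))
  lab <- labels[idx]
  split_idx <- split(seq_along(lab), lab)
  rows <- lapply(split_idx, function(ii) {
    v <- co[ii, , drop = FALSE]
    st <- shape_tensor(v)
    US <- tryCatch(shape_strain(st$S), error = function(e) matrix(NA_real_, 3, 3))
    V <- length(ii)
    c(label = NA_real_, z = st$centroid[["z"]], y = st$centroid[["y"]],
      x = st$centroid[["x"]], V = V, R_V = (3 * V / (4 * pi))^(1 / 3),
      tensor_to_row(st$S, "S"), tensor_to_row(US, "US"))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- as.integer(names(split_idx))
  out[order(out$label), , drop = FALSE]
}

#' Mean, Sauter radius and polydispersity of a bubble population
#'
#' \eqn{\langle R \rangle} is the arithmetic mean of the equivalent radii,
#' the Sauter radius is the moment ratio
#' \eqn{R_{32} = \langle R^3 \rangle / \langle R^2 \rangle} (weighted toward
#' large bubbles; \eqn{R_{32} \ge \langle R \rangle} always), and the
#' polydispersity is \eqn{p_{32} = R_{32} / \langle R \rangle - 1}, which
#' vanishes exactly for a monodisperse foam.
#'
#' @param records region table from \code{\link{region_properties}} (its
#'   \code{R_V} column is used) or a numeric vector of radii.
#' @return list with \code{mean_R}, \code{R32}, \code{p32}.
#' @export
radius_statistics <- function(records) {
  r <- if (is.data.frame(records)) records$R_V else as.numeric(records)
  if (!length(r)) stop("no radii supplied")
  if (any(r <= 0)) stop("radii must be > 0")
  mean_R <- mean(r)
  R32 <- mean(r^3) / mean(r^2)
  list(mean_R = mean_R, R32 = R32, p32 = R32 / mean_R - 1)
}

#' Local thickness of a phase
#'
#' Maximal-inscribed-sphere thickness: the value at a voxel is the diameter
#' of the largest sphere that fits entirely inside the selected phase and
#' contains that voxel (zero outside the phase). Computed from the Euclidean
#' distance transform by sphere painting from non-dominated centers, with the
#' sphere surface taken half a voxel inside the nearest background voxel
#' center. Intended for moderate volumes (up to roughly 128^3 voxels).
#'
#' @param phase binary array, 1 = liquid.
#' @param phase_of_interest \code{"liquid"} or \code{"gas"}.
#' @return 3D numeric array of thickness values (voxels).
#' @export
local_thickness <- function(phase, phase_of_interest = c("liquid", "gas")) {
  check_phase(phase)
  phase_of_interest <- match.arg(phase_of_interest)
  inside <- if (phase_of_interest == "liquid") phase == 1L else phase == 0L
  if (!any(inside)) stop("selected phase is empty")
  d <- dim(phase)
  edt <- sqrt(cpp_edt_sq(inside, d, TRUE))
  array(cpp_local_thickness(edt, d), dim = d)
}
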