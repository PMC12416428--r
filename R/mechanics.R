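#' Shape tensor of a bubble
#'
#' Second-moment tensor of the bubble's voxel coordinates about their
#' centroid, \eqn{S = \langle (r - \bar r)(r - \bar r)^T \rangle}, the average
#' running over all voxels of the bubble. The eigenvectors give the bubble's
#' principal axes; for a uniform ellipsoid with semi-axes (a, b, c) the
#' eigenvalues are (a^2, b^2, c^2)/5.
#'
#' @param coords n x 3 matrix of voxel coordinates (z, y, x).
#' @return list with \code{centroid} and the symmetric positive-semidefinite
#'   3x3 matrix \code{S} (voxel^2 units).
#' @export
shape_tensor <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("at least one voxel required")
  ctr <- colMeans(coords)
  dc <- sweep(coords, 2, ctr)
  S <- crossprod(dc) / nrow(coords)
  dimnames(S) <- NULL
  list(centroid = ctr, S = S)
}

# logarithmic (Hencky) strain of a positive-definite moment tensor about its
# isotropic state built from the geometric mean of the eigenvalues:
# U = 1/2 (ln lambda - mean ln lambda) in the eigenbasis. The 1/2 converts
# the squared-length units of the moment tensor to a length-based strain, so
# U is traceless by construction.
log_strain <- function(Tm, label = "tensor") {
  e <- eigen(Tm, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("singular ", label,
         ": flat or degenerate region, strain undefined", call. = FALSE)
  lv <- log(e$values)
  u <- 0.5 * (lv - mean(lv))
  U <- e$vectors %*% diag(u) %*% t(e$vectors)
  (U + t(U)) / 2
}

#' Strain tensor from the bubble shape tensor
#'
#' Logarithmic deviation of the shape tensor from its isotropic state, built
#' from the geometric mean of the three eigenvalues
#' \eqn{S_0 = (\lambda_1 \lambda_2 \lambda_3)^{1/3}}. The result is symmetric
#' and traceless: a bubble stretched by the volume-preserving factor
#' \eqn{e^\epsilon} along one axis has strain eigenvalues
#' \eqn{(\epsilon, -\epsilon/2, -\epsilon/2)}, and an isotropic bubble has
#' zero strain.
#'
#' @param S symmetric positive-definite shape tensor from
#'   \code{\link{shape_tensor}}.
#' @return symmetric traceless 3x3 strain tensor.
#' @export
shape_strain <- function(S) log_strain(S, "shape tensor")

#' Texture tensor of a bubble's link network
#'
#' Average outer product \eqn{M = \langle l l^T \rangle} of the link vectors
#' from a bubble's center to the centers of its neighbors. The texture is an
#' arrangement-based (rather than shape-based) proxy for local anisotropy.
#'
#' @param center bubble center (z, y, x).
#' @param neighbor_centers n x 3 matrix of neighbor centers.
#' @return symmetric positive-semidefinite 3x3 matrix (length^2 units).
#' @export
texture_tensor <- function(center, neighbor_centers) {
  nb <- matrix(as.numeric(as.matrix(neighbor_centers)), ncol = 3)
  if (nrow(nb) < 1L) stop("texture undefined: bubble has no links")
  l <- sweep(nb, 2, center)
  M <- crossprod(l) / nrow(l)
  dimnames(M) <- NULL
  M
}

#' Strain tensor from the texture tensor
#'
#' Logarithmic deviation of the texture tensor from its isotropic state
#' (geometric mean of the eigenvalues), with the factor 1/2 that accounts for
#' the texture tensor carrying squared-length units. Symmetric and traceless;
#' zero for an isotropic texture.
#'
#' @param M symmetric positive-definite texture tensor.
#' @return symmetric traceless 3x3 strain tensor.
#' @export
texture_strain <- function(M) log_strain(M, "texture tensor")

#' Texture and texture-strain table for all bubbles
#'
#' Combines per-bubble centroids with the contact network to compute the
#' texture tensor and its strain for every bubble with at least one neighbor.
#'
#' @param regions region table from \code{\link{region_properties}}.
#' @param net contact network from \code{\link{get_contacts}}.
#' @return data frame with one row per bubble: label, number of links,
#'   texture components \code{M_*} and strain components \code{UM_*}
#'   (component order zz, zy, zx, yy, yx, xx); bubbles with no links or a
#'   singular texture carry \code{NA} components.
#' @export
texture_table <- function(regions, net) {
  cents <- as.matrix(regions[, c("z", "y", "x")])
  rownames(cents) <- regions$label
  nbs <- neighbor_sets(net$pairs)
  rows <- lapply(regions$label, function(lab) {
    nb <- nbs[[as.character(lab)]]
    base <- c(label = lab, n_links = length(nb))
    if (!length(nb) || !all(as.character(nb) %in% rownames(cents)))
      return(c(base, tensor_to_row(matrix(NA_real_, 3, 3), "M"),
               tensor_to_row(matrix(NA_real_, 3, 3), "UM")))
    M <- texture_tensor(cents[as.character(lab), ],
                        cents[as.character(nb), , drop = FALSE])
    UM <- tryCatch(texture_strain(M), error = function(e) matrix(NA_real_, 3, 3))
    c(base, tensor_to_row(M, "M"), tensor_to_row(UM, "UM"))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Interfacial (Batchelor) elastic stress tensor of a bubble
#'
#' Integrates the surface-tension stress over the bubble's gas-liquid
#' interface: the bubble region is meshed at the 0.5 level of its binary
#' mask (anti-aliased by a small fixed Gaussian so that triangle normals
#' approximate the smooth interface rather than the voxel staircase) and the
#' deviatoric integrand \eqn{n n^T - Id/3} is accumulated per triangle,
#' scaled by \eqn{\Gamma / V}. The isotropic pressure part of the stress is
#' not included, since pressure is not an accessible quantity; the tensor is
#' deviatoric by construction, with tension positive.
#'
#' @param labels integer label array.
#' @param label the bubble to evaluate.
#' @param Gamma surface tension (N/m for stresses in Pa when
#'   \code{voxel_size} is in meters).
#' @param voxel_size voxel edge length.
#' @param smooth_sigma standard deviation of the anti-aliasing blur applied
#'   to the binary mask before meshing, voxels.
#' @return list of class \code{"stress_record"}: \code{sigma} (3x3 symmetric,
#'   deviatoric), \code{V_vox} (voxel count), \code{V}, \code{area} (physical
#'   units), \code{Gamma}, \code{voxel_size}.
#' @export
batchelor_stress <- function(labels, label, Gamma = 1, voxel_size = 1,
                             smooth_sigma = 1) {
  check_labels(labels)
  d <- dim(labels)
  idx <- which(labels == label)
  if (!length(idx)) stop("label ", label, " not present")
  co <- index_to_coords(idx, d) + 1L  # one-based bounds
  lo <- apply(co, 2, min); hi <- apply(co, 2, max)
  if (any(lo == 1L) || any(hi == d))
    stop("bubble ", label, " touches the image edge: its interface is open; ",
         "run remove_edge_bubbles() first")
  pad <- as.integer(ceiling(4 * smooth_sigma) + 2L)
  lo <- pmax(lo - pad, 1L); hi <- pmin(hi + pad, d)
  sub <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == label
  sd <- dim(sub)
  vol <- cpp_gauss3(as.double(sub), sd, smooth_sigma)
  mesh <- cpp_mesh_tensor(vol, sd, 0.5)
  V_vox <- length(idx)
  Tm <- mesh$tensor
  A <- mesh$area
  sigma <- Gamma / (V_vox * voxel_size) * (Tm - diag(3) * A / 3)
  structure(list(label = label, sigma = (sigma + t(sigma)) / 2,
                 V_vox = V_vox, V = V_vox * voxel_size^3,
                 area = A * voxel_size^2, Gamma = Gamma,
                 voxel_size = voxel_size),
            class = "stress_record")
}

#' @export
print.stress_record <- function(x, ...) {
  cat("Interfacial stress of bubble", x$label, "\n")
  cat("  V =", x$V, " area =", signif(x$area, 6), " Gamma =", x$Gamma, "\n")
  cat("  sigma (deviatoric):\n")
  print(signif(x$sigma, 5))
  invisible(x)
}

#' Interfacial stress table for all interior bubbles
#'
#' Runs \code{\link{batchelor_stress}} on every label that does not touch the
#' image edge and returns the six independent stress components per bubble.
#'
#' @inheritParams batchelor_stress
#' @return data frame with label, V, area and components \code{sig_*}
#'   (order zz, zy, zx, yy, yx, xx).
#' @export
batchelor_stress_all <- function(labels, Gamma = 1, voxel_size = 1,
                                 smooth_sigma = 1) {
  interior <- remove_edge_bubbles(labels)
  labs <- sort(unique(interior[interior > 0L]))
  rows <- lapply(labs, function(lb) {
    sr <- batchelor_stress(labels, lb, Gamma, voxel_size, smooth_sigma)
    c(label = lb, V = sr$V, area = sr$area, tensor_to_row(sr$sigma, "sig"))
  })
  if (!length(rows))
    return(data.frame(label = integer(), V = numeric(), area = numeric()))
  as.data.frame(do.call(rbind, rows))
}
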