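#' Specification of a synthetic foam volume
#'
#' Bundles the parameters of the synthetic-foam generator: box size, bubble
#' count, radius law, film thickness and random seed. The generator emulates
#' the statistical structure of tomograms of wet foams (polydisperse sphere
#' packings separated by liquid films) with exact ground truth, so that every
#' downstream stage of the quantification chain can be validated without any
#' experimental data.
#'
#' @param box_shape integer vector (nz, ny, nx), each >= 16.
#' @param n_bubbles number of bubbles, >= 1.
#' @param radius_law either \code{"constant"} or \code{"lognormal"}.
#' @param radius bubble radius in voxels (constant law).
#' @param meanlog,sdlog log-normal parameters of the radius in voxels
#'   (lognormal law).
#' @param film_thickness liquid film thickness between bubbles, voxels, >= 0.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @param drift displacement vector (z, y, x) in voxels per frame used by
#'   sequence generation.
#' @return an object of class \code{"foam_spec"}.
#' @export
foam_spec <- function(box_shape = c(64, 64, 64), n_bubbles = 27,
                      radius_law = c("constant", "lognormal"), radius = 8,
                      meanlog = log(8), sdlog = 0.2, film_thickness = 1,
                      seed = 1L, drift = c(0, 0, 0)) {
  radius_law <- match.arg(radius_law)
  box_shape <- as.integer(box_shape)
  if (length(box_shape) != 3L || any(box_shape < 16L))
    stop("box_shape must be three integers, all >= 16")
  if (n_bubbles < 1L) stop("n_bubbles must be >= 1")
  if (film_thickness < 0) stop("film_thickness must be >= 0")
  if (radius_law == "constant" && radius <= 0) stop("radius must be > 0")
  structure(list(box_shape = box_shape, n_bubbles = as.integer(n_bubbles),
                 radius_law = radius_law, radius = radius, meanlog = meanlog,
                 sdlog = sdlog, film_thickness = film_thickness,
                 seed = as.integer(seed), drift = drift),
            class = "foam_spec")
}

#' @export
print.foam_spec <- function(x, ...) {
  cat("Synthetic foam specification\n")
  cat("  box (z,y,x):", paste(x$box_shape, collapse = " x "), "voxels\n")
  cat("  bubbles:", x$n_bubbles, " radius law:", x$radius_law, "\n")
  if (x$radius_law == "constant") cat("  radius:", x$radius, "voxels\n")
  else cat("  meanlog:", x$meanlog, " sdlog:", x$sdlog, "\n")
  cat("  film thickness:", x$film_thickness, "voxels  seed:", x$seed, "\n")
  invisible(x)
}

# draw radii according to the spec's law
draw_radii <- function(spec) {
  if (spec$radius_law == "constant") rep(spec$radius, spec$n_bubbles)
  else rlnorm(spec$n_bubbles, spec$meanlog, spec$sdlog)
}

# rasterize spheres as a restricted Laguerre (power-distance) assignment:
# a voxel joins bubble k when |v - c_k| <= r_k, taking the smallest power
# distance when several spheres claim it (ties -> lowest label).
rasterize_spheres <- function(centers, radii, box) {
  labels <- array(0L, dim = box)
  best <- array(Inf, dim = box)
  ax <- lapply(box, function(n) seq_len(n) - 1)  # zero-based voxel centers
  for (k in seq_len(nrow(centers))) {
    c_k <- centers[k, ]
    r <- radii[k]
    lo <- pmax(1L, floor(c_k - r) + 1L)
    hi <- pmin(box, ceiling(c_k + r) + 1L)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- (ax[[1]][iz] - c_k[1])^2
    dy2 <- (ax[[2]][iy] - c_k[2])^2
    dx2 <- (ax[[3]][ix] - c_k[3])^2
    d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    pd <- d2 - r^2
    inside <- d2 <= r^2
    sub_best <- best[iz, iy, ix]
    take <- inside & (pd < sub_best)
    if (any(take)) {
      sub_lab <- labels[iz, iy, ix]
      sub_lab[take] <- k
      sub_best[take] <- pd[take]
      labels[iz, iy, ix] <- sub_lab
      best[iz, iy, ix] <- sub_best
    }
  }
  labels
}

# ground truth consistent with a rasterized label map
packing_truth <- function(labels, centers, radii, film_thickness,
                          adjacency_tol = 1) {
  n <- nrow(centers)
  vols <- tabulate(labels[labels > 0L], nbins = n)
  idx <- which(labels > 0L)
  co <- index_to_coords(idx, dim(labels))
  lab <- labels[idx]
  cent <- cbind(
    z = as.vector(tapply(co[, 1], lab, mean)),
    y = as.vector(tapply(co[, 2], lab, mean)),
    x = as.vector(tapply(co[, 3], lab, mean))
  )
  adj <- NULL
  if (n >= 2) {
    dmat <- as.matrix(stats::dist(centers))
    gap <- dmat - outer(radii, radii, "+")
    hit <- which(upper.tri(gap) & gap <= film_thickness + adjacency_tol,
                 arr.ind = TRUE)
    if (nrow(hit)) adj <- cbind(p = hit[, 1], q = hit[, 2])
  }
  if (is.null(adj)) adj <- cbind(p = integer(), q = integer())
  list(centroids = cent, designed_centers = centers, radii = radii,
       volumes = vols, adjacency = adj)
}

#' Generate a synthetic foam packing with ground truth
#'
#' Places non-overlapping spheres separated by at least the film thickness of
#' liquid, either by random sequential addition (with optional simultaneous
#' radius growth until the tightest pair reaches the film-thickness gap) or on
#' a jittered cubic grid whose spacing realizes the film gap exactly. Spheres
#' are rasterized by nearest-seed (power distance) assignment, so bubbles are
#' convex and watershed-recoverable.
#'
#' Ground-truth adjacency declares two bubbles neighbors when their surface
#' gap is at most \code{film_thickness + adjacency_tol} voxels.
#'
#' @param spec a \code{\link{foam_spec}}.
#' @param arrangement \code{"random"} (sequential addition) or \code{"grid"}
#'   (jittered cubic grid, monodisperse packings).
#' @param jitter uniform jitter amplitude of grid positions, voxels.
#' @param margin clearance kept between spheres and the box faces, voxels.
#' @param grow if \code{TRUE}, radii are scaled by the common factor that
#'   brings the closest pair (or face) to the film-thickness gap.
#' @param max_tries placement attempts per bubble before giving up.
#' @param adjacency_tol slack of the ground-truth contact criterion, voxels.
#' @return a list of class \code{"foam_packing"}: \code{labels} (integer
#'   array), \code{phase} (binary array, 1 = liquid), and \code{truth} with
#'   per-bubble \code{centroids} (zero-based voxel coordinates),
#'   \code{radii}, \code{volumes} (exact voxel counts) and \code{adjacency}
#'   (two-column matrix of label pairs, p < q).
#' @export
make_packing <- function(spec, arrangement = c("random", "grid"),
                         jitter = 0.3, margin = 1, grow = FALSE,
                         max_tries = 200L, adjacency_tol = 1) {
  stopifnot(inherits(spec, "foam_spec"))
  arrangement <- match.arg(arrangement)
  box <- spec$box_shape
  film <- spec$film_thickness
  with_seed(spec$seed, {
    radii <- draw_radii(spec)
    n <- spec$n_bubbles
    if (arrangement == "grid") {
      if (spec$radius_law != "constant")
        stop("grid arrangement requires a constant radius law")
      k <- ceiling(n^(1 / 3))
      s <- 2 * spec$radius + film
      need <- (k - 1) * s + 2 * (spec$radius + margin + jitter)
      if (any(box - 1 < need))
        stop("box too small for a ", k, "^3 grid of radius ", spec$radius,
             " bubbles (needs ", ceiling(need) + 1, " voxels per axis)")
      g <- expand.grid(z = 0:(k - 1), y = 0:(k - 1), x = 0:(k - 1))
      g <- as.matrix(g[order(g$z, g$y, g$x), ])[seq_len(n), , drop = FALSE]
      origin <- ((box - 1) - (k - 1) * s) / 2
      centers <- sweep(g * s, 2, origin, "+")
      if (jitter > 0)
        centers <- centers + matrix(runif(3 * n, -jitter, jitter), n, 3)
    } else {
      ord <- order(radii, decreasing = TRUE)
      radii <- radii[ord]
      centers <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          lo <- radii[i] + margin
          hi <- box - 1 - radii[i] - margin
          if (any(hi < lo))
            stop("bubble of radius ", round(radii[i], 2),
                 " does not fit in the box")
          cand <- lo + runif(3) * (hi - lo)
          ok <- TRUE
          if (i > 1) {
            d <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) -
                                 cand)^2))
            ok <- all(d >= radii[seq_len(i - 1)] + radii[i] + film)
          }
          if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
        }
        if (!placed)
          stop("packing placement failed: only ", i - 1, " of ", n,
               " bubbles fit after ", max_tries, " tries each; reduce ",
               "n_bubbles or radii")
      }
    }
    if (grow && n >= 1) {
      gam <- Inf
      if (n >= 2) {
        dmat <- as.matrix(stats::dist(centers))
        rs <- outer(radii, radii, "+")
        gam <- min((dmat[upper.tri(dmat)] - film) / rs[upper.tri(rs)])
      }
      face <- pmin(apply(centers, 1, function(cc) min(cc)),
                   apply(centers, 1, function(cc) min(box - 1 - cc)))
      gam <- min(gam, min((face - margin) / radii))
      if (is.finite(gam) && gam > 1) radii <- radii * gam
    }
    labels <- rasterize_spheres(centers, radii, box)
    phase <- array(0L, dim = box)
    phase[labels == 0L] <- 1L
    truth <- packing_truth(labels, centers, radii, film, adjacency_tol)
    structure(list(labels = labels, phase = phase, truth = truth,
                   spec = spec),
              class = "foam_packing")
  })
}

#' @export
print.foam_packing <- function(x, ...) {
  cat("Synthetic foam packing:", x$spec$n_bubbles, "bubbles in",
      paste(dim(x$labels), collapse = " x "), "voxels\n")
  cat("  gas fraction:", round(mean(x$labels > 0), 3),
      " ground-truth contacts:", nrow(x$truth$adjacency), "\n")
  invisible(x)
}

#' Render a grayscale tomogram from a phase map
#'
#' Emulates a reconstructed tomogram: the gas and liquid phases are mapped to
#' two intensity levels, optionally blurred by a Gaussian point-spread
#' function and corrupted with additive white noise.
#'
#' @param phase binary array, 1 = liquid.
#' @param gas_level,liquid_level intensities of the two phases (must differ).
#' @param blur_sigma Gaussian blur standard deviation, voxels, >= 0.
#' @param noise_sigma additive Gaussian noise standard deviation, >= 0.
#' @param seed integer seed for the noise.
#' @return a 3D numeric array.
#' @export
render_tomogram <- function(phase, gas_level = 50, liquid_level = 200,
                            blur_sigma = 1, noise_sigma = 0, seed = 1L) {
  check_phase(phase)
  if (gas_level == liquid_level) stop("gas_level must differ from liquid_level")
  if (blur_sigma < 0 || noise_sigma < 0) stop("sigmas must be >= 0")
  img <- array(gas_level, dim = dim(phase))
  img[phase == 1L] <- liquid_level
  img <- cpp_gauss3(as.double(img), dim(phase), blur_sigma)
  if (noise_sigma > 0)
    img <- img + with_seed(seed, array(rnorm(length(img), 0, noise_sigma),
                                       dim = dim(phase)))
  array(img, dim = dim(phase))
}

#' Advect a label map through an affine deformation sequence
#'
#' Frame k applies the map x -> A x + t to frame k-1 (about \code{center}),
#' with nearest-neighbor resampling of the label values. Frame 1 of the
#' output is the input itself.
#'
#' @param labels integer label array.
#' @param affine invertible 3x3 matrix acting on (z, y, x) coordinates.
#' @param translation displacement vector (z, y, x), voxels per frame.
#' @param n_frames number of frames returned (>= 1).
#' @param center point the affine part acts about; defaults to the box center.
#' @return a list of label arrays. Attribute \code{"outside"} lists, per
#'   frame, labels whose transformed centroid left the box (the voxels that
#'   remain in view are kept, not silently dropped).
#' @export
deform_sequence <- function(labels, affine = diag(3),
                            translation = c(0, 0, 0), n_frames = 2L,
                            center = NULL) {
  check_labels(labels)
  if (abs(det(affine)) < 1e-12) stop("affine matrix must be invertible")
  d <- dim(labels)
  if (is.null(center)) center <- (d - 1) / 2
  # destination voxel centers, zero-based, relative to the rotation center
  idx <- seq_len(prod(d))
  dst <- sweep(index_to_coords(idx, d), 2, center)
  frames <- vector("list", n_frames)
  frames[[1]] <- labels
  outside <- vector("list", n_frames)
  outside[[1]] <- integer()
  A_k <- diag(3); t_k <- c(0, 0, 0)
  cents <- label_centroids(labels)
  for (k in seq_len(n_frames - 1L)) {
    A_k <- affine %*% A_k
    t_k <- affine %*% t_k + translation
    src <- t(solve(A_k) %*% (t(dst) - as.vector(t_k))) # inverse map
    src <- sweep(src, 2, center, "+")
    si <- round(src) + 1  # back to one-based array indices
    ok <- si[, 1] >= 1 & si[, 1] <= d[1] & si[, 2] >= 1 & si[, 2] <= d[2] &
      si[, 3] >= 1 & si[, 3] <= d[3]
    out <- array(0L, dim = d)
    lin <- si[ok, 1] + d[1] * (si[ok, 2] - 1) + d[1] * d[2] * (si[ok, 3] - 1)
    out[idx[ok]] <- labels[lin]
    frames[[k + 1L]] <- out
    # flag labels whose transformed centroid falls outside the box
    tc <- t(A_k %*% (t(cents) - center) + as.vector(t_k) + center)
    bad <- which(apply(tc, 1, function(p) any(p < 0 | p > d - 1)))
    outside[[k + 1L]] <- as.integer(rownames(cents))[bad]
  }
  attr(frames, "outside") <- outside
  frames
}

# per-label centroids (zero-based), rows named by label
label_centroids <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(matrix(numeric(), 0, 3))
  co <- index_to_coords(idx, dim(labels))
  lab <- labels[idx]
  out <- cbind(z = as.vector(tapply(co[, 1], lab, mean)),
               y = as.vector(tapply(co[, 2], lab, mean)),
               x = as.vector(tapply(co[, 3], lab, mean)))
  rownames(out) <- names(tapply(co[, 1], lab, mean))
  out
}

#' Four-bubble contact-swap (T1) fixture
#'
#' Builds two label maps of four bubbles arranged around a common center: in
#' the first frame the axial pair (labels 1, 2) shares a film while the
#' equatorial pair (labels 3, 4) does not; in the second frame the roles are
#' exchanged, realizing an elementary T1 event in which exactly one contact is
#' lost and one new contact forms between the two former common neighbors.
#' Optionally the quadruplet is embedded in a packing of static background
#' bubbles.
#'
#' @param swap if \code{FALSE}, the second frame repeats the first (no event).
#' @param sep_close,sep_far half-separations of the close and far pair,
#'   voxels (sep_close < sep_far).
#' @param r_cut assignment radius around the seeds, voxels.
#' @param n_background number of extra static bubbles placed away from the
#'   quadruplet.
#' @param box box shape; enlarged automatically when background bubbles are
#'   requested.
#' @param seed seed for background placement.
#' @param dilation contact criterion passed to \code{\link{get_contacts}}.
#' @return list with \code{labels} (two label arrays), \code{nets} (two
#'   \code{contact_network}s) and \code{truth} (lost pair, new pair,
#'   quadruplet).
#' @export
make_t1_fixture <- function(swap = TRUE, sep_close = 5, sep_far = 8,
                            r_cut = 12, n_background = 0L, box = NULL,
                            seed = 1L, dilation = 1L) {
  stopifnot(sep_close < sep_far)
  if (is.null(box)) box <- if (n_background > 0L) c(96, 96, 96) else c(48, 48, 48)
  ctr <- (box - 1) / 2
  seeds_for <- function(a, b) rbind(
    ctr + c(-a, 0, 0), ctr + c(a, 0, 0),   # labels 1, 2 along z
    ctr + c(0, -b, 0), ctr + c(0, b, 0))   # labels 3, 4 along y
  assign_quad <- function(seeds) {
    lab <- array(0L, dim = box)
    best <- array(Inf, dim = box)
    ax <- lapply(box, function(n) seq_len(n) - 1)
    for (k in 1:4) {
      dz2 <- (ax[[1]] - seeds[k, 1])^2
      dy2 <- (ax[[2]] - seeds[k, 2])^2
      dx2 <- (ax[[3]] - seeds[k, 3])^2
      d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
      take <- d2 <= r_cut^2 & d2 < best
      lab[take] <- k
      best[take] <- d2[take]
    }
    lab
  }
  lab1 <- assign_quad(seeds_for(sep_close, sep_far))
  lab2 <- if (swap) assign_quad(seeds_for(sep_far, sep_close)) else lab1
  if (n_background > 0L) {
    bg <- with_seed(seed, {
      centers <- matrix(NA_real_, 0, 3)
      r_bg <- 5
      guard <- r_cut + sep_far + r_bg + 3
      tries <- 0L
      while (nrow(centers) < n_background && tries < 5000L) {
        tries <- tries + 1L
        cand <- r_bg + 1 + runif(3) * (box - 2 * (r_bg + 1) - 1)
        if (sqrt(sum((cand - ctr)^2)) < guard) next
        if (nrow(centers) &&
            any(sqrt(colSums((t(centers) - cand)^2)) < 2 * r_bg + 1)) next
        centers <- rbind(centers, cand)
      }
      if (nrow(centers) < n_background)
        stop("could only place ", nrow(centers), " of ", n_background,
             " background bubbles")
      rasterize_spheres(centers, rep(r_bg, nrow(centers)), box)
    })
    add_bg <- function(lab) {
      put <- bg > 0L & lab == 0L
      lab[put] <- bg[put] + 4L
      lab
    }
    lab1 <- add_bg(lab1); lab2 <- add_bg(lab2)
  }
  net1 <- get_contacts(lab1, dilation = dilation)
  net2 <- get_contacts(lab2, dilation = dilation)
  truth <- if (swap) list(lost = c(1L, 2L), new = c(3L, 4L), quad = 1:4)
           else list(lost = NULL, new = NULL, quad = 1:4)
  list(labels = list(lab1, lab2), nets = list(net1, net2), truth = truth)
}
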