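# adjacency list (named by label) from a pair table with columns p, q
neighbor_sets <- function(pairs) {
  labs <- sort(unique(c(pairs$p, pairs$q)))
  out <- lapply(labs, function(l)
    sort(unique(c(pairs$q[pairs$p == l], pairs$p[pairs$q == l]))))
  names(out) <- labs
  out
}

#' Extract the bubble contact network
#'
#' Two bubbles are in contact when their regions, each grown by
#' \code{dilation} voxels into the liquid, overlap or become face-adjacent --
#' i.e. when they are separated by a liquid film of at most about
#' \code{2 * dilation} voxels. The film (contact) region of a pair is the
#' two-sided shell of grown voxels at their common interface, labeled by a
#' contact id in the returned contact image; a voxel claimed by several films
#' keeps the smallest contact id.
#'
#' @param labels integer label array.
#' @param dilation growth applied to each region before the adjacency test,
#'   voxels (6-neighbor steps).
#' @return object of class \code{"contact_network"}: \code{pairs} (data frame
#'   contact_id, p, q with p < q), \code{topology} (data frame label, Z plus
#'   a list column \code{neighbors}), and \code{contact_labels} (3D integer
#'   array of film regions).
#' @export
get_contacts <- function(labels, dilation = 1L) {
  check_labels(labels)
  d <- dim(labels)
  grown <- array(cpp_grow_labels(as.integer(labels), d, as.integer(dilation)),
                 dim = d)
  adj <- adjacency_pairs(grown)
  labs <- sort(unique(labels[labels > 0L]))
  if (nrow(adj)) {
    pairs <- data.frame(contact_id = seq_len(nrow(adj)), p = adj$p, q = adj$q)
  } else {
    pairs <- data.frame(contact_id = integer(), p = integer(), q = integer())
  }
  # film image: voxels of the grown map adjacent (6-conn) to a different
  # label; each gets the contact id of its pair (smallest id wins)
  contact_labels <- array(0L, dim = d)
  if (nrow(pairs)) {
    keys <- pair_key(pairs$p, pairs$q)
    shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
    for (s in shifts) {
      nb <- shift_array(grown, s)
      hit <- which(grown > 0L & nb > 0L & nb != grown)
      if (!length(hit)) next
      id <- pairs$contact_id[match(pair_key(grown[hit], nb[hit]), keys)]
      cur <- contact_labels[hit]
      take <- !is.na(id) & (cur == 0L | id < cur)
      contact_labels[hit[take]] <- id[take]
    }
  }
  nbs <- neighbor_sets(pairs)
  topo <- data.frame(label = labs,
                     Z = vapply(as.character(labs), function(l) {
                       nb <- nbs[[l]]
                       if (is.null(nb)) 0L else length(nb)
                     }, integer(1)))
  topo$neighbors <- lapply(as.character(labs), function(l) {
    nb <- nbs[[l]]
    if (is.null(nb)) integer() else nb
  })
  structure(list(pairs = pairs, topology = topo,
                 contact_labels = contact_labels),
            class = "contact_network")
}

# shift an integer array by (dz, dy, dx), padding with 0
shift_array <- function(a, s) {
  d <- dim(a)
  out <- array(0L, dim = d)
  src <- dst <- list()
  for (i in 1:3) {
    if (s[i] >= 0) {
      dst[[i]] <- seq_len(d[i] - s[i]) + s[i]
      src[[i]] <- seq_len(d[i] - s[i])
    } else {
      dst[[i]] <- seq_len(d[i] + s[i])
      src[[i]] <- seq_len(d[i] + s[i]) - s[i]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' @export
print.contact_network <- function(x, ...) {
  cat("Contact network:", nrow(x$topology), "bubbles,",
      nrow(x$pairs), "contacts; mean Z =",
      round(mean(x$topology$Z), 2), "\n")
  invisible(x)
}

#' Geometry of individual films
#'
#' Fits each labeled contact region by an ellipsoid via its second-moment
#' (shape) tensor: the film normal is the eigenvector of the smallest
#' eigenvalue, and the in-plane semi-axes follow the uniform-disc calibration
#' \eqn{a = 2\sqrt{\lambda_1}}, \eqn{b = 2\sqrt{\lambda_2}} from the two
#' largest eigenvalues (a uniform disc of radius r has in-plane second
#' moments r^2/4). The film area is \eqn{A = \pi a b}, assuming a planar
#' film. The normal sign convention is a positive z-component (ties broken
#' by y, then x).
#'
#' @param net contact network from \code{\link{get_contacts}}.
#' @return data frame with one row per contact: contact_id, p, q, centroid
#'   (z, y, x), normal components (n_z, n_y, n_x), semi-axes a >= b, area,
#'   and a \code{degenerate} flag for contacts too small or collinear for a
#'   defined normal.
#' @export
contact_properties <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  cl <- net$contact_labels
  idx <- which(cl > 0L)
  co <- index_to_coords(idx, dim(cl))
  cid <- cl[idx]
  rows <- lapply(seq_len(nrow(net$pairs)), function(k) {
    id <- net$pairs$contact_id[k]
    v <- co[cid == id, , drop = FALSE]
    base <- data.frame(contact_id = id, p = net$pairs$p[k], q = net$pairs$q[k])
    if (nrow(v) < 3L) {
      return(cbind(base, z = NA, y = NA, x = NA, n_z = NA, n_y = NA, n_x = NA,
                   a = NA, b = NA, area = NA, degenerate = TRUE))
    }
    st <- shape_tensor(v)
    e <- eigen(st$S, symmetric = TRUE)  # eigenvalues descending
    if (e$values[2] <= 1e-12) {  # collinear voxels: no defined plane
      return(cbind(base, z = st$centroid[1], y = st$centroid[2],
                   x = st$centroid[3], n_z = NA, n_y = NA, n_x = NA,
                   a = NA, b = NA, area = NA, degenerate = TRUE))
    }
    n <- e$vectors[, 3]
    flip <- n[1] < 0 || (n[1] == 0 && (n[2] < 0 || (n[2] == 0 && n[3] < 0)))
    if (flip) n <- -n
    a <- 2 * sqrt(e$values[1]); b <- 2 * sqrt(e$values[2])
    cbind(base, z = st$centroid[1], y = st$centroid[2], x = st$centroid[3],
          n_z = n[1], n_y = n[2], n_x = n[3], a = a, b = b,
          area = pi * a * b, degenerate = FALSE)
  })
  if (!length(rows))
    return(data.frame(contact_id = integer(), p = integer(), q = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
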