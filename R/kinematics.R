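#' Track bubbles between two consecutive labeled frames
#'
#' Matches bubble centroids of frame t to frame t+1: a candidate match must
#' lie within \code{search_radius} of the predicted position (the frame-t
#' centroid, shifted by the prior displacement when one is supplied) and pass
#' the volume-matching criterion \eqn{|V_{t+1} - V_t| / V_t \le} vol_tol,
#' which excludes segmentation artifacts (split/merged bubbles). Conflicts
#' are resolved by a greedy assignment ordered by ascending match distance
#' (ties by ascending labels), which is stable and near-optimal for small
#' displacements; exact ties in both distance and volume are flagged
#' \code{"ambiguous"} rather than guessed. The matching is one-to-one.
#'
#' @param regions_t,regions_t1 region tables from
#'   \code{\link{region_properties}} for the two frames.
#' @param search_radius candidate search radius, voxels; defaults to the
#'   Sauter radius of frame t.
#' @param vol_tol relative volume tolerance, > 0.
#' @param prior optional matrix (one row per row of \code{regions_t}) of
#'   prior displacements (z, y, x), e.g. sampled from an externally computed
#'   displacement field at the frame-t centroids.
#' @return data frame with one row per frame-t bubble: labels, positions,
#'   displacement (dz, dy, dx), volumes and \code{status}
#'   (\code{"matched"}, \code{"lost"} or \code{"ambiguous"}).
#' @export
track_labels <- function(regions_t, regions_t1, search_radius = NULL,
                         vol_tol = 0.3, prior = NULL) {
  if (!nrow(regions_t) || !nrow(regions_t1)) stop("empty region table")
  if (vol_tol <= 0) stop("vol_tol must be > 0")
  if (is.null(search_radius)) search_radius <- radius_statistics(regions_t)$R32
  if (search_radius <= 0) stop("search_radius must be > 0")
  ct <- as.matrix(regions_t[, c("z", "y", "x")])
  c1 <- as.matrix(regions_t1[, c("z", "y", "x")])
  pred <- if (is.null(prior)) ct else ct + prior
  n_t <- nrow(ct); n_1 <- nrow(c1)
  dm <- sqrt(outer(pred[, 1], c1[, 1], "-")^2 +
             outer(pred[, 2], c1[, 2], "-")^2 +
             outer(pred[, 3], c1[, 3], "-")^2)
  dv <- abs(outer(regions_t$V, regions_t1$V, "-")) / regions_t$V
  admissible <- dm <= search_radius & dv <= vol_tol
  cand <- which(admissible, arr.ind = TRUE)
  status <- rep("lost", n_t)
  match_j <- rep(NA_integer_, n_t)
  if (nrow(cand)) {
    # canonical candidate list sorted by distance, then labels
    cd <- data.frame(i = cand[, 1], j = cand[, 2],
                     d = dm[cand], dv = dv[cand])
    cd <- cd[order(cd$d, regions_t$label[cd$i], regions_t1$label[cd$j]), ]
    used_j <- rep(FALSE, n_1)
    # flag exact ties: same source, equal distance and volume mismatch
    for (k in seq_len(nrow(cd))) {
      i <- cd$i[k]; j <- cd$j[k]
      if (!is.na(match_j[i]) || status[i] == "ambiguous" || used_j[j]) next
      tie <- cd$i == i & abs(cd$d - cd$d[k]) == 0 &
        abs(cd$dv - cd$dv[k]) == 0 & cd$j != j & !used_j[cd$j]
      if (any(tie)) { status[i] <- "ambiguous"; next }
      match_j[i] <- j
      used_j[j] <- TRUE
      status[i] <- "matched"
    }
  }
  disp <- matrix(NA_real_, n_t, 3)
  ok <- !is.na(match_j)
  disp[ok, ] <- c1[match_j[ok], , drop = FALSE] - ct[ok, , drop = FALSE]
  data.frame(
    label_t = regions_t$label,
    label_t1 = ifelse(ok, regions_t1$label[match_j], NA_integer_),
    z_t = ct[, 1], y_t = ct[, 2], x_t = ct[, 3],
    dz = disp[, 1], dy = disp[, 2], dx = disp[, 3],
    V_t = regions_t$V,
    V_t1 = ifelse(ok, regions_t1$V[match_j], NA_real_),
    status = status
  )
}

#' Assemble multi-step trajectories from pairwise tracking
#'
#' Chains pairwise track tables covering consecutive frame pairs into
#' per-bubble trajectories. A chain ends at the first lost or ambiguous
#' link (death); labels of a later frame never reached by a match start a
#' new trajectory (birth).
#'
#' @param track_tables list of track tables from \code{\link{track_labels}},
#'   element k covering frames k -> k+1.
#' @return object of class \code{"trajectory_set"}: a data frame with columns
#'   traj, frame (1-based), label, and position/volume when available.
#' @export
combine_tracking <- function(track_tables) {
  if (!length(track_tables)) stop("no track tables supplied")
  n_frames <- length(track_tables) + 1L
  # forward maps keyed by frame-t label
  rows <- list()
  traj_id <- 0L
  open <- list()  # label in current frame -> traj id
  for (f in seq_len(n_frames - 1L)) {
    tt <- track_tables[[f]]
    nxt <- list()
    for (k in seq_len(nrow(tt))) {
      lab <- tt$label_t[k]
      key <- as.character(lab)
      id <- open[[key]]
      if (is.null(id)) {  # birth at frame f
        traj_id <- traj_id + 1L
        id <- traj_id
        rows[[length(rows) + 1L]] <- data.frame(
          traj = id, frame = f, label = lab,
          z = tt$z_t[k], y = tt$y_t[k], x = tt$x_t[k], V = tt$V_t[k])
      }
      if (tt$status[k] == "matched") {
        lab1 <- tt$label_t1[k]
        rows[[length(rows) + 1L]] <- data.frame(
          traj = id, frame = f + 1L, label = lab1,
          z = tt$z_t[k] + tt$dz[k], y = tt$y_t[k] + tt$dy[k],
          x = tt$x_t[k] + tt$dx[k], V = tt$V_t1[k])
        nxt[[as.character(lab1)]] <- id
      }
    }
    open <- nxt
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$traj, out$frame), ]
  rownames(out) <- NULL
  structure(out, class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  lens <- table(x$traj)
  cat("Trajectory set:", length(lens), "trajectories over",
      max(x$frame), "frames; lengths",
      paste(range(lens), collapse = ".."), "\n")
  invisible(as.data.frame(x))
}

#' Frames over which a group of bubbles is jointly tracked
#'
#' Group tracking (contacts as pairs, T1 events as quadruplets, clusters):
#' the group's chain is the intersection of its members' chains, i.e. the
#' frames where every member exists on its trajectory.
#'
#' @param trajectories a \code{\link{combine_tracking}} result.
#' @param labels member labels identifying the group in \code{frame}.
#' @param frame the frame in which \code{labels} are given (default 1).
#' @return integer vector of frames where all members exist.
#' @export
group_frames <- function(trajectories, labels, frame = 1L) {
  per <- lapply(labels, function(l) {
    id <- trajectories$traj[trajectories$frame == frame &
                              trajectories$label == l]
    if (!length(id)) return(integer())
    sort(trajectories$frame[trajectories$traj == id[1]])
  })
  Reduce(intersect, per)
}
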