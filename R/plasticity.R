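#' Translate contact pairs through a tracking table
#'
#' Maps each contact's pair of frame-t bubble labels into frame-t+1 label
#' space using the pairwise tracking. Pairs with a lost (or ambiguous)
#' member cannot be translated and are flagged, to be excluded from the
#' lost/new-contact bookkeeping.
#'
#' @param pairs_t data frame with columns p, q (frame-t labels).
#' @param tracks track table from \code{\link{track_labels}} for the same
#'   frame pair.
#' @return data frame with the translated labels p, q (canonical p < q) and
#'   a logical \code{translatable} column.
#' @export
translate_pairs <- function(pairs_t, tracks) {
  map <- tracks$label_t1[match(pairs_t$p, tracks$label_t)]
  maq <- tracks$label_t1[match(pairs_t$q, tracks$label_t)]
  ok <- !is.na(map) & !is.na(maq)
  data.frame(p = pmin(map, maq), q = pmax(map, maq), translatable = ok)
}

#' Lost and newly formed contacts between two frames
#'
#' Set difference of unordered contact pairs, both tables expressed in the
#' frame-t+1 label space: lost contacts are translated frame-t pairs absent
#' from frame t+1, new contacts are frame-t+1 pairs absent from the
#' translated table. Untranslatable pairs are excluded.
#'
#' @param pairs_t_translated output of \code{\link{translate_pairs}}.
#' @param pairs_t1 data frame with columns p, q (frame-t+1 labels).
#' @return list with data frames \code{lost} and \code{new} (columns p, q).
#' @export
lost_new <- function(pairs_t_translated, pairs_t1) {
  tr <- pairs_t_translated
  if (!is.null(tr$translatable)) tr <- tr[tr$translatable, , drop = FALSE]
  k_t <- unique(pair_key(tr$p, tr$q))
  k_1 <- unique(pair_key(pairs_t1$p, pairs_t1$q))
  unkey <- function(keys) {
    if (!length(keys)) return(data.frame(p = integer(), q = integer()))
    parts <- strsplit(keys, "_", fixed = TRUE)
    data.frame(p = as.integer(vapply(parts, `[`, "", 1L)),
               q = as.integer(vapply(parts, `[`, "", 2L)))
  }
  list(lost = unkey(setdiff(k_t, k_1)), new = unkey(setdiff(k_1, k_t)))
}

#' Detect elementary T1 events from lost and new contacts
#'
#' An elementary T1 event is a contact swap between four bubbles: the film
#' between a lost pair vanishes and a new film forms between two of their
#' common neighbors. For each lost pair, candidate new pairs are searched
#' among the combinations of common neighbors of the lost pair's members;
#' conversely each new pair is matched back toward the lost set. An event is
#' emitted only when this forward/backward match is bijective -- a lost pair
#' with zero or several agreeing candidates (higher-order rearrangements)
#' is reported separately, not as a T1.
#'
#' All tables must share the frame-t+1 label space (translate frame-t pairs
#' first). Common neighborhood is evaluated, per the \code{neighbors}
#' switch, on the union of the two frames' contact topologies (default: a
#' neighbor counts if present at either end of the transition), or strictly
#' on frame t or frame t+1.
#'
#' @param L,N lost/new pair tables from \code{\link{lost_new}}.
#' @param pairs_t_translated,pairs_t1 full translated frame-t and frame-t+1
#'   pair tables (columns p, q), defining the topologies.
#' @param regions_t1 optional region table of frame t+1 for centroids of the
#'   four bubbles.
#' @param neighbors frame convention for the common-neighbor test.
#' @return data frame of class \code{"t1_table"}: lost pair (l_p, l_q), new
#'   pair (n_p, n_q) and, when regions are given, the four centroids.
#'   Attribute \code{"nonbijective"} lists lost pairs excluded by the
#'   bijectivity requirement.
#' @export
detect_t1 <- function(L, N, pairs_t_translated, pairs_t1,
                      regions_t1 = NULL,
                      neighbors = c("union", "t", "t1")) {
  neighbors <- match.arg(neighbors)
  tr <- pairs_t_translated
  if (!is.null(tr$translatable)) tr <- tr[tr$translatable, , drop = FALSE]
  topo <- switch(neighbors,
    union = rbind(tr[, c("p", "q")], pairs_t1[, c("p", "q")]),
    t = tr[, c("p", "q")],
    t1 = pairs_t1[, c("p", "q")])
  nbs <- neighbor_sets(topo)
  nb_of <- function(l) {
    v <- nbs[[as.character(l)]]
    if (is.null(v)) integer() else v
  }
  pair_rows <- function(df) lapply(seq_len(nrow(df)),
                                   function(k) c(df$p[k], df$q[k]))
  Lp <- pair_rows(L); Np <- pair_rows(N)
  # forward: lost pair -> new pairs within its common neighbors
  common_L <- lapply(Lp, function(pr) intersect(nb_of(pr[1]), nb_of(pr[2])))
  fwd <- lapply(seq_along(Lp), function(i)
    which(vapply(Np, function(npr)
      all(npr %in% common_L[[i]]) && !any(npr %in% Lp[[i]]), logical(1))))
  # backward: new pair -> lost pairs within its common neighbors
  common_N <- lapply(Np, function(pr) intersect(nb_of(pr[1]), nb_of(pr[2])))
  bwd <- lapply(seq_along(Np), function(j)
    which(vapply(Lp, function(lpr)
      all(lpr %in% common_N[[j]]) && !any(lpr %in% Np[[j]]), logical(1))))
  # mutual candidate edges, bijective when unique in both directions
  events <- list(); nonbij <- list()
  for (i in seq_along(Lp)) {
    mutual <- fwd[[i]][vapply(fwd[[i]], function(j) i %in% bwd[[j]],
                              logical(1))]
    if (length(mutual) == 1L) {
      j <- mutual
      back <- bwd[[j]][vapply(bwd[[j]], function(ii) j %in% fwd[[ii]],
                              logical(1))]
      if (length(back) == 1L && back == i) {
        events[[length(events) + 1L]] <-
          data.frame(l_p = Lp[[i]][1], l_q = Lp[[i]][2],
                     n_p = Np[[j]][1], n_q = Np[[j]][2])
        next
      }
    }
    if (length(fwd[[i]]))
      nonbij[[length(nonbij) + 1L]] <-
        data.frame(l_p = Lp[[i]][1], l_q = Lp[[i]][2],
                   n_candidates = length(fwd[[i]]))
  }
  out <- if (length(events)) do.call(rbind, events) else
    data.frame(l_p = integer(), l_q = integer(),
               n_p = integer(), n_q = integer())
  if (!is.null(regions_t1) && nrow(out)) {
    get_cent <- function(lab, ax)
      regions_t1[[ax]][match(lab, regions_t1$label)]
    for (who in c("l_p", "l_q", "n_p", "n_q"))
      for (ax in c("z", "y", "x"))
        out[[paste0(who, "_", ax)]] <- get_cent(out[[who]], ax)
  }
  attr(out, "nonbijective") <-
    if (length(nonbij)) do.call(rbind, nonbij) else
      data.frame(l_p = integer(), l_q = integer(), n_candidates = integer())
  class(out) <- c("t1_table", "data.frame")
  out
}

#' Orientation angle of a bubble-pair bar in the cylindrical shear plane
#'
#' Projects the segment joining two bubble centroids into the vertical
#' cylindrical plane (z, r-theta) at the bar midpoint and returns its angle
#' from the horizontal (azimuthal) direction, in degrees within [0, 180).
#' Used to characterize the orientation of lost and new contacts of T1
#' events in a cylindrical flow geometry (e.g. a rotating plate-plate cell
#' sheared about the vertical axis).
#'
#' @param c1,c2 centroids (z, y, x) of the two bubbles (distinct).
#' @param origin point on the cylinder axis; the axis is along z.
#' @return angle in degrees, in [0, 180).
#' @export
pair_angle <- function(c1, c2, origin = c(0, 0, 0)) {
  d <- c2 - c1
  if (all(d == 0)) stop("coincident centroids: angle undefined")
  mid <- (c1 + c2) / 2 - origin
  r <- sqrt(mid[2]^2 + mid[3]^2)
  if (r == 0) stop("bar midpoint on the cylinder axis: azimuth undefined")
  e_theta <- c(0, mid[3], -mid[2]) / r  # azimuthal direction at midpoint
  h <- sum(d * e_theta)  # horizontal (r-theta) component
  v <- d[1]              # vertical (z) component
  a <- atan2(v, h) * 180 / pi
  a %% 180
}
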