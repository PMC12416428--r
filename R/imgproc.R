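#' Remove low-frequency background from a grayscale volume
#'
#' Estimates the background as a Gaussian low-pass of the image at a scale
#' larger than the bubble diameter, subtracts it and restores the global mean,
#' flattening slow intensity drifts (beam profile, detector vignetting) while
#' leaving the gas/liquid contrast untouched. A spatially constant input is
#' returned unchanged.
#'
#' @param vol 3D numeric array.
#' @param scale standard deviation of the low-pass estimate, voxels; should be
#'   larger than the bubble diameter.
#' @return 3D numeric array of the same shape.
#' @export
remove_background <- function(vol, scale) {
  check_vol(vol)
  if (scale <= 0) stop("scale must be > 0")
  bg <- array(cpp_gauss3(as.double(vol), dim(vol), scale), dim = dim(vol))
  vol - bg + mean(bg)
}

#' Segment the liquid and gas phases of a tomogram
#'
#' Thresholds the intensity histogram, by default with Otsu's method computed
#' over the valid voxels only. The half-open convention is fixed: a voxel
#' with intensity >= the threshold belongs to the high class.
#'
#' @param vol 3D numeric array.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold threshold value when \code{method = "fixed"}.
#' @param liquid which side of the threshold is liquid; \code{"high"}
#'   (default, liquid brighter than gas, as in absorption tomograms of
#'   aqueous foams) or \code{"low"}.
#' @param mask optional binary validity array (1 = inside the sample); voxels
#'   outside are excluded from threshold estimation and flagged invalid.
#' @return binary array, 1 = liquid, with the mask (if any) attached as
#'   attribute \code{"mask"} and the threshold as attribute
#'   \code{"threshold"}.
#' @export
segment_phase <- function(vol, method = c("otsu", "fixed"), threshold = NULL,
                          liquid = c("high", "low"), mask = NULL) {
  check_vol(vol)
  method <- match.arg(method)
  liquid <- match.arg(liquid)
  vals <- if (is.null(mask)) as.vector(vol) else vol[mask > 0]
  thr <- switch(method,
    otsu = otsu_threshold(vals),
    fixed = {
      if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
      threshold
    })
  high <- vol >= thr
  phase <- array(0L, dim = dim(vol))
  phase[if (liquid == "high") high else !high] <- 1L
  attr(phase, "threshold") <- thr
  if (!is.null(mask)) attr(phase, "mask") <- mask
  phase
}

#' Remove small speckles from a phase map
#'
#' Flips connected components of either phase smaller than a size threshold,
#' suppressing segmentation speckle from noise. The package's connectivity
#' convention applies: gas components are 26-connected, liquid components
#' 6-connected. Liquid specks are removed first, then gas specks.
#'
#' @param phase binary array, 1 = liquid.
#' @param min_size_liquid,min_size_gas minimum surviving component size,
#'   voxels (0 disables the pass).
#' @return binary array.
#' @export
remove_speckles <- function(phase, min_size_liquid = 0L, min_size_gas = 0L) {
  check_phase(phase)
  if (min_size_liquid < 0 || min_size_gas < 0) stop("sizes must be >= 0")
  d <- dim(phase)
  flip_small <- function(ph, value, connectivity, min_size) {
    if (min_size <= 0) return(ph)
    cc <- cpp_label3d(ph == value, d, connectivity)
    sizes <- tabulate(cc[cc > 0L])
    small <- which(sizes < min_size)
    if (length(small)) ph[cc %in% small] <- 1L - value
    ph
  }
  phase <- flip_small(phase, 1L, 6L, min_size_liquid)
  phase <- flip_small(phase, 0L, 26L, min_size_gas)
  atts <- attributes(phase)
  phase <- array(as.integer(phase), dim = d)
  attr(phase, "mask") <- atts$mask
  phase
}

#' Watershed bubble segmentation of a phase map
#'
#' Splits the gas phase into individual bubbles by a marker-controlled
#' watershed of the negated Euclidean distance transform of the gas phase.
#' Markers are the h-maxima of the distance map (suppressing maxima shallower
#' than \code{h}, computed by grayscale reconstruction), so each marker seeds
#' one bubble. Every gas voxel is assigned to exactly one label; the flooding
#' order is deterministic (highest distance first, FIFO among ties, markers
#' seeded in ascending voxel order), so ties go to the lowest label.
#' Regions smaller than \code{min_volume} are merged into their largest
#' face-adjacent neighbor.
#'
#' @param phase binary array, 1 = liquid; the gas phase must be non-empty.
#' @param h h-maxima depth in distance units (voxels); larger values merge
#'   shallow distance maxima and prevent over-segmentation.
#' @param min_volume minimum bubble volume, voxels.
#' @return integer label array (0 = liquid).
#' @export
segment_bubbles <- function(phase, h = 2, min_volume = 0L) {
  check_phase(phase)
  d <- dim(phase)
  gas <- phase == 0L
  if (!any(gas)) stop("empty gas phase: nothing to segment")
  edt <- sqrt(cpp_edt_sq(gas, d, TRUE))
  marker <- pmax(edt - h, 0)
  recon <- cpp_reconstruct_dilation(as.double(marker), as.double(edt), d, 26L)
  maxima <- cpp_regional_maxima(recon, gas, d, 26L)
  markers <- cpp_label3d(maxima, d, 26L)
  labels <- cpp_watershed(edt, markers, gas, d, 6L)
  labels <- array(labels, dim = d)
  if (min_volume > 0L) labels <- merge_small_regions(labels, min_volume)
  labels
}

# merge regions below min_volume into their largest face-adjacent neighbor;
# isolated small regions (no neighbor) are kept
merge_small_regions <- function(labels, min_volume) {
  keep_isolated <- integer()
  repeat {
    sizes <- tabulate(labels[labels > 0L])
    present <- which(sizes > 0L)
    small <- setdiff(present[sizes[present] < min_volume], keep_isolated)
    if (!length(small)) break
    adj <- adjacency_pairs(labels)
    lab <- small[which.min(sizes[small])]
    nb <- c(adj$q[adj$p == lab], adj$p[adj$q == lab])
    if (!length(nb)) { keep_isolated <- c(keep_isolated, lab); next }
    target <- nb[which.max(sizes[nb])]
    labels[labels == lab] <- target
  }
  labels
}

#' Remove bubbles touching the image border or mask boundary
#'
#' Bubbles clipped by the field of view (or by the sample mask) have biased
#' volume, shape and contact measurements; this sets them to background.
#'
#' @param labels integer label array.
#' @param mask optional binary validity array; labels touching a voxel
#'   outside the mask are removed as well.
#' @return integer label array with surviving labels unchanged.
#' @export
remove_edge_bubbles <- function(labels, mask = NULL) {
  check_labels(labels)
  d <- dim(labels)
  edge <- unique(c(labels[1, , ], labels[d[1], , ],
                   labels[, 1, ], labels[, d[2], ],
                   labels[, , 1], labels[, , d[3]]))
  if (!is.null(mask)) {
    out <- mask == 0
    touch <- function(a, b) unique(a[b])  # labels a adjacent to outside b
    hit <- c(
      touch(labels[-d[1], , ], out[-1, , ]), touch(labels[-1, , ], out[-d[1], , ]),
      touch(labels[, -d[2], ], out[, -1, ]), touch(labels[, -1, ], out[, -d[2], ]),
      touch(labels[, , -d[3]], out[, , -1]), touch(labels[, , -1], out[, , -d[3]]),
      labels[out])
    edge <- unique(c(edge, hit))
  }
  edge <- setdiff(edge, 0L)
  if (length(edge)) labels[labels %in% edge] <- 0L
  labels
}
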