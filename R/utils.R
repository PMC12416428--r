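# internal helpers shared across modules

# validate a 3D numeric/logical array
check_vol <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(name, " must be a 3D array with dim (nz, ny, nx)", call. = FALSE)
  x
}

check_phase <- function(x) {
  check_vol(x, "phase map")
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1)))
    stop("phase map must be binary (0 = gas, 1 = liquid)", call. = FALSE)
  x
}

check_labels <- function(x) {
  check_vol(x, "label map")
  if (any(x < 0)) stop("label map must be non-negative", call. = FALSE)
  x
}

# run expr with a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# zero-based (z, y, x) coordinates of a linear index into dim d
index_to_coords <- function(idx, d) {
  idx0 <- idx - 1L
  z <- idx0 %% d[1]
  r <- idx0 %/% d[1]
  y <- r %% d[2]
  x <- r %/% d[2]
  cbind(z = z, y = y, x = x)
}

# face-adjacent label pairs (p < q, both > 0) with shared face counts
adjacency_pairs <- function(labels) {
  d <- dim(labels)
  collect <- function(a, b) {
    keep <- a != b & a > 0L & b > 0L
    if (!any(keep)) return(NULL)
    cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  }
  ps <- rbind(
    collect(labels[-d[1], , , drop = FALSE], labels[-1, , , drop = FALSE]),
    collect(labels[, -d[2], , drop = FALSE], labels[, -1, , drop = FALSE]),
    collect(labels[, , -d[3], drop = FALSE], labels[, , -1, drop = FALSE])
  )
  if (is.null(ps) || nrow(ps) == 0L)
    return(data.frame(p = integer(), q = integer(), count = integer()))
  key <- paste(ps[, 1], ps[, 2], sep = "_")
  tab <- table(key)
  parts <- strsplit(names(tab), "_", fixed = TRUE)
  out <- data.frame(
    p = as.integer(vapply(parts, `[`, "", 1L)),
    q = as.integer(vapply(parts, `[`, "", 2L)),
    count = as.integer(tab)
  )
  out[order(out$p, out$q), , drop = FALSE]
}

# canonical unordered pair keys
pair_key <- function(p, q) paste(pmin(p, q), pmax(p, q), sep = "_")

# symmetric 3x3 tensor flattened in the documented component order
tensor_to_row <- function(Tm, prefix) {
  v <- c(Tm[1, 1], Tm[1, 2], Tm[1, 3], Tm[2, 2], Tm[2, 3], Tm[3, 3])
  names(v) <- paste0(prefix, "_", c("zz", "zy", "zx", "yy", "yx", "xx"))
  v
}

row_to_tensor <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes the between-class variance of a two-class split of the intensity
#' histogram. Used as the default phase-segmentation threshold.
#'
#' @param x numeric vector of intensities (e.g. the voxels of a tomogram,
#'   restricted to a validity mask).
#' @param nbins number of histogram bins.
#' @return the threshold value; voxels with intensity >= the threshold fall in
#'   the high class.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate single-valued histogram: no Otsu threshold exists",
         call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  br[k + 1L]  # boundary between the two classes; >= threshold is high
}
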