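# shared fixtures built in code: rasterized solids, analytic oracles

# rasterized ellipsoid with semi-axes (a, b, c) along (z, y, x), centered in
# an N^3 box; returns an integer array (1 inside)
raster_ellipsoid <- function(a, b, c, N) {
  ax <- seq_len(N) - 1 - (N - 1) / 2
  d2 <- outer(outer((ax / a)^2, (ax / b)^2, "+"), (ax / c)^2, "+")
  array(as.integer(d2 <= 1), dim = c(N, N, N))
}

raster_ball <- function(R, N) raster_ellipsoid(R, R, R, N)

# zero-based voxel coordinates of the nonzero voxels of a 3D array
nz_coords <- function(a) which(a != 0, arr.ind = TRUE) - 1

# independent surface-integral oracle for the interfacial stress of an
# axis-aligned ellipsoid: dense quadrature over the analytic parametrization
# of the smooth surface, same integrand Gamma/V * (n n^T - Id/3) dA.
# Semi-axes (a, b, c) along (z, y, x).
ellipsoid_stress_oracle <- function(a, b, c, Gamma = 1, n = 400) {
  th <- (seq_len(n) - 0.5) * pi / n
  ph <- (seq_len(2 * n) - 0.5) * pi / n
  Tm <- matrix(0, 3, 3)
  A <- 0
  for (i in seq_along(th)) {
    st <- sin(th[i]); ct <- cos(th[i])
    z <- a * st * cos(ph); y <- b * st * sin(ph); x <- c * ct
    nz <- z / a^2; ny <- y / b^2; nx <- x / c^2
    nn <- sqrt(nz^2 + ny^2 + nx^2)
    dA <- a * b * c * nn * st * (pi / n)^2
    nv <- rbind(nz, ny, nx) / rep(nn, each = 3)
    Tm <- Tm + (nv * rep(dA, each = 3)) %*% t(nv)
    A <- A + sum(dA)
  }
  V <- 4 / 3 * pi * a * b * c
  Gamma / V * (Tm - diag(3) * A / 3)
}

# best bijective label matching between two label maps by overlap; returns
# per-matched-pair Jaccard indices
match_jaccard <- function(lab_a, lab_b) {
  ia <- which(lab_a > 0L | lab_b > 0L)
  key <- paste(lab_a[ia], lab_b[ia])
  ov <- table(key)
  parts <- strsplit(names(ov), " ", fixed = TRUE)
  df <- data.frame(a = as.integer(vapply(parts, `[`, "", 1)),
                   b = as.integer(vapply(parts, `[`, "", 2)),
                   n = as.integer(ov))
  df <- df[df$a > 0 & df$b > 0, ]
  df <- df[order(-df$n), ]
  va <- tabulate(lab_a[lab_a > 0L])
  vb <- tabulate(lab_b[lab_b > 0L])
  used_a <- used_b <- integer()
  jac <- numeric()
  for (k in seq_len(nrow(df))) {
    if (df$a[k] %in% used_a || df$b[k] %in% used_b) next
    used_a <- c(used_a, df$a[k]); used_b <- c(used_b, df$b[k])
    jac <- c(jac, df$n[k] / (va[df$a[k]] + vb[df$b[k]] - df$n[k]))
  }
  jac
}

# standard 27-bubble monodisperse jittered-grid packing used across tests
grid_packing_27 <- function(seed = 5L, film = 1, radius = 8) {
  make_packing(foam_spec(box_shape = c(64, 64, 64), n_bubbles = 27,
                         radius = radius, film_thickness = film,
                         seed = seed),
               arrangement = "grid")
}

# rebuild a symmetric 3x3 tensor from the flattened component order
# (zz, zy, zx, yy, yx, xx) used in the CSV tables
row_to_tensor_test <- function(v) {
  v <- as.numeric(v)
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

# two independent contact swaps in disjoint label spaces: union of two T1
# fixture pair tables with the second copy's labels offset
double_swap_tables <- function(offset = 10L) {
  fx <- make_t1_fixture()
  p1 <- fx$nets[[1]]$pairs; p2 <- fx$nets[[2]]$pairs
  shift <- function(df) data.frame(contact_id = df$contact_id + 100L,
                                   p = df$p + offset, q = df$q + offset)
  list(pairs_t = rbind(p1, shift(p1)), pairs_t1 = rbind(p2, shift(p2)),
       quads = list(1:4, 1:4 + offset))
}

# canonical unordered pair keys (test-side twin of the package internal)
pair_key_test <- function(p, q) paste(pmin(p, q), pmax(p, q), sep = "_")
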