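test_that("a single rasterized bubble has the nominal sphere volume", {
  pk <- make_packing(foam_spec(box_shape = c(32, 32, 32), n_bubbles = 1,
                               radius = 8, seed = 3))
  expect_equal(length(unique(pk$labels[pk$labels > 0])), 1L)
  V_ideal <- 4 * pi * 8^3 / 3
  expect_lt(abs(pk$truth$volumes[1] - V_ideal) / V_ideal, 0.02)
  # phase is the complement of the labels
  expect_true(all((pk$phase == 1L) == (pk$labels == 0L)))
})

test_that("a jittered 3x3x3 grid packing has 27 bubbles and a full contact grid", {
  pk <- grid_packing_27()
  expect_setequal(unique(pk$labels[pk$labels > 0]), 1:27)
  # simple-cubic grid: 3 * 2 * 3 * 3 = 54 nearest-neighbor pairs
  expect_gte(nrow(pk$truth$adjacency), 54L)
  expect_true(all(pk$truth$adjacency[, "p"] < pk$truth$adjacency[, "q"]))
})

test_that("ground truth is exactly consistent with the label map", {
  pk <- grid_packing_27(seed = 11L)
  vols <- tabulate(pk$labels[pk$labels > 0L])
  expect_identical(as.integer(pk$truth$volumes), as.integer(vols))
  cent_err <- sqrt(rowSums((pk$truth$centroids -
                              pk$truth$designed_centers)^2))
  expect_lt(max(cent_err), 0.5)
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- foam_spec(box_shape = c(48, 48, 48), n_bubbles = 8,
                  radius_law = "lognormal", meanlog = log(6), sdlog = 0.15,
                  film_thickness = 1, seed = 42L)
  a <- make_packing(sp)
  b <- make_packing(sp)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
})

test_that("impossible packings fail with the achievable count", {
  sp <- foam_spec(box_shape = c(32, 32, 32), n_bubbles = 30, radius = 7,
                  seed = 1L)
  expect_error(make_packing(sp, max_tries = 20L), "bubbles fit|does not fit")
})

test_that("noiseless rendering is two-valued and thresholds back exactly", {
  pk <- make_packing(foam_spec(box_shape = c(32, 32, 32), n_bubbles = 2,
                               radius = 6, seed = 7))
  g <- render_tomogram(pk$phase, gas_level = 50, liquid_level = 200,
                       blur_sigma = 0, noise_sigma = 0)
  expect_setequal(unique(as.vector(g)), c(50, 200))
  ph <- segment_phase(g, method = "otsu")
  expect_identical(as.integer(ph), as.integer(pk$phase))
})

test_that("blurred noisy rendering still recovers the liquid fraction", {
  pk <- grid_packing_27()
  contrast <- 150
  g <- render_tomogram(pk$phase, 50, 200, blur_sigma = 1,
                       noise_sigma = 0.05 * contrast, seed = 2L)
  ph <- segment_phase(g)
  phi_true <- mean(pk$phase == 1L)
  expect_lt(abs(liquid_fraction(ph) - phi_true), 0.02)
})

test_that("pure translation shifts every centroid by the drift", {
  pk <- grid_packing_27()
  fr <- deform_sequence(pk$labels, translation = c(2, 0, 0), n_frames = 2)
  expect_identical(fr[[1]], pk$labels)
  r0 <- region_properties(fr[[1]])
  r1 <- region_properties(fr[[2]])
  d <- as.matrix(r1[match(r0$label, r1$label), c("z", "y", "x")]) -
    as.matrix(r0[, c("z", "y", "x")])
  expect_true(all(abs(d[, 1] - 2) < 0.5))
  expect_true(all(abs(d[, 2:3]) < 0.5))
})

test_that("a volume-preserving stretch conserves bubble volumes", {
  # bubbles large enough that nearest-neighbor rasterization jitter is small,
  # placed so the stretch keeps them inside the box
  N <- 80
  lab <- array(0L, dim = c(N, N, N))
  co <- which(array(TRUE, dim(lab)), arr.ind = TRUE) - 1
  centers <- rbind(c(39.5, 39.5, 39.5), c(39.2, 20.3, 58.1),
                   c(40.6, 59.4, 21.7))
  for (k in 1:3)
    lab[sqrt(rowSums(sweep(co, 2, centers[k, ])^2)) <= 16] <- k
  A <- diag(c(1.2, 1.2^-0.5, 1.2^-0.5))
  fr <- deform_sequence(lab, affine = A, n_frames = 2)
  v0 <- tabulate(fr[[1]][fr[[1]] > 0])
  v1 <- tabulate(fr[[2]][fr[[2]] > 0])
  expect_true(all(abs(v1 - v0) / v0 < 0.02))
})

test_that("identity deformation repeats the frame and flags nothing", {
  pk <- make_packing(foam_spec(box_shape = c(32, 32, 32), n_bubbles = 3,
                               radius = 5, seed = 13L))
  fr <- deform_sequence(pk$labels, n_frames = 3)
  expect_identical(fr[[2]], pk$labels)
  expect_identical(fr[[3]], pk$labels)
  expect_length(attr(fr, "outside")[[3]], 0L)
})

test_that("bubbles advected out of the box are flagged, not dropped silently", {
  pk <- make_packing(foam_spec(box_shape = c(32, 32, 32), n_bubbles = 1,
                               radius = 5, seed = 1L))
  fr <- deform_sequence(pk$labels, translation = c(30, 0, 0), n_frames = 2)
  expect_identical(attr(fr, "outside")[[2]], 1L)
})

test_that("the T1 fixture realizes exactly one contact swap", {
  fx <- make_t1_fixture()
  tr <- data.frame(p = fx$nets[[1]]$pairs$p, q = fx$nets[[1]]$pairs$q,
                   translatable = TRUE)
  ln <- lost_new(tr, fx$nets[[2]]$pairs)
  expect_identical(nrow(ln$lost), 1L)
  expect_identical(nrow(ln$new), 1L)
  expect_setequal(c(ln$lost$p, ln$lost$q), fx$truth$lost)
  expect_setequal(c(ln$new$p, ln$new$q), fx$truth$new)
  expect_length(unique(c(ln$lost$p, ln$lost$q, ln$new$p, ln$new$q)), 4L)
})

test_that("the swap-disabled fixture loses and gains nothing", {
  fx <- make_t1_fixture(swap = FALSE)
  tr <- data.frame(p = fx$nets[[1]]$pairs$p, q = fx$nets[[1]]$pairs$q,
                   translatable = TRUE)
  ln <- lost_new(tr, fx$nets[[2]]$pairs)
  expect_identical(nrow(ln$lost), 0L)
  expect_identical(nrow(ln$new), 0L)
})
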