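test_that("pair translation maps labels through the tracking", {
  pairs <- data.frame(p = c(1L, 2L), q = c(2L, 3L))
  id_tracks <- data.frame(label_t = 1:3, label_t1 = 1:3,
                          status = "matched")
  tr <- translate_pairs(pairs, id_tracks)
  expect_identical(tr$p, pairs$p)
  expect_identical(tr$q, pairs$q)
  expect_true(all(tr$translatable))

  perm <- c(3L, 1L, 2L)
  perm_tracks <- data.frame(label_t = 1:3, label_t1 = perm,
                            status = "matched")
  tr2 <- translate_pairs(pairs, perm_tracks)
  expect_setequal(pair_key_test(tr2$p, tr2$q),
                  pair_key_test(perm[pairs$p], perm[pairs$q]))
})

test_that("pairs with a lost member are excluded from the bookkeeping", {
  pairs <- data.frame(p = c(1L, 2L), q = c(2L, 3L))
  tracks <- data.frame(label_t = 1:3, label_t1 = c(1L, NA, 3L),
                       status = c("matched", "lost", "matched"))
  tr <- translate_pairs(pairs, tracks)
  expect_identical(tr$translatable, c(FALSE, FALSE))
  ln <- lost_new(tr, data.frame(p = 1L, q = 3L))
  expect_identical(nrow(ln$lost), 0L)
  expect_identical(nrow(ln$new), 1L)  # (1,3) appears without a precursor
})

test_that("lost/new sets reduce to set differences of unordered pairs", {
  same <- data.frame(p = c(1L, 2L), q = c(3L, 4L), translatable = TRUE)
  ln <- lost_new(same, same[, c("p", "q")])
  expect_identical(nrow(ln$lost), 0L)
  expect_identical(nrow(ln$new), 0L)
  set.seed(99)
  for (rep in 1:20) {
    a <- unique(t(apply(matrix(sample(1:9, 20, TRUE), ncol = 2), 1,
                        sort)))
    b <- unique(t(apply(matrix(sample(1:9, 20, TRUE), ncol = 2), 1,
                        sort)))
    a <- a[a[, 1] != a[, 2], , drop = FALSE]
    b <- b[b[, 1] != b[, 2], , drop = FALSE]
    ln <- lost_new(data.frame(p = a[, 1], q = a[, 2], translatable = TRUE),
                   data.frame(p = b[, 1], q = b[, 2]))
    ka <- pair_key_test(a[, 1], a[, 2]); kb <- pair_key_test(b[, 1], b[, 2])
    expect_setequal(pair_key_test(ln$lost$p, ln$lost$q), setdiff(ka, kb))
    expect_setequal(pair_key_test(ln$new$p, ln$new$q), setdiff(kb, ka))
  }
})

test_that("the four-bubble fixture yields exactly one bijective T1", {
  fx <- make_t1_fixture()
  tr <- data.frame(p = fx$nets[[1]]$pairs$p, q = fx$nets[[1]]$pairs$q,
                   translatable = TRUE)
  ln <- lost_new(tr, fx$nets[[2]]$pairs)
  t1 <- detect_t1(ln$lost, ln$new, tr, fx$nets[[2]]$pairs)
  expect_identical(nrow(t1), 1L)
  expect_setequal(c(t1$l_p, t1$l_q), fx$truth$lost)
  expect_setequal(c(t1$n_p, t1$n_q), fx$truth$new)
  expect_length(unique(c(t1$l_p, t1$l_q, t1$n_p, t1$n_q)), 4L)
  expect_identical(nrow(attr(t1, "nonbijective")), 0L)
})

test_that("an unchanged foam produces no T1 events", {
  fx <- make_t1_fixture(swap = FALSE)
  tr <- data.frame(p = fx$nets[[1]]$pairs$p, q = fx$nets[[1]]$pairs$q,
                   translatable = TRUE)
  ln <- lost_new(tr, fx$nets[[2]]$pairs)
  t1 <- detect_t1(ln$lost, ln$new, tr, fx$nets[[2]]$pairs)
  expect_identical(nrow(t1), 0L)
})

test_that("two independent simultaneous swaps give two disjoint T1s", {
  ds <- double_swap_tables()
  tr <- data.frame(p = ds$pairs_t$p, q = ds$pairs_t$q, translatable = TRUE)
  ln <- lost_new(tr, ds$pairs_t1)
  t1 <- detect_t1(ln$lost, ln$new, tr, ds$pairs_t1)
  expect_identical(nrow(t1), 2L)
  quads <- lapply(seq_len(2), function(i)
    c(t1$l_p[i], t1$l_q[i], t1$n_p[i], t1$n_q[i]))
  expect_length(intersect(quads[[1]], quads[[2]]), 0L)
  expect_setequal(sort(unlist(quads)), sort(unlist(ds$quads)))
})

test_that("T1 detection survives embedding in a 50-bubble packing", {
  fx <- make_t1_fixture(n_background = 46L, seed = 8L)
  # identity tracking: labels are static across the two frames
  labs <- sort(unique(fx$labels[[1]][fx$labels[[1]] > 0]))
  tracks <- data.frame(label_t = labs, label_t1 = labs, status = "matched")
  tr <- translate_pairs(fx$nets[[1]]$pairs, tracks)
  ln <- lost_new(tr, fx$nets[[2]]$pairs)
  t1 <- detect_t1(ln$lost, ln$new, tr, fx$nets[[2]]$pairs)
  expect_identical(nrow(t1), 1L)
  expect_setequal(c(t1$l_p, t1$l_q, t1$n_p, t1$n_q), 1:4)
})

test_that("time reversal exchanges lost and new but keeps the event", {
  fx <- make_t1_fixture()
  p1 <- fx$nets[[1]]$pairs; p2 <- fx$nets[[2]]$pairs
  fwd_tr <- data.frame(p = p1$p, q = p1$q, translatable = TRUE)
  ln_f <- lost_new(fwd_tr, p2)
  t1_f <- detect_t1(ln_f$lost, ln_f$new, fwd_tr, p2)
  rev_tr <- data.frame(p = p2$p, q = p2$q, translatable = TRUE)
  ln_r <- lost_new(rev_tr, p1)
  t1_r <- detect_t1(ln_r$lost, ln_r$new, rev_tr, p1)
  expect_identical(nrow(t1_r), 1L)
  expect_setequal(c(t1_r$l_p, t1_r$l_q), c(t1_f$n_p, t1_f$n_q))
  expect_setequal(c(t1_r$n_p, t1_r$n_q), c(t1_f$l_p, t1_f$l_q))
})

test_that("emitted T1s satisfy the common-neighbor condition post hoc", {
  fx <- make_t1_fixture()
  tr <- data.frame(p = fx$nets[[1]]$pairs$p, q = fx$nets[[1]]$pairs$q,
                   translatable = TRUE)
  ln <- lost_new(tr, fx$nets[[2]]$pairs)
  t1 <- detect_t1(ln$lost, ln$new, tr, fx$nets[[2]]$pairs)
  topo <- rbind(tr[, c("p", "q")], fx$nets[[2]]$pairs[, c("p", "q")])
  nb <- function(l) unique(c(topo$q[topo$p == l], topo$p[topo$q == l]))
  common <- intersect(nb(t1$l_p), nb(t1$l_q))
  expect_true(all(c(t1$n_p, t1$n_q) %in% common))
})

test_that("bar angles follow the cylindrical-plane convention", {
  org <- c(0, 0, 0)
  # bar along the azimuthal direction at (y = 0, x = 20): e_theta ~ +y
  expect_equal(pair_angle(c(5, -1, 20), c(5, 1, 20), org), 0)
  # equal vertical and horizontal components: 45 degrees
  expect_equal(pair_angle(c(0, -1, 20), c(2, 1, 20), org), 45)
  # vertical bar: 90 degrees
  expect_equal(pair_angle(c(-3, 0, 20), c(3, 0, 20), org), 90)
  expect_error(pair_angle(c(1, 2, 3), c(1, 2, 3), org), "coincident")
})

test_that("isotropic bar orientations give a flat angle histogram", {
  set.seed(11)
  n <- 10000
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  mid <- cbind(0, 0, 50)  # all bars near the same azimuth
  a <- vapply(seq_len(n), function(i)
    pair_angle(mid[1, ] - v[i, ] / 2, mid[1, ] + v[i, ] / 2,
               origin = c(0, 0, 0)), numeric(1))
  h <- hist(a, breaks = seq(0, 180, by = 20), plot = FALSE)$counts
  expected_n <- n / length(h)
  expect_true(all(abs(h - expected_n) < 5 * sqrt(expected_n)))
})
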