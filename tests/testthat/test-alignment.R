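test_that("transition weights follow the stated closed form", {
  # equal distances cancel
  expect_equal(transition_weight(c(0, 0), c(100, 0), c(0, 100), 150), 0)
  # on-feature origin with the other feature far away approaches 1
  expect_equal(transition_weight(c(0, 0), c(0, 0), c(1e9, 0), 150), 1)
  # d_i = 1, d_j = 2 in units of sigma -> exp(-1) - exp(-2)
  w <- transition_weight(c(0, 0), c(150, 0), c(300, 0), 150)
  expect_equal(w, exp(-1) - exp(-2), tolerance = 1e-12)
  expect_equal(w, 0.2325442, tolerance = 1e-6)
  # antisymmetry under swapping i and j
  set.seed(21)
  for (k in 1:20) {
    g <- runif(2, 0, 5000); fi <- runif(2, 0, 5000); fj <- runif(2, 0, 5000)
    expect_equal(transition_weight(g, fi, fj, 150),
                 -transition_weight(g, fj, fi, 150), tolerance = 1e-12)
  }
})

test_that("literal-mode alignment equals the nearest-feature oracle", {
  g <- generate_grid(2, default_layout)
  set.seed(31)
  n <- 1000
  gx <- runif(n, 0, 5759); gy <- runif(n, 0, 1199)
  gaze <- make_gaze(gx, gy)
  al <- align_track(gaze, g, alignment_params(mode = "literal"))
  oracle <- vapply(seq_len(n), function(i) nearest_feature(gx[i], gy[i], g),
                   integer(1))
  expect_identical(al$feature_id, oracle)
})

test_that("gaze resting exactly on a feature aligns to it in both modes", {
  g <- tiny_grid()
  k <- 4L
  gaze <- make_gaze(rep(g$gx[g$feature_id == k], 10),
                    rep(g$gy[g$feature_id == k], 10))
  for (mode in c("literal", "proximity")) {
    al <- align_track(gaze, g, alignment_params(mode = mode))
    expect_true(all(al$feature_id[-1] == k))
  }
})

test_that("proximity mode suppresses single-sample noise excursions", {
  g <- tiny_grid()
  a <- g[1, ]; b <- g[2, ]   # 200 px apart
  gx <- rep(a$gx, 40); gy <- rep(a$gy, 40)
  gx[20] <- (a$gx + b$gx) / 2 + 20  # excursion just past halfway to b
  al <- align_track(make_gaze(gx, gy), g,
                    alignment_params(mode = "proximity", lambda = 0.9))
  expect_true(all(al$feature_id[5:40] == a$feature_id))
  # the same excursion flips the literal (nearest-feature) alignment
  al2 <- align_track(make_gaze(gx, gy), g,
                     alignment_params(mode = "literal"))
  expect_equal(al2$feature_id[20], b$feature_id)
})

test_that("proximity-mode hysteresis grows monotonically with lambda", {
  g <- tiny_grid()
  a <- g[1, ]; b <- g[2, ]
  gx <- c(rep(a$gx, 30), rep(b$gx, 30))
  gy <- c(rep(a$gy, 30), rep(b$gy, 30))
  gaze <- make_gaze(gx, gy)
  switch_delay <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(lam) {
    al <- align_track(gaze, g, alignment_params(lambda = lam))
    which(al$feature_id[31:60] == b$feature_id)[1]
  }, numeric(1))
  expect_true(all(diff(switch_delay) >= 0))
  expect_gt(switch_delay[5], switch_delay[1])
})

test_that("state weights stay in (0, 1] and invalid samples hold the state", {
  g <- tiny_grid()
  set.seed(41)
  gx <- runif(50, min(g$gx), max(g$gx)); gy <- runif(50, min(g$gy), max(g$gy))
  gaze <- make_gaze(gx, gy)
  gaze$valid[c(1, 2, 25, 26)] <- FALSE
  for (mode in c("literal", "proximity")) {
    al <- align_track(gaze, g, alignment_params(mode = mode))
    expect_true(all(al$v_max > 0 & al$v_max <= 1))
    expect_equal(al$feature_id[25], al$feature_id[24])
    expect_equal(al$feature_id[26], al$feature_id[24])
  }
  expect_error(align_track(gaze[0, ], g), "empty")
})

test_that("saccade extraction segments and merges as specified", {
  g <- tiny_grid()
  a <- g[1, ]; b <- g[2, ]
  # constant aligned track: no saccades
  al <- align_track(make_gaze(rep(a$gx, 20), rep(a$gy, 20)), g,
                    alignment_params(mode = "literal"))
  expect_equal(nrow(extract_saccades(al, default_layout)), 0L)

  # one jump between neighbouring features: amplitude 200 px
  al <- align_track(make_gaze(c(rep(a$gx, 20), rep(b$gx, 20)),
                              c(rep(a$gy, 20), rep(b$gy, 20))), g,
                    alignment_params(mode = "literal"))
  sc <- extract_saccades(al, default_layout)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$amplitude_px, 200)
  expect_equal(sc$from_feature, a$feature_id)
  expect_equal(sc$to_feature, b$feature_id)
  expect_equal(sc$amplitude_deg,
               angular_distance_global(default_layout, a$gx, a$gy,
                                       b$gx, b$gy))

  # two collinear jumps A -> B -> C with a short intervening dwell merge
  cfeat <- g[3, ]  # third feature in the same row, collinear with a, b
  gx <- c(rep(a$gx, 20), rep(b$gx, 3), rep(cfeat$gx, 20))
  gy <- c(rep(a$gy, 20), rep(b$gy, 3), rep(cfeat$gy, 20))
  al <- align_track(make_gaze(gx, gy), g, alignment_params(mode = "literal"))
  sc <- extract_saccades(al, default_layout, merge_angle_deg = 45,
                         merge_gap_s = 0.1)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$from_feature, a$feature_id)
  expect_equal(sc$to_feature, cfeat$feature_id)
  expect_equal(sc$amplitude_deg,
               angular_distance_global(default_layout, a$gx, a$gy,
                                       cfeat$gx, cfeat$gy))
  # with a longer dwell on B the saccades stay separate
  gx <- c(rep(a$gx, 20), rep(b$gx, 30), rep(cfeat$gx, 20))
  gy <- c(rep(a$gy, 20), rep(b$gy, 30), rep(cfeat$gy, 20))
  al <- align_track(make_gaze(gx, gy), g, alignment_params(mode = "literal"))
  expect_equal(nrow(extract_saccades(al, default_layout)), 2L)
})

test_that("amplitudes are invariant to noise that never changes alignment", {
  g <- tiny_grid()
  a <- g[1, ]; b <- g[5, ]
  set.seed(51)
  noise <- rnorm(40, 0, 10)  # well below half the 200 px spacing
  gx_clean <- c(rep(a$gx, 20), rep(b$gx, 20))
  gy <- c(rep(a$gy, 20), rep(b$gy, 20))
  al1 <- align_track(make_gaze(gx_clean, gy), g,
                     alignment_params(mode = "literal"))
  al2 <- align_track(make_gaze(gx_clean + noise, gy), g,
                     alignment_params(mode = "literal"))
  expect_identical(al1$feature_id, al2$feature_id)
  s1 <- extract_saccades(al1, default_layout)
  s2 <- extract_saccades(al2, default_layout)
  expect_equal(s1$amplitude_px, s2$amplitude_px)
  expect_equal(s1$amplitude_deg, s2$amplitude_deg)
})
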