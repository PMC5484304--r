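test_that("phantom generation is deterministic given the spec", {
  spec <- phantom_spec(grid = c(24L, 24L), n_channels = 4L,
                       semi_axes = c(45, 40), coil_radius = 80)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$b1, b$b1)
  expect_identical(a$e, b$e)
  expect_identical(a$normalization, b$normalization)
})

test_that("channel fields are rotated copies for a symmetric circular load", {
  # 4 channels on a centered circular phantom with no inclusion and no
  # jitter: channel j's |B1| must equal channel 1's rotated by 90 degrees.
  spec <- phantom_spec(grid = c(32L, 32L), n_channels = 4L,
                       semi_axes = c(60, 60), coil_radius = 100,
                       asym_load = FALSE, channel_jitter = 0)
  ph <- generate_phantom(spec)
  rot90 <- function(m) t(m)[, nrow(m):1]  # counter-clockwise quarter turn
  m1 <- abs(ph$b1[, , 1L])
  for (j in 2:4) {
    mj <- abs(ph$b1[, , j])
    mr <- m1
    for (k in seq_len(j - 1L)) mr <- rot90(mr)
    expect_lt(max(abs(mj - mr)), 1e-6 * max(m1))
  }
})

test_that("quadrature weights follow the birdcage phase pattern", {
  w8 <- quadrature_weights(8)
  expect_equal(w8[1L], 1 + 0i)
  expect_equal(w8[3L], 0 + 1i, tolerance = 1e-15)
  expect_equal(w8, exp(1i * pi * (0:7) / 4), tolerance = 1e-15)
  expect_true(all(abs(Mod(w8) - 1) < 1e-15))
  expect_true(all(abs(Mod(quadrature_weights(5)) - 1) < 1e-15))
  expect_error(quadrature_weights(0), "domain error")
})

test_that("quadrature excitation is normalized to unit mean |B1+| in the ROI", {
  fx <- small_fixture()
  ph <- fx$phantom
  wq <- quadrature_weights(dim(ph$b1)[3L])
  qsum <- abs(ptxshim:::combine_channels(ph$b1, wq))
  expect_equal(mean(qsum[ph$masks$roi]), 1, tolerance = 1e-12)
  # Idempotent renormalization.
  ph2 <- normalize_phantom(ph)
  expect_lt(max(abs(ph2$b1 - ph$b1)), 1e-12)
  expect_equal(ph2$normalization, ph$normalization, tolerance = 1e-12)
})

test_that("masks are consistent and fields vanish outside the body", {
  fx <- small_fixture()
  ph <- fx$phantom
  expect_false(any(ph$masks$roi & ph$masks$blood))
  expect_true(all(ph$masks$roi | !ph$masks$roi))
  out <- !ph$masks$body
  for (j in seq_len(dim(ph$b1)[3L]))
    expect_true(all(ph$b1[, , j][out] == 0))
  expect_true(all(abs(ph$e[, , 3L, 1L][out]) == 0))
  expect_error(generate_phantom(phantom_spec(grid = c(8L, 8L))), "spec error")
})

test_that("single-channel single-voxel Q reduces to sigma |E|^2 / (2 rho)", {
  # Hand-built phantom: one channel, uniform fields, mass target below one
  # voxel slab so no averaging happens.
  rows <- 16L; cols <- 16L
  body <- matrix(TRUE, rows, cols)
  e <- array(0i, dim = c(rows, cols, 3L, 1L))
  e[, , 1L, 1L] <- 3 + 4i
  e[, , 3L, 1L] <- 1 - 2i
  ph <- structure(list(
    b1 = array(1 + 0i, dim = c(rows, cols, 1L)), e = e,
    masks = list(body = body, roi = body, blood = body & FALSE),
    conductivity = matrix(0.6, rows, cols),
    density = matrix(1050, rows, cols), voxel_size = 5,
    normalization = 1,
    spec = phantom_spec(grid = c(rows, cols), n_channels = 1L)),
    class = "phantom_model")
  vox_mass_g <- 1050 * (5e-3)^3 * 1000
  q <- build_q_matrices(ph, mass_target = vox_mass_g * 0.9)
  expected <- 0.6 * (abs(3 + 4i)^2 + abs(1 - 2i)^2) / (2 * 1050)
  expect_equal(Re(q$local[1L, 1L, 1L]), expected, tolerance = 1e-12)
  expect_equal(Re(q$wholebody[1L, 1L]), expected, tolerance = 1e-12)
  expect_error(build_q_matrices(ph, mass_target = 1e6), "averaging error")
})

test_that("whole-body Q equals the mass-weighted mean of per-voxel Q", {
  fx <- small_fixture()
  ph <- fx$phantom
  q <- fx$qset
  # Direct summation oracle over in-body voxels.
  d <- dim(ph$e); nv <- d[1L] * d[2L]; nch <- d[4L]
  emat <- matrix(ph$e, nv * 3L, nch)
  body <- as.vector(ph$masks$body)
  vol <- (ph$voxel_size * 1e-3)^3
  num <- matrix(0i, nch, nch)
  den <- 0
  for (v in which(body)) {
    Ev <- matrix(emat[c(v, v + nv, v + 2L * nv), ], 3L, nch)
    Pv <- ph$conductivity[v] * vol / 2 * (Conj(t(Ev)) %*% Ev)
    num <- num + Pv
    den <- den + ph$density[v] * vol
  }
  expect_equal(max(abs(q$wholebody - num / den)), 0, tolerance = 1e-10)
})

test_that("Q-matrices are Hermitian and PSD", {
  fx <- small_fixture()
  q <- fx$qset
  nq <- dim(q$local)[1L]
  idx <- unique(round(seq(1L, nq, length.out = 40L)))
  for (i in idx) {
    Qi <- q$local[i, , ]
    expect_lt(max(abs(Qi - Conj(t(Qi)))), 1e-12 * max(abs(Qi)))
    ev <- eigen(Qi, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
  ev <- eigen(q$wholebody, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * max(ev))
})

test_that("scaling the fields by c scales every Q by c^2", {
  fx <- small_fixture()
  ph <- fx$phantom
  ph2 <- ph
  ph2$e <- ph$e * 3
  ph2$b1 <- ph$b1 * 3
  q1 <- build_q_matrices(ph, mass_target = 5)
  q2 <- build_q_matrices(ph2, mass_target = 5)
  expect_equal(q2$local, q1$local * 9, tolerance = 1e-12)
  expect_equal(q2$wholebody, q1$wholebody * 9, tolerance = 1e-12)
})

test_that("emulated measurements carry the blood-excluded ROI and exact maps", {
  fx <- small_fixture()
  ph <- fx$phantom
  S0 <- emulate_b1_measurement(ph, noise_sd = 0)
  roi_mask <- ph$masks$roi & !ph$masks$blood
  expect_identical(S0$roi, which(roi_mask))
  d <- dim(ph$b1)
  ref <- matrix(ph$b1, d[1L] * d[2L], d[3L])[S0$roi, ]
  expect_identical(S0$s, ref)
  expect_error(emulate_b1_measurement(ph, noise_sd = -1), "domain error")
})

test_that("map correlation degrades monotonically with noise level", {
  fx <- small_fixture()
  ph <- fx$phantom
  clean <- as.vector(abs(ph$b1))
  sds <- c(0.02, 0.1, 0.5)
  cors <- vapply(sds, function(sd) {
    mean(vapply(1:5, function(seed) {
      S <- emulate_b1_measurement(ph, noise_sd = sd, seed = seed)
      stats::cor(abs(as.vector(S$maps)), clean)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("quadrature SAR hotspot sits off-center for the default load", {
  fx <- default_fixture()
  cal <- calibrate(fx$S, p_max = 4.6)
  sm <- sar_map(quadrature_weights(8), fx$qset, cal, 0.15)
  # Center of mass of the top-decile SAR voxels, in voxel units from center.
  thr <- stats::quantile(sm$sar, 0.9)
  hot <- sm$voxel[sm$sar >= thr]
  rc <- arrayInd(hot, fx$qset$grid)
  ctr <- (fx$qset$grid + 1) / 2
  offset <- sqrt(mean(rc[, 1L] - ctr[1L])^2 + mean(rc[, 2L] - ctr[2L])^2)
  expect_gt(offset, 2)
})
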