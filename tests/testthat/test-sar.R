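test_that("calibration averages the quadrature field over the ROI", {
  # Single channel with unit sensitivity: quad mean is exactly 1.
  S1 <- channel_sensitivities(matrix(1 + 0i, 20, 1))
  cal <- calibrate(S1, p_max = 4.6)
  expect_equal(cal$b1_achieved, 4.6, tolerance = 1e-15)
  cal2 <- calibrate(S1, p_max = 9.2)
  expect_equal(cal2$b1_achieved, 2 * cal$b1_achieved, tolerance = 1e-15)
  expect_error(calibrate(channel_sensitivities(matrix(0i, 0, 1)),
                         p_max = 1), "calibration error")
  # On the normalized phantom, b1_achieved equals p_max.
  fx <- small_fixture()
  cal3 <- calibrate(fx$S, p_max = 4.616)
  expect_equal(cal3$b1_achieved, 4.616, tolerance = 1e-10)
})

test_that("SAR evaluation is quadratic in the shim and linear in duty cycle", {
  fx <- small_fixture()
  cal <- calibrate(fx$S, p_max = 4.6)
  nch <- dim(fx$qset$local)[2L]
  expect_equal(sar(rep(0i, nch), fx$qset, cal, 0.2)$local_max, 0)
  set.seed(7)
  w <- complex(real = rnorm(nch), imaginary = rnorm(nch))
  s1 <- sar(w, fx$qset, cal, 0.1)
  s2 <- sar(w, fx$qset, cal, 0.2)
  expect_equal(s2$local_max, 2 * s1$local_max, tolerance = 1e-12)
  expect_equal(s2$wholebody, 2 * s1$wholebody, tolerance = 1e-12)
  expect_error(sar(rep(1 + 0i, nch + 1L), fx$qset, cal, 0.1), "shape error")
})

test_that("local SAR scales with the square of the target flip angle", {
  fx <- small_fixture()
  pulse <- rf_pulse(preset = "gaussian", tau = 1.2)
  timing <- sequence_timing(min_tr(1.2))
  D <- duty_cycle(pulse, timing)
  wq <- quadrature_weights(fx$S$n_channels)
  s_by_theta <- function(th) {
    cal <- calibrate(fx$S, p_max = peak_amp_for_flip(th, pulse))
    sar(wq, fx$qset, cal, D)
  }
  a <- s_by_theta(pi / 6)
  b <- s_by_theta(pi / 3)
  expect_equal(b$local_max / a$local_max, 4, tolerance = 1e-9)
  expect_equal(b$wholebody / a$wholebody, 4, tolerance = 1e-9)
})

test_that("the SAR map maximum matches the scalar evaluation", {
  fx <- small_fixture()
  cal <- calibrate(fx$S, p_max = 4.6)
  set.seed(11)
  nch <- fx$S$n_channels
  w <- complex(real = rnorm(nch), imaginary = rnorm(nch))
  m <- sar_map(w, fx$qset, cal, 0.15)
  s <- sar(w, fx$qset, cal, 0.15)
  expect_equal(max(m$sar), s$local_max, tolerance = 1e-12)
  expect_equal(m$voxel[which.max(m$sar)], s$argmax)
  expect_true(all(sar_map(rep(0i, nch), fx$qset, cal, 0.15)$sar == 0))
})

test_that("quadratic forms on stored Q-matrices are real and nonnegative", {
  fx <- small_fixture()
  qfl <- ptxshim:::flatten_qset(fx$qset$local)
  nch <- dim(fx$qset$local)[2L]
  set.seed(3)
  for (i in 1:200) {
    w <- complex(real = rnorm(nch), imaginary = rnorm(nch))
    vals_c <- qfl %*% as.vector(outer(Conj(w), w))
    expect_lt(max(abs(Im(vals_c))), 1e-10 * max(abs(vals_c), 1e-30))
    expect_gte(min(Re(vals_c)), -1e-10 * max(Re(vals_c)))
  }
})

test_that("VOP compression never underestimates the full-set maximum", {
  fx <- small_fixture()
  qfl <- ptxshim:::flatten_qset(fx$qset$local)
  nch <- dim(fx$qset$local)[2L]
  set.seed(5)
  n <- 2000L
  W <- matrix(complex(real = rnorm(n * nch), imaginary = rnorm(n * nch)),
              n, nch)
  WW <- t(vapply(seq_len(n),
                 function(i) as.vector(outer(Conj(W[i, ]), W[i, ])),
                 complex(nch * nch)))
  true_max <- apply(Re(WW %*% t(qfl)), 1L, max)
  for (eps in c(0, 0.01, 0.05)) {
    v <- compress_vops(fx$qset, eps)
    vfl <- ptxshim:::flatten_qset(v$matrices)
    vop_max <- apply(Re(WW %*% t(vfl)), 1L, max)
    expect_true(all(vop_max >= true_max * (1 - 1e-12)))
    # Mean-dominating Z gives a relative overestimation bound.
    expect_true(all(vop_max <= true_max * (1 + eps + 1e-12)))
  }
})

test_that("lossless compression reproduces the exact maximum", {
  fx <- small_fixture()
  v0 <- compress_vops(fx$qset, 0)
  qfl <- ptxshim:::flatten_qset(fx$qset$local)
  vfl <- ptxshim:::flatten_qset(v0$matrices)
  set.seed(9)
  nch <- fx$S$n_channels
  for (i in 1:100) {
    w <- complex(real = rnorm(nch), imaginary = rnorm(nch))
    ww <- as.vector(outer(Conj(w), w))
    expect_equal(max(Re(vfl %*% ww)), max(Re(qfl %*% ww)),
                 tolerance = 1e-12)
  }
})

test_that("compression count shrinks as the overestimation bound loosens", {
  fx <- small_fixture()
  n1 <- dim(compress_vops(fx$qset, 0.01)$matrices)[1L]
  n3 <- dim(compress_vops(fx$qset, 0.03)$matrices)[1L]
  n10 <- dim(compress_vops(fx$qset, 0.10)$matrices)[1L]
  expect_lte(n3, n1)
  expect_lte(n10, n3)
  expect_lte(n1, dim(fx$qset$local)[1L])
  expect_error(compress_vops(fx$qset, -0.1), "domain error")
})

test_that("duplicate matrices collapse to a single VOP", {
  set.seed(13)
  M <- random_psd(4)
  qarr <- array(0i, dim = c(2L, 4L, 4L))
  qarr[1L, , ] <- M
  qarr[2L, , ] <- M
  qset <- structure(list(local = qarr, wholebody = M, voxel = 1:2,
                         grid = c(2L, 1L), mass_target = 10),
                    class = "qmatrix_set")
  v <- compress_vops(qset, 0)
  expect_identical(dim(v$matrices)[1L], 1L)
  expect_identical(v$provenance, 1L)
})
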