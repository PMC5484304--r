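# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# The default study phantom with Q-matrices, VOPs and measured maps.
default_fixture <- function() {
  cached("default", {
    ph <- generate_phantom(phantom_spec())
    qset <- build_q_matrices(ph)
    list(phantom = ph, qset = qset,
         vops = compress_vops(qset, 0.03),
         S = emulate_b1_measurement(ph))
  })
}

# A small phantom for cheap I/O and solver tests.
small_fixture <- function() {
  cached("small", {
    ph <- generate_phantom(phantom_spec(grid = c(24L, 24L), n_channels = 4L,
                                        semi_axes = c(45, 40),
                                        coil_radius = 80))
    qset <- build_q_matrices(ph, mass_target = 5)
    list(phantom = ph, qset = qset,
         vops = compress_vops(qset, 0.02),
         S = emulate_b1_measurement(ph))
  })
}

# Random Hermitian PSD matrix (mixed rank).
random_psd <- function(n, rank = n) {
  G <- matrix(complex(real = stats::rnorm(n * rank),
                      imaginary = stats::rnorm(n * rank)), n, rank)
  M <- G %*% Conj(t(G)) / rank
  (M + Conj(t(M))) / 2
}

# Random 2-channel, 12-voxel shimming instance with binding caps.
# Returns the sensitivity object, a constraint set, and the pieces needed by
# the exhaustive polar-grid oracle.
random_instance <- function(seed, theta0 = pi / 4) {
  set.seed(seed)
  nv <- 12L; nch <- 2L
  s <- matrix(complex(real = stats::rnorm(nv * nch, mean = 0.5, sd = 0.4),
                      imaginary = stats::rnorm(nv * nch, sd = 0.4)),
              nv, nch)
  S <- channel_sensitivities(s)
  qloc <- array(0i, dim = c(3L, nch, nch))
  for (i in 1:3) qloc[i, , ] <- random_psd(nch, rank = sample(1:2, 1))
  qset <- structure(list(local = qloc, wholebody = random_psd(nch),
                         voxel = 1:3, grid = c(3L, 1L), mass_target = 10),
                    class = "qmatrix_set")
  vops <- compress_vops(qset, 0)
  pulse <- rf_pulse(preset = "gaussian", tau = 1.2)
  timing <- sequence_timing(min_tr(1.2))
  cal <- calibrate(S, p_max = peak_amp_for_flip(theta0, pulse))
  # Tight SAR cap plus a modest amplitude cap so constraints bind.
  wq <- quadrature_weights(nch)
  qf0 <- max(vapply(1:3, function(i)
    Re(drop(Conj(wq) %*% qloc[i, , ] %*% wq)), numeric(1)))
  limits <- hardware_limits(
    p_peak = (2.2 * cal$p_max)^2 * 2.5, p_av = 1e6,
    lsar_max = 0.8 * qf0 * cal$b1_achieved^2 *
      duty_cycle(pulse, timing),
    wbsar_max = 1e6)
  cons <- build_constraints(pulse, timing, limits, cal, vops, theta0)
  list(S = S, cons = cons, theta0 = theta0, qset = qset)
}

# Exhaustive polar-grid oracle for the 2-channel inner problems. The global
# phase is gauge-fixed (channel 1 real, nonnegative), which leaves both
# objectives and all constraints unchanged. Returns the minimum magnitude-MSE
# cost and minimum squared-bias over the feasible grid.
grid_oracle <- function(inst, n_amp = 201L, n_ph = 201L) {
  cons <- inst$cons; S <- inst$S; theta0 <- inst$theta0
  amp_cap <- min(cons$amp_peak_cap, cons$amp_avg_cap)
  a1 <- seq(0, amp_cap, length.out = n_amp)
  a2 <- seq(0, amp_cap, length.out = n_amp)
  ph2 <- seq(0, 2 * pi, length.out = n_ph + 1L)[-(n_ph + 1L)]
  w2 <- as.vector(outer(a2, exp(1i * ph2)))  # n_amp*n_ph grid
  st <- theta0 * S$s
  g1 <- st[, 1L]; g2 <- st[, 2L]
  nv <- length(g1)
  F2 <- outer(g2, w2)  # nv x n_grid
  mats <- cons$vops$matrices
  nq <- dim(mats)[1L]
  caps <- c(rep(cons$sar_local_cap, nq), cons$sar_wb_cap)
  qs <- c(lapply(seq_len(nq), function(i) mats[i, , ]),
          list(cons$vops$wholebody))
  best_mse <- Inf; best_bias <- Inf
  for (i in seq_along(a1)) {
    f <- F2 + a1[i] * g1
    flip <- abs(f)
    feas <- rep(TRUE, length(w2))
    for (k in seq_along(qs)) {
      Q <- qs[[k]]
      qf <- a1[i]^2 * Re(Q[1L, 1L]) + abs(w2)^2 * Re(Q[2L, 2L]) +
        2 * a1[i] * Re(Q[1L, 2L] * w2)
      feas <- feas & (qf <= caps[k])
    }
    if (!any(feas)) next
    mse <- colSums((flip - theta0)^2)
    bias2 <- (colMeans(flip) - theta0)^2
    best_mse <- min(best_mse, min(mse[feas]))
    best_bias <- min(best_bias, min(bias2[feas]))
  }
  list(mse = best_mse, bias = best_bias)
}

# Heavy end-to-end runs shared by the acceptance blocks.
default_runs <- function() {
  cached("runs", {
    fx <- default_fixture()
    pulse <- rf_pulse(preset = "gaussian", tau = 1.2)
    cmp <- compare_modes(fx$S, fx$qset, hardware_limits(), pulse,
                         modes = c("quadrature", "mse"))
    # Generous per-channel power so the local SAR limit is what binds.
    generous <- optimize_sequence(
      fx$S, fx$qset, hardware_limits(p_peak = 1e4, p_av = 1e3), pulse,
      mode = "mse")
    sweep <- lapply(c(30, 45, 60, 75) * pi / 180, function(th) {
      list(quad = optimize_sequence(fx$S, fx$vops, hardware_limits(), pulse,
                                    mode = "quadrature", theta0 = th),
           mse = optimize_sequence(fx$S, fx$vops, hardware_limits(), pulse,
                                   mode = "mse", theta0 = th))
    })
    list(cmp = cmp, generous = generous, sweep = sweep)
  })
}
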