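test_that("constraint caps reproduce the hardware arithmetic", {
  fx <- small_fixture()
  pulse <- rf_pulse(preset = "gaussian", tau = 1.2)
  timing <- sequence_timing(min_tr(1.2))
  theta0 <- pi / 4
  cal <- calibrate(fx$S, p_max = peak_amp_for_flip(theta0, pulse))
  cons <- build_constraints(pulse, timing, hardware_limits(), cal, fx$vops,
                            theta0)
  # 1 kW peak at A = 2.5 W/uT^2 caps the driven field at 20 uT.
  expect_equal(cons$amp_peak_cap * cal$p_max, 20, tolerance = 1e-10)
  expect_equal(cons$amp_avg_cap * cal$p_max,
               sqrt(100 / (2.5 * cons$provenance$Delta)), tolerance = 1e-10)
  expect_true(all(unlist(cons[c("amp_peak_cap", "amp_avg_cap",
                                "sar_local_cap", "sar_wb_cap")]) > 0))

  # Doubling TR at fixed tau doubles the allowed quadratic form.
  t2 <- sequence_timing(2 * timing$tr)
  cons2 <- build_constraints(pulse, t2, hardware_limits(), cal, fx$vops,
                             theta0)
  expect_equal(cons2$sar_local_cap, 2 * cons$sar_local_cap,
               tolerance = 1e-12)
  expect_equal(cons2$sar_wb_cap, 2 * cons$sar_wb_cap, tolerance = 1e-12)
  expect_error(build_constraints(pulse, sequence_timing(-1), # nolint
                                 hardware_limits(), cal, fx$vops, theta0),
               "timing error")
})

test_that("a single uniform channel recovers the exact scalar shim", {
  theta0 <- pi / 4
  S <- channel_sensitivities(matrix(1 + 0i, 12, 1))
  qset <- structure(list(local = array(0.01 + 0i, dim = c(1L, 1L, 1L)),
                         wholebody = matrix(0.005 + 0i, 1L, 1L),
                         voxel = 1L, grid = c(1L, 1L), mass_target = 10),
                    class = "qmatrix_set")
  vops <- compress_vops(qset, 0)
  pulse <- rf_pulse(preset = "gaussian", tau = 1.2)
  timing <- sequence_timing(min_tr(1.2))
  cal <- calibrate(S, p_max = peak_amp_for_flip(theta0, pulse))
  cons <- build_constraints(pulse, timing,
                            hardware_limits(p_peak = 1e7, p_av = 1e7,
                                            lsar_max = 1e7, wbsar_max = 1e7),
                            cal, vops, theta0)
  sol <- solve_mse(S, cons, theta0)
  expect_equal(Mod(sol$w), 1, tolerance = 1e-8)
  expect_lt(sol$objective, 1e-12)
  expect_equal(sol$bias_pct, 0, tolerance = 1e-8)
})

test_that("variable exchange never increases the magnitude cost", {
  for (seed in 1:6) {
    inst <- random_instance(seed)
    sol <- solve_mse(inst$S, inst$cons, inst$theta0)
    tr <- sol$trace
    if (length(tr) > 1L)
      expect_true(all(diff(tr) <= 1e-8 * pmax(tr[-length(tr)], 1e-12)))
  }
})

test_that("inner solutions match the exhaustive polar-grid oracle", {
  # Five seeded instances here; the acceptance suite runs twenty.
  for (seed in 1:5) {
    inst <- random_instance(seed)
    oracle <- grid_oracle(inst, n_amp = 81L, n_ph = 81L)
    mse <- solve_mse(inst$S, inst$cons, inst$theta0)
    mb <- solve_min_bias(inst$S, inst$cons, inst$theta0)
    floor_ <- 1e-6 * nrow(inst$S$s) * inst$theta0^2
    expect_lte(mse$objective, oracle$mse * 1.01 + floor_)
    expect_lte(mb$objective, oracle$bias * 1.01 + floor_)
  }
})

test_that("returned solutions satisfy every constraint on the full Q set", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    for (solver in list(solve_mse, solve_min_bias)) {
      sol <- solver(inst$S, inst$cons, inst$theta0)
      m <- ptxshim:::constraint_margins(sol$w, inst$cons,
                                        qset_full = inst$qset)
      expect_true(all(m <= 1 + 1e-6))
    }
  }
})

test_that("relaxing any cap never increases the optimal cost", {
  inst <- random_instance(3)
  base <- solve_mse(inst$S, inst$cons, inst$theta0)$objective
  for (fld in c("amp_peak_cap", "amp_avg_cap", "sar_local_cap",
                "sar_wb_cap")) {
    cons2 <- inst$cons
    cons2[[fld]] <- cons2[[fld]] * 4
    relaxed <- solve_mse(inst$S, cons2, inst$theta0)$objective
    expect_lte(relaxed, base * (1 + 1e-6) + 1e-12)
  }
})

test_that("the MSE optimum beats the feasible scaled-quadrature point", {
  for (seed in c(2, 4, 6)) {
    inst <- random_instance(seed)
    mse <- solve_mse(inst$S, inst$cons, inst$theta0)
    quad <- solve_quadrature(inst$S, inst$cons, inst$theta0)
    quad_cost <- sum((quad$flip_map - inst$theta0)^2)
    expect_lte(mse$objective, quad_cost * (1 + 1e-6))
  }
})

test_that("quadrature closed form agrees with a bisection oracle", {
  for (seed in 1:6) {
    inst <- random_instance(seed)
    sol <- solve_quadrature(inst$S, inst$cons, inst$theta0)
    wq <- quadrature_weights(inst$S$n_channels)
    margin <- function(d)
      max(ptxshim:::constraint_margins(d * wq, inst$cons))
    # Largest feasible d by bisection, then the zero-bias target.
    d_hi <- 1
    while (margin(d_hi) < 1) d_hi <- d_hi * 2
    lo <- 0; hi <- d_hi
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (margin(mid) <= 1) lo <- mid else hi <- mid
    }
    d_target <- 1 / mean(abs(inst$S$s %*% wq))
    expect_equal(sol$d, min(lo, d_target), tolerance = 1e-6)
    if (sol$d < d_target * (1 - 1e-9)) {
      expect_lt(sol$bias_pct, 0)
      expect_gt(length(sol$active), 0L)
    } else {
      expect_equal(sol$bias_pct, 0, tolerance = 1e-9)
    }
  }
})

test_that("min-bias reaches exact zero bias when no cap binds", {
  inst <- random_instance(8)
  cons <- inst$cons
  cons$amp_peak_cap <- cons$amp_avg_cap <- 1e4
  cons$sar_local_cap <- cons$sar_wb_cap <- 1e8
  sol <- solve_min_bias(inst$S, cons, inst$theta0)
  expect_lt(abs(sol$bias_pct), 1e-6)
})

test_that("cap-bound min-bias reports a shortfall and an active cap", {
  inst <- random_instance(9)
  sol <- solve_min_bias(inst$S, inst$cons, inst$theta0)
  if (length(sol$active) > 0L) {
    expect_lt(mean(sol$flip_map), inst$theta0)
  }
  # Whatever the caps, the mean never overshoots past the zero-bias target
  # by more than solver tolerance.
  expect_lt(sol$bias_pct, 1e-6)
})

test_that("a poisoned cap yields a typed infeasible result, not an error", {
  inst <- random_instance(1)
  cons <- inst$cons
  cons$sar_local_cap <- -1
  sol <- solve_mse(inst$S, cons, inst$theta0)
  expect_identical(sol$status, "infeasible")
  sol2 <- solve_min_bias(inst$S, cons, inst$theta0)
  expect_identical(sol2$status, "infeasible")
})

test_that("flip metrics compute bias and population coefficient of variation", {
  m <- flip_metrics(rep(0.7854, 50), 0.7854)
  expect_equal(unname(m), c(0, 0), tolerance = 1e-12)
  m2 <- flip_metrics(c(1, 3), 2)
  expect_equal(m2[["cov"]], 0.5, tolerance = 1e-12)
  m3 <- flip_metrics(rep(42.75, 10), 45)
  expect_equal(m3[["bias_pct"]], -5, tolerance = 1e-12)
  expect_error(flip_metrics(numeric(0), 1), "empty ROI")
  expect_error(flip_metrics(c(-1, 1), 1), "undefined-cov")
})
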