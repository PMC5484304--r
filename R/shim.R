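#' Hardware and safety limits
#'
#' Per-channel peak and average forward power, RF chain gain, and the IEC
#' normal-mode SAR limits.
#'
#' @param p_peak Per-channel peak forward power (W); default 1000.
#' @param p_av Per-channel average power (W); default 100.
#' @param a RF chain gain A (W/uT^2); default 2.5.
#' @param lsar_max Maximum local 10 g SAR (W/kg); default 10.
#' @param wbsar_max Maximum whole-body SAR (W/kg); default 2.
#' @return Object of class `hardware_limits`.
#' @export
hardware_limits <- function(p_peak = 1000, p_av = 100, a = 2.5,
                            lsar_max = 10, wbsar_max = 2) {
  v <- c(p_peak = p_peak, p_av = p_av, a = a, lsar_max = lsar_max,
         wbsar_max = wbsar_max)
  if (any(v <= 0)) stop(sprintf("config error: %s must be positive",
                                names(v)[which(v <= 0)[1L]]))
  structure(as.list(v), class = "hardware_limits")
}

#' Assemble the shim constraint set at a given pulse duration and TR
#'
#' All four constraint families expressed as bounds on the shim vector, at
#' the operating point `(tau, TR)`:
#' per-channel peak power  `|w_j| <= sqrt(P_peak/A) / p_max`,
#' per-channel average power `|w_j| <= sqrt(P_av/(A*Delta)) / p_max`,
#' local SAR `max_i Re(w* Q_i w) <= lSAR_max / kappa` and whole-body SAR
#' `Re(w* Q_wb w) <= wbSAR_max / kappa`, where
#' `kappa = quad_mean^2 * theta0^2 / gamma^2 * (delta2/delta1^2) / (tau*TR)`
#' converts a quadratic form on the normalized Q-matrices into W/kg. The caps
#' must be rebuilt whenever `tau` or TR changes.
#'
#' @param pulse An [rf_pulse()] at the operating pulse duration.
#' @param timing A [sequence_timing()] (its `tr` is the operating TR).
#' @param limits A [hardware_limits()].
#' @param cal A `sar_calibration` (supplies `quad_mean`).
#' @param vops A `vop_set` (working SAR set; carries the whole-body matrix).
#' @param theta0 Target flip angle (rad).
#' @param gamma Gyromagnetic ratio (rad s^-1 uT^-1).
#' @return Object of class `constraint_set` with scalar caps
#'   `amp_peak_cap`, `amp_avg_cap`, `sar_local_cap`, `sar_wb_cap` (the SAR
#'   caps bound the raw quadratic forms), the `vops`, the SAR scale
#'   `kappa`, and `provenance = list(tau, tr, Delta, p_max)`.
#' @export
build_constraints <- function(pulse, timing, limits, cal, vops, theta0,
                              gamma = GAMMA_1H) {
  stopifnot(inherits(pulse, "rf_pulse"), inherits(timing, "sequence_timing"),
            inherits(limits, "hardware_limits"),
            inherits(cal, "sar_calibration"), inherits(vops, "vop_set"))
  tau <- pulse$tau; tr <- timing$tr
  if (tau <= 0 || tr <= 0) stop("timing error: tau and tr must be positive")
  Delta <- duty_cycle(pulse, timing)
  p_max <- peak_amp_for_flip(theta0, pulse, gamma)
  tau_s <- tau * 1e-3; tr_s <- tr * 1e-3
  kappa <- cal$quad_mean^2 * theta0^2 / gamma^2 *
    (pulse$delta2 / pulse$delta1^2) / (tau_s * tr_s)
  structure(list(
    amp_peak_cap = sqrt(limits$p_peak / limits$a) / p_max,
    amp_avg_cap = sqrt(limits$p_av / (limits$a * Delta)) / p_max,
    sar_local_cap = limits$lsar_max / kappa,
    sar_wb_cap = limits$wbsar_max / kappa,
    vops = vops, kappa = kappa,
    provenance = list(tau = tau, tr = tr, Delta = Delta, p_max = p_max)),
    class = "constraint_set")
}

# Assemble the QCQP constraint description (real representation) for a
# constraint set: per-channel modulus caps, VOP SAR caps, whole-body cap.
constraint_qcqp <- function(cons, nch) {
  amp_cap <- min(cons$amp_peak_cap, cons$amp_avg_cap)
  A_list <- vector("list", nch)
  for (j in seq_len(nch)) {
    M <- matrix(0i, nch, nch); M[j, j] <- 1
    A_list[[j]] <- herm_to_real(M)
  }
  c_vec <- rep(amp_cap^2, nch)
  nv <- dim(cons$vops$matrices)[1L]
  for (i in seq_len(nv)) {
    A_list[[length(A_list) + 1L]] <- herm_to_real(cons$vops$matrices[i, , ])
    c_vec <- c(c_vec, cons$sar_local_cap)
  }
  A_list[[length(A_list) + 1L]] <- herm_to_real(cons$vops$wholebody)
  c_vec <- c(c_vec, cons$sar_wb_cap)
  list(A_list = A_list, c_vec = c_vec, amp_cap = amp_cap)
}

# Feasibility margins of a shim w against a constraint set; values <= 1 mean
# satisfied. SAR margins use the VOP working set unless a full set is given.
constraint_margins <- function(w, cons, qset_full = NULL) {
  amp <- abs(w)
  sarset <- if (is.null(qset_full)) cons$vops else qset_full
  mats <- if (inherits(sarset, "vop_set")) sarset$matrices else sarset$local
  qf_max <- max(quad_forms(flatten_qset(mats), w))
  wb <- quad_form1(cons$vops$wholebody, w)
  c(peak = max(amp) / cons$amp_peak_cap,
    average = max(amp) / cons$amp_avg_cap,
    local_sar = qf_max / cons$sar_local_cap,
    wholebody_sar = wb / cons$sar_wb_cap)
}

active_constraints <- function(margins, tol = 1e-3) {
  names(margins)[margins >= 1 - tol]
}

feasible_within <- function(margins, tol = 1e-9) all(margins <= 1 + tol)

#' Flip-angle bias and coefficient of variation over the ROI
#'
#' `bias_pct = (mean(flip) - theta0) / theta0 * 100`;
#' `cov = population sd / mean` (the divisor is the voxel count, not n-1).
#'
#' @param flip_map Numeric vector of achieved flip angles over the ROI.
#' @param theta0 Target flip angle (same units as `flip_map`).
#' @return Named numeric vector `c(bias_pct, cov)`.
#' @export
flip_metrics <- function(flip_map, theta0) {
  if (length(flip_map) == 0L) stop("empty ROI")
  m <- mean(flip_map)
  if (m == 0) stop("undefined-cov: zero mean flip angle")
  sd_pop <- sqrt(mean((flip_map - m)^2))
  c(bias_pct = (m - theta0) / theta0 * 100, cov = sd_pop / m)
}

# Common wrap-up: metrics, margins, active set, solution object.
finish_solution <- function(w, S, cons, theta0, objective, z, status,
                            trace, exchanges) {
  f <- drop(theta0 * (S$s %*% w))
  flip <- abs(f)
  met <- flip_metrics(flip, theta0)
  margins <- constraint_margins(w, cons)
  structure(list(w = w, objective = objective, bias_pct = met[["bias_pct"]],
                 cov = met[["cov"]], flip_map = flip, phase_ref = z,
                 margins = margins,
                 active = active_constraints(margins), status = status,
                 trace = trace, exchanges = exchanges, theta0 = theta0),
            class = "shim_solution")
}

# Initial auxiliary phase: the phase of a quadrature-mode excitation.
quad_phase_init <- function(S) {
  f <- drop(S$s %*% quadrature_weights(S$n_channels))
  z <- f / abs(f)
  z[!is.finite(z)] <- 1 + 0i
  z
}

# Deterministic start list for the variable exchange: the quadrature-mode
# phase (the canonical initialization), a flat phase, the phase of the best
# rank-one fit (dominant right singular vector of S), and the phases of the
# two strongest individual channels. Multi-start guards against local minima
# of the nonconvex magnitude problem.
phase_starts <- function(S) {
  safe_phase <- function(f) {
    z <- f / abs(f)
    z[!is.finite(z)] <- 1 + 0i
    z
  }
  starts <- list(quad = quad_phase_init(S),
                 flat = rep(1 + 0i, nrow(S$s)))
  sv <- tryCatch(svd(S$s, nu = 0L, nv = 1L)$v[, 1L], error = function(e) NULL)
  if (!is.null(sv)) starts$svd <- safe_phase(drop(S$s %*% sv))
  strength <- colMeans(abs(S$s))
  for (j in utils::head(order(-strength), 2L))
    starts[[paste0("ch", j)]] <- safe_phase(S$s[, j])
  starts
}

#' Shim solver options
#'
#' @param max_exchange Maximum variable-exchange iterations (default 20).
#' @param tol Relative cost-change stopping tolerance (default 1e-4).
#' @param z Optional fixed auxiliary phase vector; when supplied the exchange
#'   loop is skipped (accelerated mode).
#' @return List of options.
#' @export
shim_opts <- function(max_exchange = 20L, tol = 1e-4, z = NULL) {
  list(max_exchange = as.integer(max_exchange), tol = tol, z = z)
}

# Solve one convex subproblem min ||Creal x - d||^2 under the constraint set;
# returns complex w. Creal is the real representation (2p x 2n), d real (2p).
solve_convex_sub <- function(Creal, d, qc) {
  H <- crossprod(Creal)
  b <- drop(crossprod(Creal, d))
  res <- solve_qcqp(H, b, sum(d^2), qc$A_list, qc$c_vec)
  list(w = real_to_cplx(res$x), status = res$status)
}

# Magnitude cost sum((|S_theta w| - theta0)^2); the exchange objective at the
# optimal per-voxel phase.
mag_cost <- function(S, w, theta0) {
  sum((abs(drop(theta0 * (S$s %*% w))) - theta0)^2)
}

# Try scaling w by real factor c (feasibility-checked); returns the better w.
scale_polish <- function(w, c_fac, cons, accept = function(w2) TRUE) {
  if (!is.finite(c_fac) || c_fac <= 0) return(w)
  w2 <- w * c_fac
  if (feasible_within(constraint_margins(w2, cons), 1e-12) && accept(w2)) w2
  else w
}

#' Minimum-squared-error (magnitude least squares) shim
#'
#' Minimizes the squared deviation of the achieved flip-angle magnitude from
#' target over the ROI, subject to the constraint set, via variable exchange:
#' alternately solve the convex problem `||S_theta w - theta0 z||^2` with the
#' unit-modulus auxiliary phase `z` fixed, then update `z` to the phase of
#' the achieved excitation. The exchange is run from a small deterministic
#' set of phase starts (quadrature-mode phase, flat phase, dominant singular
#' vector) and the best converged run is returned, guarding against local
#' minima of the nonconvex magnitude problem. A feasibility-checked global
#' rescale is applied at the end. The cost is nonincreasing across exchanges
#' within each run.
#'
#' @param S A [channel_sensitivities()].
#' @param cons A [build_constraints()] result.
#' @param theta0 Target flip angle (rad).
#' @param opts A [shim_opts()].
#' @return Object of class `shim_solution`: `w`, `objective` (magnitude MSE
#'   cost), `bias_pct`, `cov`, `flip_map`, `phase_ref`, `margins`, `active`,
#'   `status`, `trace`, `exchanges`.
#' @export
solve_mse <- function(S, cons, theta0, opts = shim_opts()) {
  stopifnot(inherits(S, "channel_sensitivities"),
            inherits(cons, "constraint_set"))
  nch <- S$n_channels
  if (nrow(S$s) < nch)
    warning("degenerate ROI: fewer voxels than channels")
  qc <- constraint_qcqp(cons, nch)
  if (min(qc$c_vec) <= 0 || qc$amp_cap <= 0)
    return(structure(list(status = "infeasible", w = rep(0i, nch)),
                     class = "shim_solution"))
  St_real <- cplx_to_real(theta0 * S$s)
  fixed_z <- !is.null(opts$z)
  run_from <- function(z0) {
    z <- z0
    trace <- numeric(0)
    w <- rep(0i, nch)
    n_ex <- if (fixed_z) 1L else opts$max_exchange
    for (k in seq_len(n_ex)) {
      d <- c(Re(theta0 * z), Im(theta0 * z))
      w <- solve_convex_sub(St_real, d, qc)$w
      trace <- c(trace, mag_cost(S, w, theta0))
      if (!fixed_z) {
        f <- drop(S$s %*% w)
        zn <- f / abs(f)
        zn[!is.finite(zn)] <- z[!is.finite(zn)]
        z <- zn
      }
      if (k > 1L &&
          abs(trace[k] - trace[k - 1L]) <=
            opts$tol * max(trace[k - 1L], 1e-12))
        break
    }
    # Optimal feasible rescale of the magnitude cost.
    flip <- abs(drop(theta0 * (S$s %*% w)))
    c_fac <- theta0 * sum(flip) / sum(flip^2)
    w <- scale_polish(w, c_fac, cons,
                      accept = function(w2)
                        mag_cost(S, w2, theta0) <= mag_cost(S, w, theta0))
    list(w = w, z = z, trace = trace, cost = mag_cost(S, w, theta0))
  }
  runs <- if (fixed_z) list(run_from(opts$z))
          else lapply(phase_starts(S), run_from)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]
  finish_solution(best$w, S, cons, theta0, best$cost, best$z,
                  "optimal", best$trace, length(best$trace))
}

#' Minimum-bias shim
#'
#' Minimizes the squared deviation of the mean achieved flip angle from
#' target, with the projected image phase removed before averaging:
#' `|mean(z* o S_theta w) - theta0|^2`, subject to the constraint set. The
#' flip-angle variance is unconstrained, so homogeneity may worsen relative
#' to quadrature. When no cap binds, a zero-bias solution exists and the
#' final feasibility-checked rescale attains it exactly.
#'
#' @inheritParams solve_mse
#' @return A `shim_solution`; `objective` is the achieved squared bias (in
#'   flip-angle units).
#' @export
solve_min_bias <- function(S, cons, theta0, opts = shim_opts()) {
  stopifnot(inherits(S, "channel_sensitivities"),
            inherits(cons, "constraint_set"))
  nch <- S$n_channels
  qc <- constraint_qcqp(cons, nch)
  if (min(qc$c_vec) <= 0 || qc$amp_cap <= 0)
    return(structure(list(status = "infeasible", w = rep(0i, nch)),
                     class = "shim_solution"))
  fixed_z <- !is.null(opts$z)
  bias_cost <- function(w) (mean(abs(drop(theta0 * (S$s %*% w)))) - theta0)^2
  run_from <- function(z0) {
    z <- z0
    trace <- numeric(0)
    w <- rep(0i, nch)
    n_ex <- if (fixed_z) 1L else opts$max_exchange
    for (k in seq_len(n_ex)) {
      crow <- matrix(colMeans(Conj(z) * (theta0 * S$s)), 1L)
      w <- solve_convex_sub(cplx_to_real(crow), c(theta0, 0), qc)$w
      trace <- c(trace, bias_cost(w))
      if (!fixed_z) {
        f <- drop(S$s %*% w)
        zn <- f / abs(f)
        zn[!is.finite(zn)] <- z[!is.finite(zn)]
        z <- zn
      }
      if (k > 1L &&
          abs(trace[k] - trace[k - 1L]) <=
            opts$tol * max(trace[k - 1L], 1e-12))
        break
    }
    # Rescale to zero bias if the caps allow it (the bias target is linear
    # in a real scale factor).
    mflip <- mean(abs(drop(theta0 * (S$s %*% w))))
    w <- scale_polish(w, theta0 / mflip, cons)
    list(w = w, z = z, trace = trace, cost = bias_cost(w))
  }
  runs <- if (fixed_z) list(run_from(opts$z))
          else lapply(phase_starts(S), run_from)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]
  finish_solution(best$w, S, cons, theta0, best$cost, best$z,
                  "optimal", best$trace, length(best$trace))
}

#' Optimal quadrature (single-channel equivalent) shim
#'
#' Restricts the shim to `w = d * w_quad` with a single real scale `d >= 0`,
#' as on a conventional single-channel system. The flip-angle homogeneity
#' within the ROI is then fixed; only the overall scale can change. The
#' optimum is closed-form: `d` targets zero bias and is clipped by whichever
#' cap binds first, giving a negative bias when a cap is reached.
#'
#' @inheritParams solve_mse
#' @return A `shim_solution` with an extra field `d`.
#' @export
solve_quadrature <- function(S, cons, theta0) {
  stopifnot(inherits(S, "channel_sensitivities"),
            inherits(cons, "constraint_set"))
  wq <- quadrature_weights(S$n_channels)
  d_target <- 1 / mean(abs(S$s %*% wq))
  qf_local <- max(quad_forms(flatten_qset(cons$vops$matrices), wq))
  qf_wb <- quad_form1(cons$vops$wholebody, wq)
  d_caps <- c(peak = cons$amp_peak_cap,
              average = cons$amp_avg_cap,
              local_sar = sqrt(cons$sar_local_cap / qf_local),
              wholebody_sar = sqrt(cons$sar_wb_cap / qf_wb))
  d <- min(d_target, d_caps)
  w <- d * wq
  sol <- finish_solution(w, S, cons, theta0,
                         (d * theta0 / d_target - theta0)^2,
                         quad_phase_init(S), "closed_form",
                         trace = numeric(0), exchanges = 0L)
  sol$d <- d
  sol
}

#' @export
print.shim_solution <- function(x, ...) {
  if (identical(x$status, "infeasible")) {
    cat("<shim_solution> infeasible\n"); return(invisible(x))
  }
  cat(sprintf(
    "<shim_solution> bias = %.3f%%, cov = %.4f, active: %s\n",
    x$bias_pct, x$cov,
    if (length(x$active)) paste(x$active, collapse = ", ") else "none"))
  invisible(x)
}
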