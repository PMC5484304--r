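# Primal log-barrier interior-point solver for convex QCQPs of the form
#
#   minimize    x' H x - 2 b' x + c0
#   subject to  x' A_i x <= c_i,   i = 1..m
#
# with H PSD and every A_i PSD, c_i > 0 (so x = 0 is strictly feasible).
# This covers the complex shimming subproblems in their real 2*n_ch
# representation: least-squares objectives, per-channel modulus caps and
# quadratic SAR caps. Newton's method is used on the centering problems;
# the per-channel modulus caps make the barrier Hessian positive definite
# even when H is rank-deficient. Per-constraint work is batched into matrix
# products so sets with hundreds of SAR matrices stay fast.

# Real 2n x 2n representation of a complex Hermitian quadratic form:
# x = [Re w; Im w], x' A x = Re(w* M w).
herm_to_real <- function(M) {
  R <- Re(M); I <- Im(M)
  rbind(cbind(R, -I), cbind(I, R))
}

# Real representation of a complex linear map w -> C w (C is p x n complex):
# returns 2p x 2n real matrix acting on [Re w; Im w] -> [Re Cw; Im Cw].
cplx_to_real <- function(C) {
  R <- Re(C); I <- Im(C)
  rbind(cbind(R, -I), cbind(I, R))
}

real_to_cplx <- function(x) {
  n <- length(x) / 2L
  complex(real = x[seq_len(n)], imaginary = x[n + seq_len(n)])
}

#' @keywords internal
solve_qcqp <- function(H, b, c0, A_list, c_vec,
                       gap_tol = 1e-9, newton_tol = 1e-11,
                       max_newton = 60L, mu = 20) {
  n <- nrow(H)
  m <- length(A_list)
  stopifnot(length(c_vec) == m)
  if (any(c_vec <= 0)) {
    return(list(x = rep(0, n), status = "infeasible",
                objective = c0, gap = NA_real_))
  }
  # Scale each constraint to x' Atil x <= 1 and the objective to order 1.
  Astack <- do.call(rbind, lapply(seq_len(m),
                                  function(i) A_list[[i]] / c_vec[i]))
  # Row i of Aflat is vec(A_i / c_i): weighted sums of the A_i in one BLAS op.
  Aflat <- t(vapply(seq_len(m),
                    function(i) as.vector(A_list[[i]] / c_vec[i]),
                    numeric(n * n)))
  f_scale <- max(abs(c0), sum(b^2), 1e-12)
  Hs <- H / f_scale; bs <- b / f_scale

  fval <- function(x) drop(x %*% Hs %*% x) - 2 * drop(bs %*% x)
  # A_i x for all i as an n x m matrix, and slacks 1 - x'A_i x.
  ax_all <- function(x) matrix(Astack %*% x, n, m)
  slacks <- function(AX, x) 1 - drop(crossprod(AX, x))

  x <- rep(0, n)
  t <- 1
  repeat {
    for (it in seq_len(max_newton)) {
      AX <- ax_all(x)
      s <- slacks(AX, x)
      g <- t * (2 * drop(Hs %*% x) - 2 * bs) + 2 * drop(AX %*% (1 / s))
      # Barrier Hessian: sum 2 A_i/s_i + 4 (A_i x)(A_i x)'/s_i^2.
      AXw <- sweep(AX, 2L, 2 / s, `*`)
      Hn <- 2 * t * Hs + matrix(drop(crossprod(Aflat, 2 / s)), n, n) +
        tcrossprod(AXw)
      ch <- tryCatch(chol(Hn), error = function(e) NULL)
      if (is.null(ch)) ch <- chol(Hn + diag(1e-10 * max(diag(Hn)), n))
      dx <- -backsolve(ch, forwardsolve(t(ch), g))
      lambda2 <- -sum(g * dx)
      if (lambda2 / 2 < newton_tol) break
      alpha <- 1
      phi0 <- t * fval(x) - sum(log(s))
      repeat {
        xn <- x + alpha * dx
        sn <- slacks(ax_all(xn), xn)
        if (all(sn > 0)) {
          phin <- t * fval(xn) - sum(log(sn))
          if (phin <= phi0 + 1e-4 * alpha * sum(g * dx)) break
        }
        alpha <- alpha / 2
        if (alpha < 1e-14) break
      }
      if (alpha < 1e-14) break
      x <- x + alpha * dx
    }
    if (m / t < gap_tol) break
    t <- t * mu
  }
  list(x = x, status = "optimal",
       objective = fval(x) * f_scale + c0, gap = m / t * f_scale,
       slacks = slacks(ax_all(x), x))
}
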