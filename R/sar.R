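# Flatten a (n_vox, nch, nch) array of Hermitian matrices into the
# (n_vox, nch^2) layout used for vectorised quadratic forms.
flatten_qset <- function(qarr) {
  d <- dim(qarr)
  matrix(qarr, d[1L], d[2L] * d[3L])
}

# Re(w* Q_i w) for every matrix in a flattened set.
quad_forms <- function(qflat, w) {
  Re(qflat %*% as.vector(outer(Conj(w), w)))
}

quad_form1 <- function(Q, w) Re(drop(Conj(w) %*% Q %*% w))

#' Calibrate the SAR model against measured sensitivities
#'
#' The Q-matrices give SAR per unit squared normalized drive; to evaluate SAR
#' for a physical pulse they are scaled by the square of the achieved mean
#' quadrature B1+ at the pulse peak: `b1_achieved = p_max * mean|S w_quad|`
#' over the ROI. Under an exactly normalized phantom the spatial mean is 1 and
#' `b1_achieved = p_max`.
#'
#' @param S A [channel_sensitivities()].
#' @param w_quad Quadrature weights (default from channel count).
#' @param p_max Peak pulse amplitude (uT).
#' @return Object of class `sar_calibration` with `b1_achieved` (uT),
#'   `quad_mean` (dimensionless mean |S w_quad| over the ROI) and `p_max`.
#' @export
calibrate <- function(S, w_quad = quadrature_weights(S$n_channels), p_max) {
  stopifnot(inherits(S, "channel_sensitivities"))
  if (nrow(S$s) == 0L) stop("calibration error: empty ROI")
  qm <- mean(abs(S$s %*% w_quad))
  structure(list(b1_achieved = p_max * qm, quad_mean = qm, p_max = p_max),
            class = "sar_calibration")
}

#' Evaluate maximum local and whole-body SAR for a shim
#'
#' `SAR_i = Re(w* Q_i w) * b1_achieved^2 * Delta` over the (possibly
#' VOP-compressed) local set; the whole-body value uses the single whole-body
#' matrix. Evaluating on a VOP set never underestimates the full-set maximum.
#'
#' @param w Complex shim vector.
#' @param qset A `qmatrix_set` or `vop_set`.
#' @param cal A `sar_calibration`.
#' @param Delta Sequence power duty cycle.
#' @return List: `local_max` (W/kg), `wholebody` (W/kg), `argmax` (index into
#'   the set; for a full set this labels the voxel).
#' @export
sar <- function(w, qset, cal, Delta) {
  mats <- if (inherits(qset, "vop_set")) qset$matrices else qset$local
  nch <- dim(mats)[2L]
  if (length(w) != nch) stop("shape error: shim length != channel count")
  scale <- cal$b1_achieved^2 * Delta
  qf <- quad_forms(flatten_qset(mats), w)
  i <- which.max(qf)
  list(local_max = qf[i] * scale,
       wholebody = quad_form1(qset$wholebody, w) * scale,
       argmax = if (inherits(qset, "vop_set")) i else qset$voxel[i])
}

#' Per-voxel SAR map
#'
#' @inheritParams sar
#' @param qset A full `qmatrix_set` (one matrix per voxel).
#' @return Data frame: `voxel` (linear grid index), `sar` (W/kg). The maximum
#'   equals `sar()$local_max` evaluated on the same set.
#' @export
sar_map <- function(w, qset, cal, Delta) {
  stopifnot(inherits(qset, "qmatrix_set"))
  qf <- quad_forms(flatten_qset(qset$local), w)
  data.frame(voxel = qset$voxel, sar = qf * cal$b1_achieved^2 * Delta)
}

# Largest eigenvalue of a Hermitian matrix.
spec_norm_herm <- function(M) {
  max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Compress a Q-matrix set into virtual observation points (VOPs)
#'
#' Greedy domination: candidates are visited in decreasing spectral norm
#' (ties broken by original index) and added to the VOP set unless an
#' existing VOP `V` dominates them in the sense that `V + epsilon * Z - Q`
#' is PSD, where `Z` is the arithmetic mean of the set. The stored VOP
#' matrices are the overestimating `V + epsilon * Z`, so that for every shim
#' the VOP-set maximum is at least the full-set maximum and overestimates it
#' by at most `epsilon * w* Z w`. Because `w* Z w` is the mean of the
#' quadratic forms, which cannot exceed their maximum, the overestimation is
#' at most a fraction `epsilon` of the true maximum for every shim. With
#' `epsilon = 0` the compression is lossless.
#'
#' @param qset A `qmatrix_set`.
#' @param epsilon Overestimation bound as a fraction (>= 0), e.g. 0.03.
#' @return Object of class `vop_set`: `matrices` (n_vop x nch x nch,
#'   overestimating), `raw` (the dominating members themselves), `epsilon`,
#'   `provenance` (indices into the original set), `Z`, `wholebody`,
#'   `n_full`.
#' @export
compress_vops <- function(qset, epsilon = 0.03) {
  stopifnot(inherits(qset, "qmatrix_set"))
  if (epsilon < 0) stop("domain error: epsilon must be >= 0")
  qarr <- qset$local
  nq <- dim(qarr)[1L]; nch <- dim(qarr)[2L]
  norms <- vapply(seq_len(nq),
                  function(i) spec_norm_herm(qarr[i, , ]), numeric(1))
  ord <- order(-norms, seq_len(nq))
  Z <- apply(qarr, c(2L, 3L), mean)
  Z <- (Z + Conj(t(Z))) / 2
  eZ <- epsilon * Z
  tol <- 1e-9 * max(norms)
  keep <- integer(0)
  vop_over <- list()  # V + eps*Z for kept members
  for (i in ord) {
    Qi <- qarr[i, , ]
    dominated <- FALSE
    for (V in vop_over) {
      ev <- eigen(V - Qi, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) >= -tol) { dominated <- TRUE; break }
    }
    if (!dominated) {
      keep <- c(keep, i)
      vop_over[[length(vop_over) + 1L]] <- Qi + eZ
    }
  }
  mats <- array(0i, dim = c(length(keep), nch, nch))
  raw <- array(0i, dim = c(length(keep), nch, nch))
  for (k in seq_along(keep)) {
    mats[k, , ] <- vop_over[[k]]
    raw[k, , ] <- qarr[keep[k], , ]
  }
  structure(list(matrices = mats, raw = raw, epsilon = epsilon,
                 provenance = keep, Z = Z, wholebody = qset$wholebody,
                 n_full = nq),
            class = "vop_set")
}

#' @export
print.vop_set <- function(x, ...) {
  cat(sprintf("<vop_set> %d VOPs of %d matrices (epsilon = %g)\n",
              dim(x$matrices)[1L], x$n_full, x$epsilon))
  invisible(x)
}
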