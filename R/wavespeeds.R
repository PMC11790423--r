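# Acoustic tensor and characteristic wave speeds. The speeds feed both the
# CFL time-step control and the dissipation coefficient of the LLF flux.

#' Acoustic tensor along a material direction
#'
#' The 3x3 tensor \eqn{Q_{ik} = N_J (\partial P_{iJ}/\partial F_{kL}) N_L}
#' whose eigenvalues, divided by the density, are the squared plane-wave
#' speeds along the unit material direction N. The derivative of the first
#' Piola-Kirchhoff stress is evaluated by central finite differences on F
#' (step \eqn{h = 10^{-6}\max(1, \|F\|)}), at frozen memory variables: the
#' memory tensors enter P linearly and are constant during the hyperbolic
#' sub-step.
#'
#' @param F deformation gradient (3x3, det F > 0).
#' @param mem list of memory tensors (or NULL).
#' @param N unit direction vector (length 3).
#' @param ac an [ac_config()].
#' @param mat a [qlv_material()].
#' @return 3x3 acoustic tensor (Pa).
#' @export
acoustic_tensor <- function(F, mem = NULL, N, ac, mat) {
  stopifnot(abs(sum(N^2) - 1) < 1e-8)
  if (det(F) <= 0) stop("element inversion: det F <= 0")
  memm <- NULL
  if (!is.null(mem) && length(mem) > 0)
    memm <- matrix(unlist(lapply(mem, sym6_pack)), 6L * length(mem), 1L)
  h <- 1e-6 * max(1, sqrt(sum(F^2)))
  Q <- matrix(0, 3L, 3L)
  for (k in 1:3) {
    Fp <- F; Fp[k, ] <- Fp[k, ] + h * N
    Fm_ <- F; Fm_[k, ] <- Fm_[k, ] - h * N
    Pp <- .stress_all(matrix(vec9_pack(Fp), 9L, 1L), memm, ac, mat)$P[, 1L]
    Pm <- .stress_all(matrix(vec9_pack(Fm_), 9L, 1L), memm, ac, mat)$P[, 1L]
    dP <- vec9_unpack((Pp - Pm) / (2 * h))
    Q[, k] <- dP %*% N
  }
  Q
}

# Vectorised per-cell maximum characteristic speed along axis `dir`
# (N = e_dir). Only three F-components interact with the direction, so six
# stress evaluations suffice. qm: ncomp x n.
.dir_speeds <- function(qm, dir, ac, mat) {
  Fm <- qm[1:9, , drop = FALSE]
  n <- ncol(Fm)
  memm <- if (mat$n_relax > 0L) qm[-(1:12), , drop = FALSE] else NULL
  h <- 1e-6 * pmax(1, sqrt(colSums(Fm^2)))
  rowsP <- .iF(1:3, dir)
  Q <- matrix(0, 9L, n)
  for (k in 1:3) {
    r <- .iF(k, dir)
    Fp <- Fm; Fp[r, ] <- Fp[r, ] + h
    Fl <- Fm; Fl[r, ] <- Fl[r, ] - h
    Pp <- .stress_all(Fp, memm, ac, mat)$P
    Pm <- .stress_all(Fl, memm, ac, mat)$P
    dP <- (Pp[rowsP, , drop = FALSE] - Pm[rowsP, , drop = FALSE]) /
      rep(2 * h, each = 3L)
    Q[.iF(1:3, k), ] <- dP  # Q_ik = dP_i,dir / dF_k,dir
  }
  lscale <- mat$rho0 * mat$c_inf^2 * (4 / 3 + 1 / ac$epsilon)
  lam <- .eig3_max(Q, scale = lscale)
  bad <- attr(lam, "bad")
  if (any(bad))
    stop(sprintf("loss of hyperbolicity: complex acoustic-tensor spectrum in %d cell(s), first at cell %d",
                 sum(bad), which(bad)[1L]))
  neg <- lam < -1e-8 * lscale
  if (any(neg))
    stop(sprintf("loss of hyperbolicity: negative acoustic-tensor eigenvalue in %d cell(s), first at cell %d",
                 sum(neg), which(neg)[1L]))
  sqrt(pmax(lam, 0) / mat$rho0)
}

# per-cell speeds along every non-singleton axis; returns (n_axes x ncells)
# with rownames giving the axis
.field_speeds <- function(field, ac, mat) {
  axes <- which(c(field$nx, field$ny, field$nz) > 1L)
  if (length(axes) == 0L) axes <- 1L
  out <- matrix(0, length(axes), ncol(field$q))
  rownames(out) <- as.character(axes)
  for (i in seq_along(axes))
    out[i, ] <- .dir_speeds(field$q, axes[i], ac, mat)
  out
}

#' Maximum wave speed over the field
#'
#' Largest characteristic speed over all cells and over the axis directions
#' of the dimensionally split scheme, obtained from the eigenvalues of the
#' acoustic tensor. This is the speed entering the CFL condition.
#'
#' @param field a [state_field()].
#' @param ac an [ac_config()].
#' @param mat a [qlv_material()].
#' @return scalar speed (m/s).
#' @export
max_wave_speed <- function(field, ac, mat) {
  max(.field_speeds(field, ac, mat))
}
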