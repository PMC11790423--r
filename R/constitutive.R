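# QLV constitutive law with artificial compressibility: strain measures,
# elastic and viscous stresses, pressure, and the exact relaxation update of
# the memory variables.
#
# User-facing functions take single 3x3 tensors (or sym6 vectors); the
# vectorised kernels suffixed `_all` act on column-per-cell matrices and are
# what the solver calls.

#' Principal strain invariants
#'
#' First and second principal invariants of a symmetric strain tensor C:
#' \eqn{I_1 = \mathrm{tr}\,C} and
#' \eqn{I_2 = \tfrac12(I_1^2 - \mathrm{tr}\,C^2)}.
#'
#' @param C symmetric positive-definite 3x3 matrix (e.g. right Cauchy-Green).
#' @return named numeric vector `c(I1, I2)`.
#' @export
strain_invariants <- function(C) {
  stopifnot(is.matrix(C), all(dim(C) == c(3L, 3L)))
  if (max(abs(C - t(C))) > 1e-12 * max(1, max(abs(C))))
    stop("strain tensor must be symmetric")
  I1 <- sum(diag(C))
  c(I1 = I1, I2 = (I1^2 - sum(diag(C %*% C))) / 2)
}

#' Isochoric elastic stress
#'
#' Second Piola-Kirchhoff stress of the Mooney-Rivlin/Yeoh energy evaluated
#' on the volume-preserving strain:
#' \eqn{\bar S^e = 2(\bar W_1 + \bar I_1 \bar W_2)I - 2\bar W_2 \bar C}
#' with \eqn{\bar W_1 = C_{10} + 2C_{20}(\bar I_1 - 3)} and
#' \eqn{\bar W_2 = C_{01}}.
#'
#' @param C_bar unimodular (det = 1) symmetric 3x3 strain tensor.
#' @param mat a [qlv_material()].
#' @return symmetric 3x3 stress matrix (Pa).
#' @export
elastic_stress_bar <- function(C_bar, mat) {
  if (abs(det(C_bar) - 1) > 1e-10)
    stop("C_bar must be unimodular: pass the volume-preserving strain")
  s <- .elastic_stress_bar_all(matrix(sym6_pack(C_bar), 6L, 1L), mat)
  sym6_unpack(s[, 1L])
}

# vectorised: Cbar as sym6 columns
.elastic_stress_bar_all <- function(Cbar, mat) {
  I1b <- Cbar[1, ] + Cbar[4, ] + Cbar[6, ]
  W1 <- mat$C10 + 2 * mat$C20 * (I1b - 3)
  W2 <- mat$C01
  iso <- 2 * (W1 + I1b * W2)
  out <- -2 * W2 * Cbar
  out[.SYM6_DIAG, ] <- out[.SYM6_DIAG, , drop = FALSE] +
    rep(iso, each = 3L)
  out
}

#' Lagrangian deviatoric projection
#'
#' Applies the deviatoric operator of the Lagrangian description,
#' \eqn{\mathrm{Dev}\,S = S - \tfrac13 (S:C)\,C^{-1}}, which removes the
#' part of S power-conjugate to volumetric strain. The result R satisfies
#' R:C = 0 to round-off.
#'
#' @param S symmetric 3x3 tensor.
#' @param C symmetric invertible 3x3 strain tensor.
#' @return symmetric 3x3 tensor.
#' @export
dev_lagrangian <- function(S, C) {
  dC <- det(C)
  if (!is.finite(dC) || abs(dC) < .Machine$double.xmin * 1e10)
    stop("singular strain tensor in deviatoric projection")
  Sm <- matrix(sym6_pack(S), 6L, 1L)
  Cm <- matrix(sym6_pack(C), 6L, 1L)
  sym6_unpack(.dev_all(Sm, Cm, .syminv(Cm, dC))[, 1L])
}

.dev_all <- function(Sm, Cm, Cinv) {
  tr <- .symdot(Sm, Cm)
  Sm - rep(tr / 3, each = 6L) * Cinv
}

#' Artificial-compressibility pressure
#'
#' Pressure from the quadratic volumetric energy \eqn{U(J)=\tfrac12 K(J-1)^2}:
#' \eqn{p = -U'(J) = -K(J-1)} with \eqn{K = \mu/\epsilon}.
#'
#' @param J volume dilation det F, positive.
#' @param ac an [ac_config()].
#' @param mat a [qlv_material()].
#' @return pressure (Pa), vectorised over `J`.
#' @export
ac_pressure <- function(J, ac, mat) {
  if (any(J <= 0))
    stop("element inversion: non-positive volume dilation J")
  -.bulk_modulus(mat, ac) * (J - 1)
}

#' Total stress of the weakly compressible QLV solid
#'
#' Second Piola-Kirchhoff stress
#' \deqn{S = J U'(J) C^{-1} + J^{-2/3}\,\mathrm{Dev}\,\bar S^e
#'       - \sum_\ell S^v_\ell,}
#' where the deviatoric projection is taken with respect to the
#' volume-preserving strain \eqn{\bar C = J^{-2/3} C}, together with the
#' first Piola-Kirchhoff stress P = F S. The memory variables enter linearly
#' with a minus sign and are held fixed (they evolve in the relaxation
#' sub-step, see [relax_update()]).
#'
#' @param F deformation gradient, 3x3 matrix with positive determinant.
#' @param mem memory variables: list of symmetric 3x3 matrices (length
#'   `mat$n_relax`), or NULL for none.
#' @param ac an [ac_config()].
#' @param mat a [qlv_material()].
#' @return list with symmetric `S` and `P = F S` (3x3 matrices, Pa).
#' @export
total_stress <- function(F, mem = NULL, ac, mat) {
  Fm <- matrix(vec9_pack(F), 9L, 1L)
  memm <- NULL
  if (!is.null(mem) && length(mem) > 0)
    memm <- matrix(unlist(lapply(mem, sym6_pack)), 6L * length(mem), 1L)
  st <- .stress_all(Fm, memm, ac, mat, want_S = TRUE)
  list(S = sym6_unpack(st$S[, 1L]), P = vec9_unpack(st$P[, 1L]))
}

# Vectorised total stress. Fm: 9 x n; memm: (6N) x n or NULL.
# Returns list(P [, S, J]).
.stress_all <- function(Fm, memm, ac, mat, want_S = FALSE) {
  J <- .det9(Fm)
  if (any(J <= 0)) {
    bad <- which(J <= 0)
    stop(sprintf("element inversion: det F <= 0 in %d cell(s), first at cell %d",
                 length(bad), bad[1L]))
  }
  Cm <- .C_from_F(Fm)
  J23 <- J^(2 / 3)
  Cbar <- Cm / rep(J23, each = 6L)
  Cbar_inv <- .syminv(Cbar, .det6(Cbar))
  Se <- .elastic_stress_bar_all(Cbar, mat)
  SDe <- .dev_all(Se, Cbar, Cbar_inv)
  K <- .bulk_modulus(mat, ac)
  # J U'(J) C^-1 with C^-1 = Cbar^-1 / J^(2/3)
  vol <- K * (J - 1) * J / J23
  S <- rep(vol, each = 6L) * Cbar_inv + SDe / rep(J23, each = 6L)
  if (!is.null(memm)) {
    for (l in seq_len(mat$n_relax))
      S <- S - memm[(6L * (l - 1L) + 1L):(6L * l), , drop = FALSE]
  }
  out <- list(P = .FS_prod(Fm, S))
  if (want_S) { out$S <- S; out$J <- J }
  out
}

# deviatoric isochoric elastic stress Dev(Se_bar) wrt Cbar, for the
# relaxation source term; Fm: 9 x n -> 6 x n
.sbar_de_all <- function(Fm, mat) {
  J <- .det9(Fm)
  Cm <- .C_from_F(Fm)
  Cbar <- Cm / rep(J^(2 / 3), each = 6L)
  Cbar_inv <- .syminv(Cbar, .det6(Cbar))
  .dev_all(.elastic_stress_bar_all(Cbar, mat), Cbar, Cbar_inv)
}

#' Exact relaxation update of the memory variables
#'
#' Integrates the linear relaxation equations
#' \eqn{\dot S^v_\ell = \omega_\ell (g_\ell \bar S^{De} - S^v_\ell)} exactly
#' over a time step with the driving stress held fixed:
#' \deqn{S^v_\ell \leftarrow e^{-\omega_\ell \Delta t} S^v_\ell +
#'       (1 - e^{-\omega_\ell \Delta t})\, g_\ell \bar S^{De}.}
#' The update is unconditionally stable for any `dt`.
#'
#' @param mem list of symmetric 3x3 memory tensors, length `mat$n_relax`.
#' @param S_De_bar deviatoric isochoric elastic stress (symmetric 3x3).
#' @param dt time step (s), non-negative.
#' @param mat a [qlv_material()].
#' @return updated list of memory tensors.
#' @export
relax_update <- function(mem, S_De_bar, dt, mat) {
  stopifnot(dt >= 0, length(mem) == mat$n_relax)
  sd <- sym6_pack(S_De_bar)
  lapply(seq_len(mat$n_relax), function(l) {
    e <- exp(-mat$omega[l] * dt)
    sym6_unpack(e * sym6_pack(mem[[l]]) + (1 - e) * mat$g[l] * sd)
  })
}

# vectorised relaxation applied in place on the state matrix (rows 13+ are
# memory components); qm: ncomp x n
.relax_all <- function(qm, dt, mat) {
  if (mat$n_relax == 0L || dt == 0) return(qm)
  SDe <- .sbar_de_all(qm[1:9, , drop = FALSE], mat)
  for (l in seq_len(mat$n_relax)) {
    e <- exp(-mat$omega[l] * dt)
    rows <- (12L + 6L * (l - 1L) + 1L):(12L + 6L * l)
    qm[rows, ] <- e * qm[rows, , drop = FALSE] + (1 - e) * mat$g[l] * SDe
  }
  qm
}
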