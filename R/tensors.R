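# Vectorised 3x3 tensor algebra on column-per-cell storage.
#
# A deformation gradient F is stored as a 9-vector in row-major order
# (F11,F12,F13,F21,F22,F23,F31,F32,F33); symmetric tensors as 6-vectors in
# the order (11,12,13,22,23,33). All internal kernels act on matrices whose
# columns are grid cells, so a single call handles the whole field.

# row index of F_ij in the 9-vector layout
.iF <- function(i, j) (i - 1L) * 3L + j

.SYM6_DIAG <- c(1L, 4L, 6L)

#' Pack a 3x3 matrix into layout vectors
#'
#' `sym6_pack()` stores a symmetric tensor as its six independent components
#' in the order (11,12,13,22,23,33); `sym6_unpack()` restores the full 3x3
#' matrix. `vec9_pack()`/`vec9_unpack()` do the same for a general tensor in
#' row-major order.
#'
#' @param M a 3x3 numeric matrix.
#' @param s a numeric vector of length 6 (or 9 for `vec9_unpack`).
#' @return the packed vector, or the reconstructed 3x3 matrix.
#' @export
sym6_pack <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3L, 3L)))
  c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])
}

#' @rdname sym6_pack
#' @export
sym6_unpack <- function(s) {
  matrix(c(s[1], s[2], s[3],
           s[2], s[4], s[5],
           s[3], s[5], s[6]), 3L, 3L, byrow = TRUE)
}

#' @rdname sym6_pack
#' @export
vec9_pack <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3L, 3L)))
  as.numeric(t(M))
}

#' @rdname sym6_pack
#' @export
vec9_unpack <- function(s) matrix(s, 3L, 3L, byrow = TRUE)

# C = F^T F as sym6 columns; Fm is 9 x n
.C_from_F <- function(Fm) {
  f <- function(k) Fm[k, , drop = TRUE]
  rbind(f(1)^2 + f(4)^2 + f(7)^2,
        f(1) * f(2) + f(4) * f(5) + f(7) * f(8),
        f(1) * f(3) + f(4) * f(6) + f(7) * f(9),
        f(2)^2 + f(5)^2 + f(8)^2,
        f(2) * f(3) + f(5) * f(6) + f(8) * f(9),
        f(3)^2 + f(6)^2 + f(9)^2)
}

# det of 9 x n general tensors (closed-form cofactor expansion)
.det9 <- function(Fm) {
  f <- function(k) Fm[k, , drop = TRUE]
  f(1) * (f(5) * f(9) - f(6) * f(8)) -
    f(2) * (f(4) * f(9) - f(6) * f(7)) +
    f(3) * (f(4) * f(8) - f(5) * f(7))
}

# det of sym6 columns
.det6 <- function(Cm) {
  c1 <- Cm[1, ]; c2 <- Cm[2, ]; c3 <- Cm[3, ]
  c4 <- Cm[4, ]; c5 <- Cm[5, ]; c6 <- Cm[6, ]
  c1 * (c4 * c6 - c5^2) - c2 * (c2 * c6 - c5 * c3) + c3 * (c2 * c5 - c4 * c3)
}

# inverse of sym6 columns; `det` may be supplied when already known
.syminv <- function(Cm, det = NULL) {
  c1 <- Cm[1, ]; c2 <- Cm[2, ]; c3 <- Cm[3, ]
  c4 <- Cm[4, ]; c5 <- Cm[5, ]; c6 <- Cm[6, ]
  if (is.null(det)) det <- .det6(Cm)
  rbind((c4 * c6 - c5^2) / det,
        (c3 * c5 - c2 * c6) / det,
        (c2 * c5 - c3 * c4) / det,
        (c1 * c6 - c3^2) / det,
        (c2 * c3 - c1 * c5) / det,
        (c1 * c4 - c2^2) / det)
}

# full contraction A:B of sym6 columns
.symdot <- function(Am, Bm) {
  Am[1, ] * Bm[1, ] + Am[4, ] * Bm[4, ] + Am[6, ] * Bm[6, ] +
    2 * (Am[2, ] * Bm[2, ] + Am[3, ] * Bm[3, ] + Am[5, ] * Bm[5, ])
}

# P = F S with F as 9 x n and S as sym6 columns; returns 9 x n
.FS_prod <- function(Fm, Sm) {
  s1 <- Sm[1, ]; s2 <- Sm[2, ]; s3 <- Sm[3, ]
  s4 <- Sm[4, ]; s5 <- Sm[5, ]; s6 <- Sm[6, ]
  out <- Fm
  for (i in 1:3) {
    fi1 <- Fm[.iF(i, 1), ]; fi2 <- Fm[.iF(i, 2), ]; fi3 <- Fm[.iF(i, 3), ]
    out[.iF(i, 1), ] <- fi1 * s1 + fi2 * s2 + fi3 * s3
    out[.iF(i, 2), ] <- fi1 * s2 + fi2 * s4 + fi3 * s5
    out[.iF(i, 3), ] <- fi1 * s3 + fi2 * s5 + fi3 * s6
  }
  out
}

# Largest real eigenvalue of 3x3 tensors stored as 9 x n columns, through the
# trigonometric solution of the characteristic cubic. The spectrum of an
# acoustic tensor of a hyperbolic system is real; a strongly complex pair
# signals loss of hyperbolicity and is reported via attribute "bad".
.eig3_max <- function(Qm, scale = 1) {
  q <- function(k) Qm[k, , drop = TRUE]
  tr <- q(1) + q(5) + q(9)
  trQ2 <- q(1)^2 + q(5)^2 + q(9)^2 +
    2 * (q(2) * q(4) + q(3) * q(7) + q(6) * q(8))
  c2 <- tr
  c1 <- (tr^2 - trQ2) / 2
  c0 <- .det9(Qm)
  p <- c1 - c2^2 / 3
  qd <- -2 * c2^3 / 27 + c1 * c2 / 3 - c0
  disc <- -4 * p^3 - 27 * qd^2
  # a negative discriminant signals a complex pair; repeated real roots give
  # disc ~ 0 polluted by round-off, so the test is relative to the cubic's
  # own scale
  bad <- disc < -1e-12 * (4 * abs(p)^3 + 27 * qd^2 + .Machine$double.xmin)
  m <- 2 * sqrt(pmax(-p, 0) / 3)
  cosarg <- ifelse(m > 0, pmin(pmax(3 * qd / (p * m), -1), 1), 0)
  cosarg[!is.finite(cosarg)] <- 0
  lam <- m * cos(acos(cosarg) / 3) + c2 / 3
  attr(lam, "bad") <- bad
  lam
}
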