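# Material parameter objects: quasi-linear viscoelastic solid and the
# artificial-compressibility configuration.

#' Quasi-linear viscoelastic material
#'
#' Defines an incompressible quasi-linear viscoelastic (QLV) solid whose
#' instantaneous elastic response is of combined Mooney--Rivlin/Yeoh type,
#' with strain energy
#' \deqn{\bar W = C_{10}(\bar I_1-3) + C_{01}(\bar I_2-3) + C_{20}(\bar I_1-3)^2,}
#' and `n_relax = length(g)` linear relaxation mechanisms acting on the
#' deviatoric elastic stress through stress-like memory variables. Each
#' mechanism has a dimensionless magnitude \eqn{g_\ell \in (0,1)} and a
#' relaxation frequency \eqn{\omega_\ell > 0} (rad/s).
#'
#' Derived quantities are attached to the returned object:
#' the shear modulus \eqn{\mu = 2(C_{10}+C_{01})}, the nonlinearity
#' parameter \eqn{\beta = 3C_{20}/(C_{10}+C_{01})}, the high-frequency
#' (instantaneous) shear wave speed \eqn{c_\infty = \sqrt{\mu/\rho_0}} and
#' the low-frequency (equilibrium) speed
#' \eqn{c_0 = c_\infty\sqrt{1-\sum_\ell g_\ell}}.
#'
#' @param rho0 mass density (kg/m^3), positive.
#' @param C10,C01,C20 Rivlin coefficients (Pa); `C10 + C01` must be positive.
#' @param g numeric vector of relaxation magnitudes, each in (0,1), with
#'   `sum(g) < 1`. Length 0 gives a purely elastic solid.
#' @param omega numeric vector of relaxation frequencies (rad/s), positive,
#'   same length as `g`.
#' @return an object of class `qlv_material`.
#' @seealso [qlv_gelatin()] for the built-in gelatin parameter set,
#'   [convert_elastic_params()] to build `C10`, `C20` from `(mu, beta)`.
#' @export
qlv_material <- function(rho0, C10, C01 = 0, C20 = 0,
                         g = numeric(0), omega = numeric(0)) {
  stopifnot(is.numeric(rho0), length(rho0) == 1L, rho0 > 0)
  if (C10 + C01 <= 0)
    stop("C10 + C01 must be positive (shear modulus mu = 2*(C10+C01))")
  if (length(g) != length(omega))
    stop("g and omega must have the same length")
  if (length(g) > 0) {
    if (any(g <= 0 | g >= 1) || sum(g) >= 1)
      stop("relaxation magnitudes must satisfy g_l in (0,1) and sum(g) < 1")
    if (any(omega <= 0))
      stop("relaxation frequencies omega_l must be positive")
  }
  mu <- 2 * (C10 + C01)
  mat <- list(rho0 = rho0, C10 = C10, C01 = C01, C20 = C20,
              g = as.numeric(g), omega = as.numeric(omega),
              n_relax = length(g),
              mu = mu,
              beta = 3 * C20 / (C10 + C01),
              c_inf = sqrt(mu / rho0),
              c0 = sqrt(mu / rho0) * sqrt(1 - sum(g)))
  class(mat) <- "qlv_material"
  mat
}

#' @export
print.qlv_material <- function(x, ...) {
  cat("QLV material (Mooney-Rivlin/Yeoh elastic response)\n")
  cat(sprintf("  rho0 = %g kg/m^3, C10 = %g Pa, C01 = %g Pa, C20 = %g Pa\n",
              x$rho0, x$C10, x$C01, x$C20))
  cat(sprintf("  mu = %g Pa, beta = %g, c_inf = %.4g m/s, c0 = %.4g m/s\n",
              x$mu, x$beta, x$c_inf, x$c0))
  if (x$n_relax > 0) {
    cat(sprintf("  %d relaxation mechanisms:\n", x$n_relax))
    for (l in seq_len(x$n_relax))
      cat(sprintf("    g%d = %g, omega%d = %g rad/s\n", l, x$g[l], l, x$omega[l]))
  } else cat("  purely elastic (no relaxation mechanisms)\n")
  invisible(x)
}

#' Gelatin material preset
#'
#' Parameter set for a gelatin sample with three relaxation mechanisms,
#' fitted to shear-wave measurements over 75--675 Hz: density 1000 kg/m^3,
#' shear modulus 2.684 kPa, nonlinearity parameter 4.4, relaxation magnitudes
#' (0.0434, 0.0466, 0.2213) at frequencies 2\eqn{\pi}(10, 100, 1000) rad/s.
#' The Rivlin coefficients are derived under the Yeoh assumption
#' \eqn{C_{01}=0}, giving C10 = 1.342 kPa and C20 = 1.968 kPa.
#'
#' @param elastic if TRUE, drop the relaxation mechanisms (instantaneous
#'   elastic response only).
#' @return a [qlv_material()] object.
#' @export
qlv_gelatin <- function(elastic = FALSE) {
  cf <- convert_elastic_params(mu = 2684, beta = 4.4, C01 = 0)
  if (elastic)
    qlv_material(rho0 = 1000, C10 = cf$C10, C01 = 0, C20 = cf$C20)
  else
    qlv_material(rho0 = 1000, C10 = cf$C10, C01 = 0, C20 = cf$C20,
                 g = c(0.0434, 0.0466, 0.2213),
                 omega = 2 * pi * c(10, 100, 1000))
}

#' Rivlin coefficients from shear modulus and nonlinearity parameter
#'
#' Inverts the relations \eqn{\mu = 2(C_{10}+C_{01})} and
#' \eqn{\beta = 3C_{20}/(C_{10}+C_{01})} for the Yeoh coefficients, given a
#' chosen second Mooney coefficient `C01` (zero by default, the usual
#' assumption for soft tissue).
#'
#' @param mu shear modulus (Pa), positive.
#' @param beta dimensionless parameter of nonlinearity.
#' @param C01 second Mooney coefficient (Pa).
#' @return list with elements `C10` and `C20` (Pa).
#' @export
convert_elastic_params <- function(mu, beta, C01 = 0) {
  stopifnot(mu > 0)
  C10 <- mu / 2 - C01
  if (C10 <= 0) stop("C01 too large: C10 = mu/2 - C01 must be positive")
  list(C10 = C10, C20 = beta * (C10 + C01) / 3)
}

#' Artificial-compressibility configuration
#'
#' The incompressibility constraint det F = 1 is relaxed into a stiff
#' pressure--dilatation law \eqn{p = -K(J-1)} with bulk modulus
#' \eqn{K = \mu/\epsilon}, where the compressibility ratio
#' \eqn{\epsilon = \mu/K} is a small parameter. `epsilon` may be given
#' directly, or as a mesh-dependent policy \eqn{\epsilon = A (\Delta x/L)^\alpha}
#' with exponent \eqn{0 \le \alpha < 2} (the window in which the scheme
#' converges to the incompressible solution); in the latter case call
#' [ac_epsilon()] to resolve the value per mesh.
#'
#' @param epsilon compressibility ratio mu/K (dimensionless), positive.
#' @param Gamma Courant number in (0, 1].
#' @return an object of class `ac_config` with fields `epsilon` and `Gamma`.
#' @export
ac_config <- function(epsilon, Gamma = 0.95) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            Gamma > 0, Gamma <= 1)
  structure(list(epsilon = epsilon, Gamma = Gamma), class = "ac_config")
}

#' @export
print.ac_config <- function(x, ...) {
  nu <- (1 - 2 * x$epsilon / 3) / (2 * (1 + x$epsilon / 3))
  cat(sprintf(
    "Artificial compressibility: epsilon = %g (Poisson ratio %.4g), Gamma = %g\n",
    x$epsilon, nu, x$Gamma))
  invisible(x)
}

#' @rdname ac_config
#' @param A,alpha policy constants of the mesh-dependent rule
#'   \eqn{\epsilon = A(\Delta x/L)^\alpha}.
#' @param dx mesh size (m).
#' @param L domain length (m).
#' @export
ac_epsilon <- function(A, alpha, dx, L) {
  if (alpha < 0 || alpha >= 2)
    stop("the AC exponent must satisfy 0 <= alpha < 2")
  A * (dx / L)^alpha
}

# bulk modulus for a material/AC pair
.bulk_modulus <- function(mat, ac) mat$mu / ac$epsilon
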