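# Closed-form and semi-analytic references: viscoelastic dispersion,
# FFT-synthesised quasi-analytic solutions, von Neumann amplification
# factors, modified-equation order predictions and the compression-shear
# coupling estimate.

# complex relaxation function Q(w) = sum g_l w_l / (w_l + i w)
.relax_Q <- function(omega, mat) {
  if (mat$n_relax == 0L) return(rep(0 + 0i, length(omega)))
  out <- rep(0 + 0i, length(omega))
  for (l in seq_len(mat$n_relax))
    out <- out + mat$g[l] * mat$omega[l] / (mat$omega[l] + 1i * omega)
  out
}

#' Viscoelastic dispersion relation
#'
#' Complex wave speed of infinitesimal harmonic waves
#' \eqn{\propto e^{i(\omega t - \kappa X)}} in the QLV solid with artificial
#' compressibility:
#' \deqn{\frac{c_I(\omega)^2}{c_\infty^2} =
#'   \Big(1 - \sum_\ell \frac{g_\ell\,\omega_\ell}{\omega_\ell + i\omega}\Big)
#'   \Big(1 + \tfrac13 \delta_{I1}\Big) + \frac{1}{\epsilon}\,\delta_{I1},}
#' where the \eqn{1/\epsilon} stiffening of compression waves is purely
#' elastic (the artificial bulk energy carries no relaxation). The branch of
#' the complex square root with positive real part is taken, so right-going
#' waves decay (\eqn{\mathrm{Im}\,\kappa < 0}).
#'
#' The shear branch does not involve \eqn{\epsilon}; its phase velocity
#' tends to `mat$c0` as \eqn{\omega \to 0} and to `mat$c_inf` as
#' \eqn{\omega \to \infty}.
#'
#' @param omega angular frequency (rad/s), positive, vectorised.
#' @param mat a [qlv_material()].
#' @param ac an [ac_config()]; may be NULL for the shear branch.
#' @param mode "shear" or "compression".
#' @return object of class `dispersion_result`: a list with `omega`,
#'   complex speed `c_complex`, wavenumber `kappa`, `phase_velocity`
#'   (\eqn{\omega/\mathrm{Re}\,\kappa}) and `dissipation_factor`
#'   (\eqn{-\mathrm{Im}\,\kappa^2/\mathrm{Re}\,\kappa^2}).
#' @export
dispersion <- function(omega, mat, ac = NULL, mode = c("shear", "compression")) {
  mode <- match.arg(mode)
  stopifnot(all(omega > 0))
  base <- 1 - .relax_Q(omega, mat)
  c2rel <- if (mode == "compression") {
    if (is.null(ac)) stop("the compression branch needs an ac_config")
    base * (4 / 3) + 1 / ac$epsilon
  } else base
  cc <- mat$c_inf * sqrt(c2rel)
  cc <- ifelse(Re(cc) < 0, -cc, cc)
  kappa <- omega / cc
  structure(list(omega = omega, c_complex = cc, kappa = kappa,
                 phase_velocity = omega / Re(kappa),
                 dissipation_factor = -Im(kappa^2) / Re(kappa^2),
                 mode = mode),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion (%s branch), %d frequencies\n", x$mode,
              length(x$omega)))
  utils::head(data.frame(omega = x$omega,
                         phase_velocity = x$phase_velocity,
                         dissipation_factor = x$dissipation_factor))
}

#' Dissipation factor of artificial compression waves
#'
#' Closed form of the compression-wave dissipation factor,
#' \deqn{-\frac{\mathrm{Im}\,\kappa^2}{\mathrm{Re}\,\kappa^2} =
#'  \frac{\sum_\ell g_\ell \omega_\ell \omega/(\omega_\ell^2+\omega^2)}
#'       {1 + \dfrac{3}{4\epsilon} -
#'        \sum_\ell g_\ell \omega_\ell^2/(\omega_\ell^2+\omega^2)}.}
#' It vanishes for any frequency in the incompressible limit
#' \eqn{\epsilon \to 0}: the artificial waves then travel infinitely fast
#' and without attenuation.
#'
#' @param omega angular frequency (rad/s), positive, vectorised.
#' @param mat a [qlv_material()].
#' @param ac an [ac_config()].
#' @return dimensionless dissipation factor.
#' @export
compression_dissipation <- function(omega, mat, ac) {
  num <- numeric(length(omega)); den_s <- 0
  for (l in seq_len(mat$n_relax)) {
    d <- mat$omega[l]^2 + omega^2
    num <- num + mat$g[l] * mat$omega[l] * omega / d
    den_s <- den_s + mat$g[l] * mat$omega[l]^2 / d
  }
  num / (1 + 3 / (4 * ac$epsilon) - den_s)
}

#' Quasi-analytic solution of the forced linear problem
#'
#' Synthesises the right-going velocity field
#' \deqn{v_I(X, t) = \frac{1}{2\pi}\int_0^\infty \mathrm{Re}\Big[
#'   \frac{\hat s(\omega)}{c_I(\omega)}\,
#'   e^{i\omega t - i\kappa(\omega) X}\Big]\,d\omega}
#' by FFT of the source signal (500 samples per period by default,
#' zero-padded by at least 10 extra periods, total length rounded up to a
#' power of two) followed by frequency-domain propagation with the complex
#' speed of [dispersion()]. When the material is elastic the result reduces
#' to the d'Alembert solution \eqn{s(t - X/c)/(2c)}.
#'
#' @param X positions (m), non-negative (right-going branch).
#' @param t evaluation time (s).
#' @param mat a [qlv_material()].
#' @param ac an [ac_config()] (needed for the compression branch).
#' @param mode "shear" or "compression".
#' @param Omega fundamental angular frequency of the signal (rad/s).
#' @param A amplitude multiplier.
#' @param samples_per_period,pad_periods FFT discretisation constants.
#' @return velocity profile at the requested positions (m/s).
#' @export
quasi_analytic_solution <- function(X, t, mat, ac = NULL,
                                    mode = c("shear", "compression"),
                                    Omega, A = 1,
                                    samples_per_period = 500L,
                                    pad_periods = 10L) {
  mode <- match.arg(mode)
  stopifnot(all(X >= 0), t >= 0)
  Tp <- 2 * pi / Omega
  dts <- Tp / samples_per_period
  N <- 2^ceiling(log2(samples_per_period * (1L + pad_periods)))
  tt <- (seq_len(N) - 1L) * dts
  s <- source_signal(tt, Omega, A)
  Shat <- stats::fft(s)
  k <- seq_len(N %/% 2L)           # positive-frequency bins (omega_0 = 0 drops out)
  wk <- 2 * pi * k / (N * dts)
  disp <- dispersion(wk, mat, ac, mode)
  ck <- disp$c_complex
  kap <- disp$kappa
  # resolution guard: the slowest propagated phase must fit in the record
  if (t + max(X) / min(Re(ck)) > N * dts)
    stop("FFT record too short for the requested time and distance; increase pad_periods")
  Hk <- Shat[k + 1L] / ck * exp(1i * wk * t)
  out <- numeric(length(X))
  for (j in seq_along(X))
    out[j] <- sum(Re(Hk * exp(-1i * kap * X[j]))) / N
  out
}

#' Von Neumann amplification factor of the linear LLF scheme
#'
#' Both roots
#' \eqn{\xi = 1 - \Gamma + \Gamma\cos\kappa\Delta x \pm
#'      i\,\Gamma\,(c_I/\bar c)\sin\kappa\Delta x}
#' of the 2x2 eigenproblem obtained by inserting harmonic modes in the
#' scheme's stencil. Under \eqn{0 < \Gamma \le 1} and
#' \eqn{0 < c_I/\bar c \le 1} both satisfy \eqn{|\xi| \le 1} (von Neumann
#' stability); at \eqn{\Gamma = 1} and \eqn{c_I = \bar c} the scheme is
#' exact transport with \eqn{|\xi| = 1}.
#'
#' @param kdx normalised wavenumber \eqn{\kappa\Delta x} in [0, pi],
#'   vectorised.
#' @param Gamma Courant number in (0, 1].
#' @param speed_ratio effective speed ratio \eqn{c_I/\bar c} in (0, 1].
#' @return complex matrix with columns `plus` and `minus`.
#' @export
amplification_factor <- function(kdx, Gamma, speed_ratio) {
  stopifnot(all(kdx >= 0), all(kdx <= pi + 1e-12),
            Gamma > 0, Gamma <= 1, speed_ratio > 0, speed_ratio <= 1)
  re <- 1 - Gamma + Gamma * cos(kdx)
  im <- Gamma * speed_ratio * sin(kdx)
  cbind(plus = complex(real = re, imaginary = im),
        minus = complex(real = re, imaginary = -im))
}

#' Predicted order of accuracy under a mesh-dependent AC parameter
#'
#' Modified-equation analysis of the LLF scheme: when the compressibility
#' ratio scales as \eqn{\epsilon \propto \Delta x^\alpha}, the numerical
#' shear-wave attenuation is of order \eqn{(\kappa\Delta x)^{1-\alpha/2}},
#' so the leading order of accuracy in shear is \eqn{1 - \alpha/2}. The
#' exponent must satisfy \eqn{0 \le \alpha < 2} for the scheme to converge
#' to the incompressible solution.
#'
#' @param alpha AC exponent in [0, 2).
#' @return predicted convergence order.
#' @export
predicted_order <- function(alpha) {
  if (any(alpha < 0) || any(alpha >= 2))
    stop("no convergence window: the AC exponent must satisfy 0 <= alpha < 2")
  1 - alpha / 2
}

#' Coupling-induced compression strain
#'
#' Leading-order estimate of the compression strain generated by nonlinear
#' coupling from a shear strain \eqn{\gamma}:
#' \deqn{\partial_X u_1 \simeq \tfrac13 \epsilon \gamma^2
#'       \big(1 + \tfrac23 \beta \gamma^2\big).}
#'
#' @param gamma shear strain (dimensionless), vectorised.
#' @param epsilon compressibility ratio.
#' @param beta parameter of nonlinearity.
#' @return compression strain estimate.
#' @export
coupling_amplitude <- function(gamma, epsilon, beta) {
  (epsilon / 3) * gamma^2 * (1 + (2 / 3) * beta * gamma^2)
}
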