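# One-dimensional linearised antiplane AC system.
#
# In the infinitesimal-strain elastic limit the split scheme reduces, for
# each polarisation I, to a 2x2 linear system dU/dt + M dU/dX = 0 with
# U = (F_I1, v_I) and M = [[0, -1], [-c_I^2, 0]], where
# c_I^2/c_inf^2 = 1 + (1/3 + 1/eps) * (I == 1). The LLF update then takes
# the closed stencil form
#   U_i^{n+1} = (1 - G) U_i - (G / 2 cbar) M (U_{i+1} - U_{i-1})
#                + (G / 2)(U_{i+1} + U_{i-1}),
# with G the Courant number based on the fastest speed cbar = c_1. This
# module integrates that system directly (first-order LLF or MUSCL-Hancock)
# and provides the exact d'Alembert references used in the accuracy,
# locking and convergence studies.

#' Linear characteristic speed of the AC system
#'
#' @param I polarisation index: 1 = compression (carries the artificial
#'   bulk stiffness), 2 or 3 = shear.
#' @param mat a [qlv_material()] (supplies `c_inf`).
#' @param epsilon compressibility ratio.
#' @return speed (m/s).
#' @export
linear_speed <- function(I, mat, epsilon) {
  mat$c_inf * sqrt(1 + (1 / 3 + 1 / epsilon) * (I == 1))
}

#' Integrate the linearised 1D AC system
#'
#' Marches the 2-component system for one polarisation on a uniform grid
#' with cells at integer multiples of `dx` spanning [-L/2, L/2], with
#' non-reflecting (constant-extrapolation) ghost cells. Two problems are
#' supported: the Cauchy problem whose initial data is the right-going
#' pulse
#' \deqn{U(X,0) = \frac{s(-X/c_I)}{2c_I}\,(-1/c_I,\; 1),}
#' and the forced problem (material initially at rest) where
#' \eqn{s(t^{n+1}) \Delta t/\Delta x} is added to the velocity component of
#' the cell at X = 0 after each step.
#'
#' @param problem "cauchy" or "forced".
#' @param I polarisation (1 compression, 2 or 3 shear).
#' @param mat a [qlv_material()].
#' @param epsilon compressibility ratio (sets the fastest speed c_1 used
#'   for the time step and the LLF dissipation).
#' @param dx mesh size (m).
#' @param L domain length (m).
#' @param Omega fundamental angular frequency of the signal (rad/s).
#' @param A amplitude multiplier.
#' @param t_final final time (s).
#' @param Gamma Courant number.
#' @param reconstruction "none" (first-order LLF) or "muscl_minmod".
#' @return list with cell centres `X`, components `F` and `v`, the final
#'   time `t`, speeds `cI`, `cbar`, and the step count.
#' @export
lin1d_run <- function(problem = c("cauchy", "forced"), I = 2, mat, epsilon,
                      dx, L = 1, Omega, A = 1, t_final,
                      Gamma = 0.95,
                      reconstruction = c("none", "muscl_minmod")) {
  problem <- match.arg(problem)
  reconstruction <- match.arg(reconstruction)
  cI <- linear_speed(I, mat, epsilon)
  cbar <- linear_speed(1, mat, epsilon)
  i_half <- round(L / 2 / dx)
  X <- (-i_half:i_half) * dx
  n <- length(X)
  g <- 2L
  U <- matrix(0, 2L, n + 2L * g)
  ix <- g + seq_len(n)
  if (problem == "cauchy") {
    s0 <- source_signal(-X / cI, Omega, A)
    U[1L, ix] <- -s0 / (2 * cI^2)
    U[2L, ix] <- s0 / (2 * cI)
    if (-2 * pi * cI / Omega < X[1])
      stop("initial pulse support is clipped by the domain")
  }
  i0 <- g + which.min(abs(X))
  dt0 <- Gamma * dx / cbar
  t <- 0; step <- 0L
  nn <- n + 2L * g
  u1 <- U[1L, ]; u2 <- U[2L, ]
  # flux f(U) = (-u2, -cI^2 u1); everything below is plain vector arithmetic
  while (t < t_final - 1e-14) {
    dt <- min(dt0, t_final - t)
    G <- cbar * dt / dx
    mid <- 2:(nn - 1L)
    if (reconstruction == "none") {
      # closed stencil of the LLF update
      n1 <- (1 - G) * u1[mid] + (G / (2 * cbar)) * (u2[mid + 1L] - u2[mid - 1L]) +
        (G / 2) * (u1[mid + 1L] + u1[mid - 1L])
      n2 <- (1 - G) * u2[mid] +
        (G * cI^2 / (2 * cbar)) * (u1[mid + 1L] - u1[mid - 1L]) +
        (G / 2) * (u2[mid + 1L] + u2[mid - 1L])
      u1[mid] <- n1; u2[mid] <- n2
    } else {
      s1 <- c(0, .minmod(u1[mid] - u1[mid - 1L], u1[mid + 1L] - u1[mid]), 0)
      s2 <- c(0, .minmod(u2[mid] - u2[mid - 1L], u2[mid + 1L] - u2[mid]), 0)
      # Hancock predictor advances both faces by half a flux difference,
      # which for f = M U is -(dt/2dx) M sigma
      a1 <- (dt / (2 * dx)) * s2
      a2 <- (dt / (2 * dx)) * cI^2 * s1
      hi1 <- u1 + s1 / 2 + a1; hi2 <- u2 + s2 / 2 + a2
      lo1 <- u1 - s1 / 2 + a1; lo2 <- u2 - s2 / 2 + a2
      iL <- 1:(nn - 1L)
      qL1 <- hi1[iL]; qL2 <- hi2[iL]
      qR1 <- lo1[iL + 1L]; qR2 <- lo2[iL + 1L]
      P1 <- -0.5 * (qL2 + qR2) - 0.5 * cbar * (qR1 - qL1)
      P2 <- -0.5 * cI^2 * (qL1 + qR1) - 0.5 * cbar * (qR2 - qL2)
      u1[mid] <- u1[mid] - (dt / dx) * (P1[mid] - P1[mid - 1L])
      u2[mid] <- u2[mid] - (dt / dx) * (P2[mid] - P2[mid - 1L])
    }
    u1[1:g] <- u1[g + 1L]; u2[1:g] <- u2[g + 1L]
    u1[(n + g + 1L):nn] <- u1[n + g]; u2[(n + g + 1L):nn] <- u2[n + g]
    t <- t + dt; step <- step + 1L
    if (problem == "forced")
      u2[i0] <- u2[i0] + source_signal(t, Omega, A) * dt / dx
  }
  list(X = X, F = u1[ix], v = u2[ix], t = t, cI = cI, cbar = cbar,
       steps = step)
}

#' Exact solutions of the linear 1D problems
#'
#' `lin1d_exact_cauchy()` is the translated right-going pulse
#' \eqn{v_I = s(t - X/c_I)/(2 c_I)}; `lin1d_exact_forced()` is the
#' d'Alembert solution \eqn{v_I = s(t - |X|/c_I)/(2 c_I)} of the forced
#' wave equation with point source at the origin.
#'
#' @param X positions (m).
#' @param t time (s).
#' @param cI wave speed (m/s).
#' @param Omega,A signal parameters.
#' @return list with components `F` and `v` at the cell centres.
#' @export
lin1d_exact_cauchy <- function(X, t, cI, Omega, A = 1) {
  s <- source_signal(t - X / cI, Omega, A)
  list(F = -s / (2 * cI^2), v = s / (2 * cI))
}

#' @rdname lin1d_exact_cauchy
#' @export
lin1d_exact_forced <- function(X, t, cI, Omega, A = 1) {
  s <- source_signal(t - abs(X) / cI, Omega, A)
  list(F = -sign(X) * s / (2 * cI^2), v = s / (2 * cI))
}
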