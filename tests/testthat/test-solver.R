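# Split finite-volume integrator: fluxes, sweeps, reconstruction, Strang
# composition, CFL control.

test_that("physical flux has the stated block structure", {
  f0 <- state_field(1, dx = 0.01, n_relax = 3)
  q <- f0$q[, 1]
  expect_equal(physical_flux(q, 1, ac09, gel), rep(0, 30))
  # linear antiplane state: F31 = gamma at rest; v-flux carries -P31/rho0
  gam <- 1e-6
  q[7] <- gam
  fl <- physical_flux(q, 1, ac09, gel)
  expect_equal(fl[12], -gel$mu * gam / gel$rho0, tolerance = 1e-6)
  expect_equal(fl[13:30], rep(0, 18))  # memory blocks are not transported
  # F-block is exactly linear in v at frozen F
  q2 <- q; q2[10:12] <- c(1, 2, 3)
  fl2 <- physical_flux(q2, 1, ac09, gel)
  expect_equal(fl2[c(1, 4, 7)] - fl[c(1, 4, 7)], -c(1, 2, 3))
  q3 <- q; q3[10:12] <- 2 * c(1, 2, 3)
  expect_equal(physical_flux(q3, 1, ac09, gel)[c(1, 4, 7)] - fl[c(1, 4, 7)],
               -2 * c(1, 2, 3))
})

test_that("LLF flux is consistent and a full sweep matches the closed linear stencil", {
  f0 <- state_field(1, dx = 0.01, n_relax = 0)
  q <- f0$q[, 1]; q[7] <- 1e-7; q[12] <- 1e-7
  expect_equal(llf_flux(q, q, 1, 2.5, ac09, gel_el),
               physical_flux(q, 1, ac09, gel_el))
  # random infinitesimal antiplane data: the sweep must reproduce
  #   U^{n+1} = (1-G) U - (G/2cbar) M (U_+ - U_-) + (G/2)(U_+ + U_-)
  set.seed(29)
  n <- 24
  amp <- 1e-8
  F31 <- stats::rnorm(n, sd = amp); v3 <- stats::rnorm(n, sd = amp)
  fld <- state_field(n, dx = 2e-3, n_relax = 0)
  ic <- softshock:::.interior_cols(fld)
  fld$q[7, ic] <- F31; fld$q[12, ic] <- v3
  fld <- fill_ghosts(fld)
  cbar <- max_wave_speed(fld, ac09, gel_el)
  expect_equal(cbar, linear_speed(1, gel_el, 0.9), tolerance = 1e-6)
  G <- 0.95
  dt <- G * 2e-3 / cbar
  out <- sweep(fld, 1, dt, scheme_config("none", Gamma = G), ac09, gel_el)
  cI <- gel_el$c_inf
  M <- matrix(c(0, -cI^2, -1, 0), 2)
  U <- rbind(c(F31[1], F31, F31[n]), c(v3[1], v3, v3[n]))  # with ghosts
  i <- 2:(n + 1)
  Unew <- (1 - G) * U[, i] - (G / (2 * cbar)) * M %*% (U[, i + 1] - U[, i - 1]) +
    (G / 2) * (U[, i + 1] + U[, i - 1])
  expect_equal(out$q[7, ic], Unew[1, ], tolerance = 1e-6)
  expect_equal(out$q[12, ic], Unew[2, ], tolerance = 1e-6)
})

test_that("minmod reconstruction is exact on linear data and flat at extrema", {
  q <- c(1, 2, 4)
  r <- muscl_reconstruct(q_minus = q - 1, q_0 = q, q_plus = q + 1)
  expect_equal(r$left, q - 0.5)
  expect_equal(r$right, q + 0.5)
  r <- muscl_reconstruct(q_minus = 0, q_0 = 1, q_plus = 0)  # local maximum
  expect_equal(r$left, 1)
  expect_equal(r$right, 1)
  r <- muscl_reconstruct(q_minus = 0, q_0 = 1, q_plus = 5)  # limited slope
  expect_equal(r$right - r$left, 1)
})

test_that("periodic sweeps conserve every component to round-off", {
  set.seed(31)
  n <- 32
  fld <- state_field(n, dx = 0.01, n_relax = 0, bc = "periodic")
  ic <- softshock:::.interior_cols(fld)
  fld$q[7, ic] <- 1e-3 * sin(2 * pi * (1:n) / n)
  fld$q[12, ic] <- 1e-3 * cos(2 * pi * (1:n) / n)
  fld <- fill_ghosts(fld)
  for (recon in c("none", "muscl_minmod")) {
    f <- fld
    sums0 <- rowSums(f$q[, ic])
    sch <- scheme_config(recon, Gamma = 0.9)
    for (step in 1:100) {
      sp <- softshock:::.dir_speeds(f$q, 1L, ac09, gel_el)
      dt <- cfl_dt(max(sp), sch, c(0.01, NA, NA))
      f <- sweep(f, 1, dt, sch, ac09, gel_el, speeds = sp)
    }
    sums1 <- rowSums(f$q[, ic])
    expect_lt(max(abs(sums1 - sums0) / pmax(abs(sums0), 1)), 1e-12)
  }
})

test_that("uniform fields are invariant under sweeps and Strang steps", {
  fld <- state_field(8, 4, dx = 0.01, n_relax = 0)
  fld <- fill_ghosts(fld)
  q0 <- fld$q
  sch <- scheme_config("muscl_minmod")
  out <- strang_step(fld, 1e-3, sch, ac09, gel_el, t = 0)
  expect_equal(out$q, q0, tolerance = 1e-14)
})

test_that("relaxation half-steps compose into one exact full step on uniform fields", {
  set.seed(37)
  fld <- state_field(4, dx = 0.01, n_relax = 3)
  Sv <- lapply(1:3, function(l) rand_sym(sd = 10))
  for (l in 1:3)
    fld$q[12 + 6 * (l - 1) + 1:6, ] <- sym6_pack(Sv[[l]])
  fld <- fill_ghosts(fld)
  dt <- 2e-4
  out <- strang_step(fld, dt, scheme_config("none"), ac09, gel, t = 0)
  # spatially uniform: transport does nothing, only relaxation acts;
  # two exact half-steps must equal one exact full step
  SDe <- dev_lagrangian(elastic_stress_bar(diag(3), gel), diag(3))
  for (l in 1:3) {
    e <- exp(-gel$omega[l] * dt)
    expect_equal(sym6_unpack(out$q[12 + 6 * (l - 1) + 1:6, 1]),
                 e * Sv[[l]] + (1 - e) * gel$g[l] * SDe, tolerance = 1e-13)
  }
})

test_that("CFL step follows Gamma * min(dx) / cbar and the cost drivers", {
  sch <- scheme_config("none", Gamma = 0.95)
  expect_equal(cfl_dt(2.56, sch, c(2e-3, NA, NA)), 0.95 * 2e-3 / 2.56)
  expect_equal(cfl_dt(2.56, sch, c(2e-3, 1e-3, 4e-3)), 0.95 * 1e-3 / 2.56)
  expect_equal(cfl_dt(1, sch, c(1e-3, NA, NA)) / cfl_dt(1, sch, c(5e-4, NA, NA)), 2)
  expect_error(cfl_dt(0, sch, c(1e-3, NA, NA)), "positive")
  # dt shrinks as eps decreases, through the artificial wave speed
  f <- state_field(2, dx = 1e-3)
  dts <- sapply(c(0.9, 0.1, 0.02), function(eps)
    cfl_dt(max_wave_speed(f, ac_config(eps), gel_el), sch, c(1e-3, NA, NA)))
  expect_true(all(diff(dts) < 0))
})

test_that("full solver at infinitesimal amplitude matches the linear path", {
  mat <- gel_el
  Om <- 16 * pi * mat$c_inf
  cfg <- list(problem = "nonlinear_1d", mat = mat, dx = 4e-3, L = 1,
              epsilon = 0.9, Gamma = 0.95, Omega = Om, amplitude = 1e-6,
              final_time = 0.08, scheme = "muscl")
  full <- run_experiment(cfg)
  lin <- lin1d_run("forced", 2, mat, 0.9, 4e-3, 1, Om, A = 1e-6,
                   t_final = 0.08, reconstruction = "muscl_minmod")
  expect_equal(full$X, lin$X)
  expect_lt(max(abs(full$v - lin$v)) / max(abs(lin$v)), 1e-4)
})

test_that("viscoelastic 1D solution converges towards the FFT reference", {
  Om <- 16 * pi * gel$c_inf
  A <- 1e-3   # infinitesimal regime: the reference is linear viscoelastic
  errs <- sapply(c(8, 4, 2) * 1e-3, function(dx) {
    cfg <- list(problem = "viscoelastic_1d", mat = gel, dx = dx, L = 1,
                epsilon = 0.9, Gamma = 0.95, Omega = Om, amplitude = A,
                final_time = 0.12, scheme = "muscl")
    r <- run_experiment(cfg)
    keep <- r$X > 0.02 & r$X < 0.47
    ref <- quasi_analytic_solution(r$X[keep], 0.12, gel, NULL, "shear", Om,
                                   A = A)
    sqrt(sum((r$v[keep] - ref)^2) / sum(ref^2))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.2)
})

test_that("shear shocks steepen with amplitude and stay oscillation-free", {
  # the viscoelastic shock-formation run: large amplitudes develop much
  # steeper shear fronts than small ones, and the minmod limiter keeps the
  # total variation from growing once the source is off
  Om <- 16 * pi * gel$c_inf
  run_amp <- function(A, t_final, dx = 2e-3) {
    cfg <- list(problem = "nonlinear_1d", mat = gel, dx = dx, L = 1,
                epsilon = 0.9, Gamma = 0.95, Omega = Om, amplitude = A,
                final_time = t_final, scheme = "muscl")
    run_experiment(cfg)
  }
  r05 <- run_amp(0.5, 0.08, dx = 1e-3)
  r2 <- run_amp(2, 0.08, dx = 1e-3)
  steep <- function(r) max(abs(diff(r$v))) / (r$X[2] - r$X[1])
  expect_gt(steep(r2) / (4 * steep(r05)), 1.25)  # > 5x gradient growth
  tv <- function(r) sum(abs(diff(r$v)))
  a <- run_amp(2, 0.09); b <- run_amp(2, 0.11)
  expect_lt(tv(b), tv(a) * 1.01)
})
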