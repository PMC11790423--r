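# Constitutive law: strain measures, stresses, pressure, relaxation.

test_that("strain invariants match hand-evaluated cases", {
  expect_equal(strain_invariants(diag(3)), c(I1 = 3, I2 = 3))
  expect_equal(strain_invariants(diag(c(4, 1, 1))), c(I1 = 6, I2 = 9))
  # simple shear F31 = 0.5: I1 = 3 + gamma^2
  F <- diag(3); F[3, 1] <- 0.5
  expect_equal(unname(strain_invariants(t(F) %*% F)[1]), 3.25)
  expect_error(strain_invariants(matrix(1:9, 3)), "symmetric")
})

test_that("material constructor derives the printed gelatin constants", {
  expect_equal(gel$mu, 2684)
  expect_equal(gel$beta, 4.4)
  expect_equal(gel$c_inf, sqrt(2.684), tolerance = 1e-12)
  expect_equal(gel$c0, gel$c_inf * sqrt(1 - sum(gel$g)), tolerance = 1e-12)
  expect_error(qlv_material(rho0 = -1, C10 = 1), "rho0")
  expect_error(qlv_material(rho0 = 1, C10 = 1, g = c(0.6, 0.5),
                            omega = c(1, 2)), "sum")
})

test_that("Rivlin coefficients from (mu, beta) reproduce the gelatin fit", {
  cf <- convert_elastic_params(2684, 4.4)
  expect_equal(cf$C10, 1342)
  expect_equal(cf$C20, 1968, tolerance = 1e-3)
  # neo-Hookean limit and round-trip through the derived fields
  expect_equal(convert_elastic_params(1000, 0)$C20, 0)
  m <- qlv_material(1000, cf$C10, 0, cf$C20)
  expect_equal(m$mu, 2684)
  expect_equal(m$beta, 4.4)
  expect_error(convert_elastic_params(100, 1, C01 = 60), "positive")
})

test_that("isochoric elastic stress matches limits and the energy oracle", {
  expect_equal(elastic_stress_bar(diag(3), gel),
               2 * (gel$C10 + 2 * gel$C01) * diag(3))
  nh <- qlv_material(1000, C10 = 500)
  Cb <- diag(c(2, 1, 0.5))
  expect_equal(elastic_stress_bar(Cb, nh), 2 * 500 * diag(3))
  # finite-difference oracle 2 dW/dC on a sheared unimodular strain
  F <- diag(3); F[3, 1] <- 0.3
  C <- t(F) %*% F
  Wb <- function(C) {
    I1 <- sum(diag(C)); I2 <- (I1^2 - sum(diag(C %*% C))) / 2
    gel$C10 * (I1 - 3) + gel$C01 * (I2 - 3) + gel$C20 * (I1 - 3)^2
  }
  h <- 1e-6
  Sfd <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Cp <- C; Cm <- C
    Cp[i, j] <- Cp[i, j] + h / 2; Cp[j, i] <- Cp[j, i] + h / 2
    Cm[i, j] <- Cm[i, j] - h / 2; Cm[j, i] <- Cm[j, i] - h / 2
    Sfd[i, j] <- 2 * (Wb(Cp) - Wb(Cm)) / (2 * h)
  }
  Se <- elastic_stress_bar(C, gel)
  expect_lt(max(abs(Se - Sfd)) / max(abs(Se)), 1e-6)
  expect_error(elastic_stress_bar(2 * diag(3), gel), "unimodular")
})

test_that("deviatoric projection annihilates the C-contraction", {
  expect_equal(dev_lagrangian(diag(3), diag(3)), matrix(0, 3, 3))
  set.seed(42)
  for (k in 1:10) {
    A <- rand_sym()
    C <- A %*% A + 3 * diag(3)  # symmetric positive definite
    S <- rand_sym()
    R <- dev_lagrangian(S, C)
    expect_lt(abs(sum(R * C)), 1e-10 * max(abs(S)) * max(abs(C)))
    # fixed point: already projected tensors pass through unchanged
    expect_equal(dev_lagrangian(R, C), R, tolerance = 1e-12)
  }
  R <- dev_lagrangian(diag(c(1, 2, 3)), diag(c(2, 1, 1)))
  expect_lt(abs(sum(R * diag(c(2, 1, 1)))), 1e-12)
})

test_that("AC pressure is the linear odd law p = -K(J-1)", {
  expect_equal(ac_pressure(1, ac09, gel), 0)
  expect_equal(ac_pressure(0.99, ac09, gel), 2684 / 0.9 * 0.01,
               tolerance = 1e-12)
  J <- c(0.7, 0.95, 1.2)
  expect_equal(ac_pressure(J, ac09, gel) + ac_pressure(2 - J, ac09, gel),
               rep(0, 3))
  expect_error(ac_pressure(-0.1, ac09, gel), "inversion")
})

test_that("total stress vanishes in the reference state and is -sum(Sv) at identity", {
  ts <- total_stress(diag(3), NULL, ac09, gel)
  expect_equal(ts$S, matrix(0, 3, 3))
  expect_equal(ts$P, matrix(0, 3, 3))
  set.seed(7)
  mem <- lapply(1:3, function(l) rand_sym())
  ts <- total_stress(diag(3), mem, ac09, gel)
  expect_equal(ts$S, -Reduce(`+`, mem), tolerance = 1e-12)
})

test_that("antiplane shear stress reproduces the cubic truncation in both elastic limits", {
  for (gam in c(0.05, 0.1)) {
    F <- diag(3); F[3, 1] <- gam
    # fast limit: memory variables stay zero -> instantaneous modulus mu
    P <- total_stress(F, NULL, ac09, gel)$P
    expect_equal(P[3, 1], gel$mu * (gam + 2 / 3 * gel$beta * gam^3),
                 tolerance = 1e-10)
    # slow limit: memory variables at equilibrium g_l * Dev(Se_bar)
    Cb <- t(F) %*% F       # antiplane shear is isochoric
    SDe <- dev_lagrangian(elastic_stress_bar(Cb, gel), Cb)
    mem <- lapply(seq_len(gel$n_relax), function(l) gel$g[l] * SDe)
    P <- total_stress(F, mem, ac09, gel)$P
    expect_equal(P[3, 1],
                 (1 - sum(gel$g)) * gel$mu * (gam + 2 / 3 * gel$beta * gam^3),
                 tolerance = 1e-10)
  }
})

test_that("P equals the energy gradient dW/dF for random compressible states", {
  set.seed(11)
  for (k in 1:20) {
    F <- rand_unimodular() * (1 + stats::rnorm(1, sd = 0.02))
    P <- total_stress(F, NULL, ac09, gel_el)$P
    Pfd <- fd_stress(F, gel_el, ac09)
    expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-5)
  }
  expect_error(total_stress(-diag(3), NULL, ac09, gel), "inversion")
})

test_that("AC stress approaches the incompressible deviatoric stress as eps -> 0", {
  # at det F = 1 the volumetric term drops out: the AC stress is
  # independent of eps and equals the incompressible deviatoric stress
  set.seed(23)
  F <- rand_unimodular(sd = 0.05)
  S_tight <- total_stress(F, NULL, ac_config(1e-4), gel_el)$S
  S_09 <- total_stress(F, NULL, ac09, gel_el)$S
  expect_equal(S_tight, S_09, tolerance = 1e-10)
  C <- t(F) %*% F
  S_inc <- dev_lagrangian(elastic_stress_bar(C, gel_el), C)
  expect_equal(S_09, S_inc, tolerance = 1e-10)
  # an imposed volumetric perturbation produces a deviation that scales
  # linearly with its size
  d <- 1e-4
  dev1 <- max(abs(total_stress(F * (1 + d), NULL, ac09, gel_el)$S - S_09))
  dev2 <- max(abs(total_stress(F * (1 + 2 * d), NULL, ac09, gel_el)$S - S_09))
  expect_equal(dev2 / dev1, 2, tolerance = 0.05)
})

test_that("relaxation update is exact, stable and trace-free preserving", {
  set.seed(3)
  SDe <- rand_sym()
  SDe <- SDe - sum(diag(SDe)) / 3 * diag(3)  # trace-free driver
  mem0 <- lapply(1:3, function(l) {
    M <- rand_sym(); M - sum(diag(M)) / 3 * diag(3)
  })
  expect_equal(relax_update(mem0, SDe, 0, gel), mem0)
  # equilibrium fixed point
  meq <- lapply(seq_len(gel$n_relax), function(l) gel$g[l] * SDe)
  expect_equal(relax_update(meq, SDe, 0.37, gel), meq, tolerance = 1e-14)
  # dt -> infinity contracts onto the equilibrium
  expect_equal(relax_update(mem0, SDe, 1e6, gel), meq, tolerance = 1e-12)
  # trace-free inputs stay trace-free
  up <- relax_update(mem0, SDe, 1e-3, gel)
  for (l in 1:3) expect_lt(abs(sum(diag(up[[l]]))), 1e-14)
  # semigroup property: two half steps equal one full step exactly
  half2 <- relax_update(relax_update(mem0, SDe, 5e-4, gel), SDe, 5e-4, gel)
  expect_equal(half2, relax_update(mem0, SDe, 1e-3, gel), tolerance = 1e-14)
})

test_that("relaxation update agrees with an adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(5)
  SDe <- rand_sym()
  mem0 <- lapply(1:3, function(l) rand_sym())
  dt <- 1e-3
  up <- relax_update(mem0, SDe, dt, gel)
  for (l in 1:3) {
    rhs <- function(t, y, p)
      list(gel$omega[l] * (gel$g[l] * as.vector(SDe) - y))
    sol <- deSolve::ode(as.vector(mem0[[l]]), c(0, dt), rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
    expect_lt(max(abs(matrix(sol[2, -1], 3) - up[[l]])) /
                max(abs(up[[l]])), 1e-9)
  }
})
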