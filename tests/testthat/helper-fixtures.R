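# Shared fixtures: gelatin material presets and random tensor generators.

gel <- qlv_gelatin()
gel_el <- qlv_gelatin(elastic = TRUE)
ac09 <- ac_config(0.9)

# random unimodular deformation gradient near the identity
rand_unimodular <- function(sd = 0.1) {
  F <- diag(3) + matrix(stats::rnorm(9, sd = sd), 3L, 3L)
  F / det(F)^(1 / 3)
}

rand_sym <- function(sd = 1) {
  M <- matrix(stats::rnorm(9, sd = sd), 3L, 3L)
  (M + t(M)) / 2
}

# scalar strain energy of the weakly compressible Mooney-Rivlin/Yeoh solid,
# used as an independent differentiation oracle for the stress
mry_energy <- function(F, mat, ac) {
  J <- det(F)
  C <- t(F) %*% F
  Cb <- J^(-2 / 3) * C
  I1b <- sum(diag(Cb))
  I2b <- (I1b^2 - sum(diag(Cb %*% Cb))) / 2
  K <- mat$mu / ac$epsilon
  0.5 * K * (J - 1)^2 + mat$C10 * (I1b - 3) + mat$C01 * (I2b - 3) +
    mat$C20 * (I1b - 3)^2
}

# central-difference first Piola-Kirchhoff stress dW/dF
fd_stress <- function(F, mat, ac, h = 1e-6) {
  P <- matrix(0, 3L, 3L)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (mry_energy(Fp, mat, ac) - mry_energy(Fm, mat, ac)) / (2 * h)
  }
  P
}
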