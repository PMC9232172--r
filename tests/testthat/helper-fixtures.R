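# shared fixture builders and oracles for the suite

solid_params <- function(...) mech_params(0.12, 0.04, ...)
fluid_params <- function(...) mech_params(0.01, 0.025, ...)

# per-cell energy of the regular-hexagon lattice as a function of area
# (independent oracle for the ground state and bulk modulus)
hex_cell_energy <- function(A, lambda, gamma) {
  L <- sqrt(24 * A / sqrt(3))
  0.5 * (A - 1)^2 + lambda * L / 2 + gamma * L^2 / 2
}

# numerical bulk modulus: second derivative of per-cell energy under
# isotropic linear strain, divided by the ground-state area
numerical_bulk_modulus <- function(lambda, gamma, h = 1e-4) {
  gs <- ground_state(lambda, gamma)
  f <- function(e) hex_cell_energy(gs$A_g * (1 + e)^2, lambda, gamma)
  (f(h) - 2 * f(0) + f(-h)) / h^2 / gs$A_g
}

# numerical shear modulus: area-preserving stretch of the honeycomb unit
# cell with the internal sublattice offset relaxed; see the methods
# vignette for the strain convention (factor 3/2)
numerical_shear_modulus <- function(lambda, gamma, h = 1e-3) {
  gs <- ground_state(lambda, gamma)
  ang <- pi / 6 + (0:5) * pi / 3
  P <- cbind(cos(ang), sin(ang)) * gs$l_g
  shear_energy <- function(e) {
    F <- diag(c(1 + e, 1 / (1 + e)))
    obj <- function(d) {
      Q <- P %*% t(F)
      Q[c(2, 4, 6), 1] <- Q[c(2, 4, 6), 1] + d[1]
      Q[c(2, 4, 6), 2] <- Q[c(2, 4, 6), 2] + d[2]
      A <- 0.5 * sum(Q[, 1] * Q[c(2:6, 1), 2] - Q[c(2:6, 1), 1] * Q[, 2])
      L <- sum(sqrt(rowSums((Q[c(2:6, 1), ] - Q)^2)))
      0.5 * (A - 1)^2 + lambda * L / 2 + gamma * L^2 / 2
    }
    stats::optim(c(0, 0), obj, method = "BFGS",
                 control = list(reltol = 1e-14))$value
  }
  1.5 * (shear_energy(h) - 2 * shear_energy(0) + shear_energy(-h)) / h^2 /
    gs$A_g
}

# a small randomized multi-type mesh for gradient checks
random_test_mesh <- function(seed = 1, n = 19, jitter = 0.02) {
  set.seed(seed)
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(n, gs$l_g)
  m$type[sample(length(m$cells), max(1, n %/% 4))] <- 1L
  m$vertices <- m$vertices +
    matrix(rnorm(length(m$vertices), 0, jitter), ncol = 2)
  m
}
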