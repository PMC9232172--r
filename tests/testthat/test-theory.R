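test_that("ground state matches the 1D energy-minimization oracle", {
  # oracle: minimize the per-cell hexagon energy over the area directly
  for (p in list(c(0, 0), c(0.12, 0.04), c(0.01, 0.025), c(0.06, 0.055))) {
    gs <- ground_state(p[1], p[2])
    opt <- optimize(hex_cell_energy, c(1e-4, 1.5),
                    lambda = p[1], gamma = p[2], tol = 1e-12)
    expect_equal(gs$A_g, opt$minimum, tolerance = 1e-6)
    expect_equal(gs$A_g, sqrt(3) / 24 * gs$L_g^2, tolerance = 1e-12)
    expect_equal(gs$l_g, gs$L_g / 6)
    expect_lte(gs$A_g, 1 + 1e-12)
  }
  # zero-tension limit: preferred area recovered exactly
  gs0 <- ground_state(0, 0)
  expect_equal(gs0$A_g, 1, tolerance = 1e-12)
  expect_equal(gs0$L_g, sqrt(8 * sqrt(3)), tolerance = 1e-12)
})

test_that("ground-state values for the published parameter sets", {
  gs <- ground_state(0.12, 0.04)
  expect_equal(gs$L_g, 2.8244, tolerance = 1e-4)
  expect_equal(gs$A_g, 0.5757, tolerance = 1e-3)
  gf <- ground_state(0.01, 0.025)
  expect_equal(gf$L_g, 3.3637, tolerance = 1e-4)
  expect_equal(gf$A_g, 0.8166, tolerance = 1e-3)
})

test_that("elastic moduli agree with numerical strain-response oracles", {
  sets <- list(c(0.12, 0.04), c(0.01, 0.025), c(0.01, 0.047), c(0.01, 0.069),
               c(0.06, 0.015), c(0.06, 0.035), c(0.06, 0.055),
               c(0.12, 0.015), c(0.12, 0.021))
  for (p in sets) {
    mod <- elastic_moduli(p[1], p[2])
    expect_equal(mod[["K"]], numerical_bulk_modulus(p[1], p[2]),
                 tolerance = 0.05)
    Gnum <- numerical_shear_modulus(p[1], p[2])
    expect_equal(mod[["G"]], Gnum, tolerance = 0.05)
  }
  # zero-tension closed forms
  expect_equal(unname(elastic_moduli(0, 0)), c(4, 0), tolerance = 1e-10)
})

test_that("K and G are negatively correlated over the parameter grid", {
  grid <- expand.grid(lambda = seq(0.01, 0.12, length.out = 8),
                      gamma = seq(0.015, 0.07, length.out = 8))
  mods <- t(mapply(elastic_moduli, grid$lambda, grid$gamma))
  expect_lt(cor(mods[, 1], mods[, 2]), -0.8)
})

test_that("hexagon constant and interfacial count", {
  k <- hexagon_constant()
  expect_equal(k, 0.62043, tolerance = 1e-4)
  # oracle: area of a regular hexagon with edge k*sqrt(a) is a
  a <- 0.7
  r <- k * sqrt(a)
  expect_equal(3 * sqrt(3) / 2 * r^2, a, tolerance = 1e-12)
  expect_equal(interfacial_count(100), sqrt(2 * sqrt(3) * pi * 100),
               tolerance = 1e-12)
  expect_equal(interfacial_count(100), 33.0, tolerance = 1e-2)
})

test_that("force-balance coefficients and published anchor values", {
  gs <- ground_state(0.12, 0.04)
  n <- interfacial_count(100)
  q <- force_balance_coefficients(gs$A_g, gs$L_g, 0.12, 0.04, mu = 1, n = n)
  expect_equal(q[["q1"]], 0.1043, tolerance = 1e-3)
  # Gamma = 0 simplifications
  q0 <- force_balance_coefficients(0.5, 2.6, 0.1, 0, mu = 1, n = 10)
  expect_equal(q0[["q1"]], 0.5 / 3)
  expect_equal(q0[["q2"]], pi * 0.1 / (2 * 10 * hexagon_constant()))
  expect_gt(q0[["q2"]], 0)
})

test_that("cubic roots and stability labels", {
  # factorization oracle: q1 = 1, q2 = 0 -> u(u^2 - 3) = 0
  eq <- solve_force_balance(1, 0)
  expect_equal(sort(eq$u), c(-sqrt(3), 0, sqrt(3)), tolerance = 1e-9)
  expect_true(eq$stable[eq$u > 1])
  expect_false(eq$stable[abs(eq$u) < 1e-9])
  # saddle-node at q2 = q1^{3/2}: double root at sqrt(q1)
  eq2 <- solve_force_balance(1, 1)
  pos <- eq2$u[eq2$u > 0.5]
  expect_equal(pos, rep(1, length(pos)), tolerance = 1e-5)
  # two positive roots for 0 < q2 < q1^{3/2}: larger stable, smaller not
  eq3 <- solve_force_balance(1, 0.5)
  pos <- eq3[eq3$u > 0, ]
  expect_equal(nrow(pos), 2)
  expect_true(pos$stable[which.max(pos$u)])
  expect_false(pos$stable[which.min(pos$u)])
})

test_that("ring force is an exact factor of the cubic", {
  set.seed(4)
  for (i in 1:20) {
    A_N <- runif(1, 0.3, 1); L_N <- sqrt(24 * A_N / sqrt(3))
    lam <- runif(1, 0.005, 0.15); gam <- runif(1, 0.005, 0.08)
    mu <- runif(1, 1, 6); n <- runif(1, 5, 40)
    k <- hexagon_constant()
    q <- force_balance_coefficients(A_N, L_N, lam, gam, mu, n, k)
    u <- runif(5, 0.05, 1.2)
    F <- ring_net_force(u, A_N, L_N, lam, gam, mu, n, k)
    expect_equal(F, -2 * k * (u^3 - 3 * q[["q1"]] * u + 2 * q[["q2"]]),
                 tolerance = 1e-12)
  }
  # contractility is compressive: dF/dmu < 0
  F1 <- ring_net_force(0.7, 0.58, 2.82, 0.12, 0.04, 2, 20)
  F2 <- ring_net_force(0.7, 0.58, 2.82, 0.12, 0.04, 3, 20)
  expect_lt(F2, F1)
})

test_that("critical point: saddle-node consistency and published anchors", {
  k <- hexagon_constant()
  for (p in list(c(0.12, 0.04), c(0.01, 0.025))) {
    gs <- ground_state(p[1], p[2])
    n <- interfacial_count(100)
    cp <- critical_point(gs$A_g, gs$L_g, p[1], p[2], n, k)
    expect_true(cp$bifurcates)
    # at mu = mu2 the cubic has a (numerically) double positive root sqrt(q1)
    mu2 <- cp$mu2_lambda / p[1]
    q <- force_balance_coefficients(gs$A_g, gs$L_g, p[1], p[2], mu2, n, k)
    disc <- q[["q2"]]^2 - q[["q1"]]^3
    expect_lt(abs(disc), 1e-10)
    eq <- solve_force_balance(q[["q1"]], q[["q2"]])
    expect_equal(max(eq$u), sqrt(cp$q1), tolerance = 1e-4)
  }
  cp_s <- critical_point(ground_state(0.12, 0.04)$A_g,
                         ground_state(0.12, 0.04)$L_g,
                         0.12, 0.04, interfacial_count(100), k)
  expect_equal(cp_s$rho2, 9.59, tolerance = 0.01)
  expect_equal(cp_s$mu2_lambda, 1.51, tolerance = 0.01)
  cp_f <- critical_point(ground_state(0.01, 0.025)$A_g,
                         ground_state(0.01, 0.025)$L_g,
                         0.01, 0.025, interfacial_count(100), k)
  expect_equal(cp_f$rho2, 4.60, tolerance = 0.01)
  expect_equal(cp_f$mu2_lambda, 2.12, tolerance = 0.01)
  # no bifurcation when q1 <= 0
  cp0 <- critical_point(0.1, 1.2, 0.12, 0.04, 10, k)
  expect_false(cp0$bifurcates)
  expect_true(is.na(cp0$rho2))
})

test_that("mu1_from_rho1 inverts the cubic", {
  gs <- ground_state(0.12, 0.04)
  n <- interfacial_count(100)
  k <- hexagon_constant()
  cp <- critical_point(gs$A_g, gs$L_g, 0.12, 0.04, n, k)
  # coincident criticalities
  expect_equal(mu1_from_rho1(cp$rho2, gs$A_g, gs$L_g, 0.12, 0.04, n, k),
               cp$mu2_lambda, tolerance = 1e-10)
  # round trip: the stable root at mu1 sits at rho1^{-1/2}
  rho1 <- 3
  mu1l <- mu1_from_rho1(rho1, gs$A_g, gs$L_g, 0.12, 0.04, n, k)
  q <- force_balance_coefficients(gs$A_g, gs$L_g, 0.12, 0.04, mu1l / 0.12,
                                  n, k)
  eq <- solve_force_balance(q[["q1"]], q[["q2"]])
  st <- eq$u[eq$stable & eq$u > 0]
  expect_equal(max(st), rho1^-0.5, tolerance = 1e-8)
  # rho1 < rho2 (less compression needed) => mu1 < mu2
  expect_lt(mu1l, cp$mu2_lambda)
  # a rho1 below the ground-state density needs mu < 1: diagnostic warning
  expect_warning(
    mu1_from_rho1(1.2, gs$A_g, gs$L_g, 0.12, 0.04, n, k), "below baseline")
})

test_that("Scenario 2 calibration recovers the ground state in the limit", {
  n <- interfacial_count(100)
  for (p in list(c(0.12, 0.04), c(0.01, 0.025))) {
    gs <- ground_state(p[1], p[2])
    cal <- scenario2_interface_calibration(gs$A_g, p[1], p[2], n)
    # mu = 1 equilibrium near the ground state (approximation-level check)
    expect_equal(cal$L_N, gs$L_g, tolerance = 0.15)
    # denser onset (a0 < A_g) => smaller interfacial normal cells
    cal2 <- scenario2_interface_calibration(0.8 * gs$A_g, p[1], p[2], n)
    expect_lt(cal2$A_N, cal$A_N)
    # downstream: Scenario 2 critical contractility below Scenario 1
    cp1 <- critical_point(gs$A_g, gs$L_g, p[1], p[2], n)
    cp2 <- critical_point(cal2$A_N, cal2$L_N, p[1], p[2], n)
    if (cp2$bifurcates) expect_lt(cp2$mu2_lambda, cp1$mu2_lambda)
  }
})

test_that("rho_MCE ordering and parameter dependence", {
  for (p in list(c(0.12, 0.04), c(0.01, 0.025), c(0.06, 0.055),
                 c(0.06, 0.035))) {
    r <- vapply(3:5, rho_mce, 0, lambda = p[1], gamma = p[2])
    expect_true(all(diff(r) > 0))   # rho_MCE(3) < rho_MCE(4) < rho_MCE(5)
    expect_true(all(r > 0))
  }
  expect_error(rho_mce(6, 0.12, 0.04))
})

test_that("rho1 regression: self-consistency and linearity", {
  sets <- list(c(0.12, 0.04), c(0.01, 0.025), c(0.01, 0.047),
               c(0.01, 0.069), c(0.06, 0.015), c(0.06, 0.035),
               c(0.06, 0.055), c(0.12, 0.015), c(0.12, 0.021))
  X <- t(vapply(sets, function(p)
    vapply(3:5, rho_mce, 0, lambda = p[1], gamma = p[2]), numeric(3)))
  c_true <- c(0.3, 0.5, 0.1)
  rho1 <- as.numeric(X %*% c_true)
  fit <- rho1_regression(rho1, X)
  expect_equal(unname(fit$coefficients), c_true, tolerance = 1e-8)
  expect_equal(fit$fitted, rho1, tolerance = 1e-8)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # linearity of the predictor
  expect_equal(fit$predict(2 * X), 2 * fit$fitted, tolerance = 1e-10)
  expect_error(rho1_regression(rho1, X[, c(1, 1, 1)]))
})

test_that("scaling variable", {
  expect_equal(scaling_variable(0.12, 1, 100), 0)
  expect_equal(scaling_variable(0.12, 3, 100), 0.12 * 2 / 10)
  # quadrupling N_theta halves the variable
  expect_equal(scaling_variable(0.12, 3, 400),
               scaling_variable(0.12, 3, 100) / 2)
})
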