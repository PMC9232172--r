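test_that("edge line tension: type rules and contractility", {
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(7, gs$l_g)
  m$type[1] <- 1L   # central cell abnormal
  p <- solid_params(mu = 5)
  ed <- mesh_edges(m)
  interf <- which(!is.na(ed$c2) & (m$type[ed$c1] != m$type[ed$c2]))[1]
  bulk <- which(!is.na(ed$c2) & m$type[ed$c1] == 0L & m$type[ed$c2] == 0L)[1]
  bnd <- which(is.na(ed$c2))[1]
  expect_equal(edge_line_tension(m, p, ed$v1[bulk], ed$v2[bulk]), 0.12)
  expect_equal(edge_line_tension(m, p, ed$v1[interf], ed$v2[interf]), 0.60)
  expect_equal(edge_line_tension(m, p, ed$v1[interf], ed$v2[interf],
                                 contractility_active = FALSE), 0.12)
  expect_equal(edge_line_tension(m, p, ed$v1[bnd], ed$v2[bnd]), 0.12)
  # mu = 1: interfacial equals bulk
  p1 <- solid_params(mu = 1)
  expect_equal(edge_line_tension(m, p1, ed$v1[interf], ed$v2[interf]), 0.12)
  # unequal per-type Lambda: arithmetic-mean base
  pm <- mech_params(lambda_normal = 0.12, lambda_abnormal = 0.04,
                    gamma = 0.04, mu = 2)
  expect_equal(edge_line_tension(m, pm, ed$v1[interf], ed$v2[interf]),
               2 * 0.08)
})

test_that("total energy: hand-computed hexagon and linearity", {
  h <- build_hexagonal_tissue(1, 0.62043)   # unit-area regular hexagon
  p <- solid_params()
  L <- 6 * 0.62043
  expect_equal(total_energy(h, p), 0.12 * L + 0.02 * L^2, tolerance = 1e-4)
  # Lambda = Gamma = 0 and area exactly 1 -> zero energy
  p0 <- mech_params(lambda = 0, gamma = 1e-12)
  expect_lt(total_energy(h, p0), 1e-6)
  # doubling all tension coefficients doubles (U - area term)
  m <- random_test_mesh(seed = 5)
  u1 <- total_energy(m, mech_params(0.06, 0.02, mu = 1))
  u2 <- total_energy(m, mech_params(0.12, 0.04, mu = 1))
  uarea <- total_energy(m, mech_params(0, 1e-15, mu = 1))
  expect_equal(u2 - uarea, 2 * (u1 - uarea), tolerance = 1e-8)
})

test_that("analytic forces match central finite differences", {
  m <- random_test_mesh(seed = 42)
  m$phase[3] <- 1L; m$t_entry[3] <- -0.05; m$a_entry[3] <- 0.5  # one mitotic
  p <- solid_params(mu = 3)
  cyc <- cycle_params()
  F <- vertex_forces(m, p, cyc, t_now = 0)
  h <- 1e-6
  for (i in seq(1, nrow(m$vertices), by = 3)) {
    for (d in 1:2) {
      mp <- m; mp$vertices[i, d] <- mp$vertices[i, d] + h
      mm <- m; mm$vertices[i, d] <- mm$vertices[i, d] - h
      fd <- -(total_energy(mp, p, cyc) - total_energy(mm, p, cyc)) / (2 * h)
      expect_equal(F[i, d], fd, tolerance = 1e-6)
    }
  }
})

test_that("forces: equilibrium, translation invariance, zero net force", {
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(19, gs$l_g)
  F <- vertex_forces(m, solid_params())
  ed <- mesh_edges(m)
  bv <- unique(c(ed$v1[is.na(ed$c2)], ed$v2[is.na(ed$c2)]))
  iv <- setdiff(seq_len(nrow(m$vertices)), bv)
  # interior of the ground-state lattice is in equilibrium
  expect_lt(max(abs(F[iv, ])), 1e-8)
  # net force on a free tissue vanishes
  expect_lt(max(abs(colSums(F))), 1e-10)
  # uniform translation leaves forces unchanged
  m2 <- m
  m2$vertices <- m2$vertices + matrix(c(3.2, -1.7), nrow(m$vertices), 2,
                                      byrow = TRUE)
  expect_equal(vertex_forces(m2, solid_params()), F, tolerance = 1e-9)
  # fixed vertices get zero force
  m3 <- random_test_mesh(seed = 9)
  m3$fixed[5] <- TRUE
  expect_equal(vertex_forces(m3, solid_params())[5, ], c(0, 0))
  # dilated single hexagon: inward radial restoring force on each vertex
  h <- build_hexagonal_tissue(1, 0.62043 * 1.1)
  Fh <- vertex_forces(h, solid_params())
  rad <- h$vertices / sqrt(rowSums(h$vertices^2))
  expect_true(all(rowSums(Fh * rad) < 0))
})

test_that("euler_step: fixed point, monotone energy, first-order scaling", {
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(19, gs$l_g)
  p <- solid_params(dt = 1e-4)
  # near-equilibrium: interior vertices barely move
  m1 <- euler_step(m, p)
  ed <- mesh_edges(m)
  bv <- unique(c(ed$v1[is.na(ed$c2)], ed$v2[is.na(ed$c2)]))
  iv <- setdiff(seq_len(nrow(m$vertices)), bv)
  expect_lt(max(abs(m1$vertices[iv, ] - m$vertices[iv, ])), 1e-12)
  # gradient flow: energy non-increasing along a perturbed trajectory
  mr <- random_test_mesh(seed = 7, jitter = 0.05)
  u <- total_energy(mr, p)
  for (k in 1:20) {
    mr <- euler_step(mr, p, n_steps = 50)
    u2 <- total_energy(mr, p)
    expect_lte(u2, u + 1e-12)
    u <- u2
  }
  # halving dt halves the per-step displacement to first order
  mj <- random_test_mesh(seed = 8, jitter = 0.05)
  d1 <- euler_step(mj, solid_params(dt = 1e-4))$vertices - mj$vertices
  d2 <- euler_step(mj, solid_params(dt = 5e-5))$vertices - mj$vertices
  expect_equal(d1, 2 * d2, tolerance = 1e-6)
})

test_that("relax_tissue drives a perturbed patch back to low energy", {
  p <- solid_params(dt = 1e-3)
  m <- random_test_mesh(seed = 11, jitter = 0.08)
  u0 <- total_energy(m, p)
  mr <- relax_tissue(m, p, t_relax = 2)
  expect_lt(total_energy(mr, p), u0)
  expect_length(validate_mesh(mr), 0)
})
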