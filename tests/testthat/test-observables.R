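# build a synthetic trajectory object without running the engine
fake_traj <- function(t, n_ab, area_ab, onset = 0, status = 0L) {
  structure(list(
    samples = data.frame(t = t, n_abnormal = n_ab,
                         n_normal = 100, area_abnormal = area_ab,
                         area_normal = 60),
    events = data.frame(), onset_time = onset, status = status,
    a0 = NA_real_), class = "tissue_trajectory")
}

test_that("abnormal density definitions", {
  m <- make_fixture("rosette7")
  m$type[] <- 1L
  # 7 unit-area cells -> density 1
  expect_equal(abnormal_density(m), 1 / cell_geometry(m, 1)$area,
               tolerance = 1e-6)
  # uniform 2x dilation scales density by 1/4
  m2 <- m
  m2$vertices <- 2 * m2$vertices
  expect_equal(abnormal_density(m2), abnormal_density(m) / 4,
               tolerance = 1e-12)
  m$type[] <- 0L
  expect_true(is.na(abnormal_density(m)))
  # trajectory route
  tr <- fake_traj(0:10, rep(4L, 11), rep(2, 11))
  expect_equal(abnormal_density(tr), rep(2, 11))
})

test_that("rho_bar: constant, success, and spike insensitivity", {
  # constant density c -> 1/rho_bar = 1/c
  tr <- fake_traj(seq(0, 50, 0.5), rep(10L, 101), rep(4, 101))
  rb <- rho_bar(tr, tau_A = 5)
  expect_equal(rb$inv_rho_bar, 0.4, tolerance = 1e-9)
  # success: N reaches zero -> defined as 0
  trs <- fake_traj(0:20, c(rep(5L, 15), 3L, 1L, 0L, 0L, 0L, 0L),
                   c(rep(2, 15), 1, 0.3, 0, 0, 0, 0))
  expect_equal(rho_bar(trs, 5)$inv_rho_bar, 0)
  # onset spike then plateau: moving-average minimum reflects the plateau
  tt <- seq(0, 50, 0.5)
  rho <- c(rep(8, 20), rep(2, length(tt) - 20))   # spike of 10 t.u.
  trp <- fake_traj(tt, rep(10L, length(tt)), 10 / rho)
  rbp <- rho_bar(trp, tau_A = 5)
  expect_equal(rbp$rho_bar, 2, tolerance = 1e-9)
  # window longer than record -> error
  expect_error(rho_bar(fake_traj(0:3, rep(2L, 4), rep(1, 4)), tau_A = 50),
               "window")
})

test_that("classify_outcome on synthetic time courses", {
  tau_A <- 5
  tt <- seq(0, 500, 1)
  # N hits zero -> success
  n <- pmax(0L, as.integer(20 - tt))
  trs <- fake_traj(tt, n, pmax(n * 0.5, 0))
  expect_equal(classify_outcome(trs, 10, tau_A), "success")
  # oscillating below the ceiling -> growth suspension
  n2 <- as.integer(12 + 5 * sin(tt / 7))
  trg <- fake_traj(tt, n2, n2 * 0.3)
  expect_equal(classify_outcome(trg, 10, tau_A, gs_threshold = 20),
               "growth_suspension")
  # growth beyond the ceiling -> failure
  n3 <- as.integer(10 * exp(tt / 100))
  trf <- fake_traj(tt, n3, n3 * 0.4)
  expect_equal(classify_outcome(trf, 10, tau_A, gs_threshold = 20),
               "failure")
  # early bailout flag -> failure regardless of the record
  trb <- fake_traj(0:10, rep(30L, 11), rep(10, 11), status = 2L)
  expect_equal(classify_outcome(trb, 10, tau_A, window = 5), "failure")
  # too-short non-terminated record -> error
  expect_error(classify_outcome(fake_traj(0:10, rep(5L, 11), rep(2, 11)),
                                10, tau_A), "window")
})

test_that("rho_star and rho_doublestar estimators", {
  runs <- data.frame(
    mu = rep(c(1, 2, 3, 4), each = 4),
    outcome = c(rep("failure", 4), rep("growth_suspension", 4),
                rep("growth_suspension", 2), rep("success", 2),
                rep("success", 4)),
    inv_rho_bar = c(runif(4, 0.5, 0.6), rep(0.3, 4),
                    rep(0.32, 2), 0, 0, rep(0, 4)))
  expect_equal(estimate_rho_star(runs[runs$mu == 2, ]), 1 / 0.3)
  expect_error(estimate_rho_star(runs[runs$outcome == "failure", ]), "GS|no")
  # clean jump between grid points: rho** read from the last failing point
  runs2 <- data.frame(
    mu = rep(1:8, each = 4),
    outcome = rep(c("failure", "success"), c(7 * 4, 4)),
    inv_rho_bar = c(rep(seq(0.6, 0.2, length.out = 7), each = 4), rep(0, 4)))
  est <- estimate_rho_doublestar(runs2)
  expect_equal(est$mu_jump, 8)
  expect_equal(est$mu_last_fail, 7)
  expect_equal(est$rho_doublestar, 1 / 0.2, tolerance = 1e-9)
  expect_error(estimate_rho_doublestar(runs2[runs2$mu < 8, ]), "jump")
})

test_that("side distribution", {
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(61, gs$l_g)
  ed <- mesh_edges(m)
  interior <- setdiff(seq_along(m$cells), unique(ed$c1[is.na(ed$c2)]))
  sd1 <- side_distribution(m, m$cell_id[interior])
  expect_equal(sum(sd1), 1)
  expect_equal(unname(sd1[["6"]]), 1)       # ground state: all hexagons
  expect_error(side_distribution(m, 99999))
})

test_that("cell stress tensor: isotropy and boundary-consistent mean", {
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(61, gs$l_g)
  p <- solid_params()
  ed <- mesh_edges(m)
  interior <- setdiff(seq_along(m$cells), unique(ed$c1[is.na(ed$c2)]))
  ctr <- interior[which.min(colSums(vapply(m$cell_id[interior], function(id)
    cell_geometry(m, id)$centroid, numeric(2))^2))]
  st <- cell_stress_tensor(m, p, m$cell_id[ctr])
  # hexagonal symmetry: principal stresses coincide
  expect_lt(st$anisotropy, 1e-6)
  # relaxed free-boundary tissue: interior area-weighted mean stress trace
  # vanishes (the rim carries the boundary-tension compression)
  mr <- relax_tissue(m, solid_params(dt = 1e-3), t_relax = 3)
  edr <- mesh_edges(mr)
  inr <- setdiff(seq_along(mr$cells), unique(edr$c1[is.na(edr$c2)]))
  met <- vapply(mr$cell_id[inr], function(id) cell_geometry(mr, id)$area, 0)
  tra <- vapply(mr$cell_id[inr], function(id)
    sum(diag(cell_stress_tensor(mr, p, id)$sigma)), 0)
  expect_lt(abs(sum(tra * met) / sum(met)), 0.01)
})

test_that("hill fits recover parameters and midpoints", {
  x <- seq(0.2, 3, length.out = 12)
  K <- 1.2; h <- 4
  f_dec <- K^h / (x^h + K^h)
  fit <- hill_fit(x, f_dec, "decreasing")
  expect_equal(fit$K, K, tolerance = 1e-5)
  expect_equal(fit$h, h, tolerance = 1e-4)
  expect_equal(fit$fn(fit$K), 0.5, tolerance = 1e-9)
  g_inc <- x^h / (x^h + K^h)
  fit2 <- hill_fit(x, g_inc, "increasing")
  expect_equal(fit2$K, K, tolerance = 1e-5)
  # noisy monotone data: fitted curve is monotone in the right direction
  set.seed(2)
  noisy <- pmin(1, pmax(0, f_dec + rnorm(12, 0, 0.04)))
  fit3 <- hill_fit(x, noisy, "decreasing")
  expect_true(all(diff(fit3$fn(x)) < 0))
  # degenerate data rejected
  expect_error(hill_fit(x, rep(1, 12), "decreasing"), "degenerate")
})
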