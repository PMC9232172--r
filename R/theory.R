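#' Hexagonal ground state
#'
#' For given line tension \eqn{\Lambda} and perimeter elasticity
#' \eqn{\Gamma}, the energy-minimizing regular hexagonal packing has cell
#' perimeter \eqn{L_g} equal to the largest positive root of
#' \deqn{L^3 + 8(12\Gamma - \sqrt 3)\,L + 48\Lambda = 0,}
#' obtained from d/dL of the per-cell energy
#' \eqn{e(L) = \tfrac12((\sqrt3/24)L^2 - 1)^2 + \Lambda L/2 + \Gamma L^2/2}
#' (each edge is shared by two cells, hence \eqn{\Lambda L/2}).  The cell
#' area follows as \eqn{A_g = (\sqrt3/24)L_g^2 \le 1} and the edge length as
#' \eqn{l_g = L_g/6}.  Only the parameter region where the ground state is
#' the regular hexagonal packing is supported.
#'
#' @param lambda line-tension coefficient (>= 0).
#' @param gamma perimeter-elasticity coefficient (>= 0).
#' @return object of class `ground_state`: list with `L_g`, `A_g`, `l_g`,
#'   `K`, `G`, `lambda`, `gamma`.
#' @examples
#' gs <- ground_state(0.12, 0.04)
#' c(gs$A_g, gs$K, gs$G)   # 0.576, 2.01, 1.27
#' @export
ground_state <- function(lambda, gamma) {
  stopifnot(lambda >= 0, gamma >= 0)
  r <- polyroot(c(48 * lambda, 8 * (12 * gamma - sqrt(3)), 0, 1))
  r <- Re(r[abs(Im(r)) < 1e-8 * (1 + Mod(r))])
  r <- r[r > 1e-12]
  if (!length(r))
    stop("no positive ground-state perimeter: (lambda, gamma) outside the ",
         "hexagonal-packing regime")
  L_g <- max(r)
  A_g <- sqrt(3) / 24 * L_g^2
  l_g <- L_g / 6
  # check it is the energy-minimizing branch (d2e/dL2 > 0)
  d2 <- 3 * L_g^2 / 96 - sqrt(3) / 12 + gamma
  if (d2 <= 0) stop("ground-state root is not a minimum")
  structure(list(L_g = L_g, A_g = A_g, l_g = l_g,
                 K = 9 * sqrt(3) * l_g^2 + 8 * sqrt(3) * gamma - 2,
                 G = 3 * (1 - A_g),
                 lambda = lambda, gamma = gamma),
            class = "ground_state")
}

#' @export
print.ground_state <- function(x, ...) {
  cat(sprintf(
    "<ground_state> (Lambda, Gamma) = (%g, %g): L_g = %.4f, A_g = %.4f, K = %.3f, G = %.3f\n",
    x$lambda, x$gamma, x$L_g, x$A_g, x$K, x$G))
  invisible(x)
}

#' Elastic moduli of the ground state
#'
#' Bulk modulus \eqn{K = 9\sqrt3\, l_g^2 + 8\sqrt3\,\Gamma - 2} and shear
#' modulus \eqn{G = 3(1 - A_g) = 12\sqrt3\,\Gamma + \sqrt3\,\Lambda/l_g}
#' of the hexagonal ground state.  In the zero-tension limit
#' (\eqn{\Lambda = \Gamma = 0}) they reduce to \eqn{K = 4}, \eqn{G = 0}.
#' Larger K with smaller G corresponds to a more fluid tissue.
#'
#' The convention matches the second derivative of per-cell energy with
#' respect to linear strain: \eqn{K = A_g^{-1}\, d^2 e/d\varepsilon^2} under
#' isotropic dilation \eqn{r \to (1+\varepsilon) r}, and
#' \eqn{G = (3/2)\, A_g^{-1}\, d^2 e/d\varepsilon^2} under area-preserving
#' stretch \eqn{(x, y) \to ((1+\varepsilon)x, y/(1+\varepsilon))} with the
#' internal sublattice degree of freedom relaxed.
#'
#' @inheritParams ground_state
#' @return named numeric vector `c(K = , G = )`.
#' @export
elastic_moduli <- function(lambda, gamma) {
  gs <- ground_state(lambda, gamma)
  c(K = gs$K, G = gs$G)
}

#' Regular-hexagon shape constant and interfacial cell count
#'
#' For a regular hexagon of area \eqn{a}, the edge length is
#' \eqn{r = k\sqrt a} with \eqn{k = \sqrt{2\sqrt3}/3 \approx 0.6204}.
#' Matching the perimeter of a circular cluster of N hexagonal cells to the
#' polyline through its convex interfacial vertices (interface angle
#' \eqn{\theta_2 = \pi/6}) gives the interfacial count
#' \eqn{n = \sqrt{2\sqrt3\,\pi N}}, valid for large N.
#'
#' @return `hexagon_constant()`: the constant k.
#' @export
hexagon_constant <- function() sqrt(2 * sqrt(3)) / 3

#' @rdname hexagon_constant
#' @param N number of cells in the cluster (>= 1).
#' @return `interfacial_count()`: approximate number of interfacial cells.
#' @export
interfacial_count <- function(N) {
  stopifnot(all(N >= 1))
  sqrt(2 * sqrt(3) * pi * N)
}

#' Coefficients of the cluster force-balance cubic
#'
#' The radial force balance of a rotationally symmetric abnormal cluster
#' under interfacial contractility \eqn{\mu\Lambda} reduces to the cubic
#' \eqn{u^3 - 3 q_1 u + 2 q_2 = 0} in the characteristic length
#' \eqn{u = \sqrt a} (cell area \eqn{a = u^2 = 1/\rho}), with
#' \deqn{q_1 = A_N/3 - 2\Gamma(1 + \pi/n), \qquad
#'       q_2 = \frac{\pi \mu\Lambda - \Gamma L_N (n - \pi)}{2 n k}.}
#'
#' @param A_N,L_N area and perimeter of the interfacial normal cells
#'   (ground-state values under Scenario 1; see
#'   [scenario2_interface_calibration()] for Scenario 2).
#' @param lambda,gamma mechanical coefficients.
#' @param mu interfacial contractility factor.
#' @param n number of interfacial abnormal cells (> pi).
#' @param k hexagon shape constant (default [hexagon_constant()]).
#' @return named numeric vector `c(q1 = , q2 = )`.
#' @export
force_balance_coefficients <- function(A_N, L_N, lambda, gamma, mu, n,
                                       k = hexagon_constant()) {
  stopifnot(n > pi)
  c(q1 = A_N / 3 - 2 * gamma * (1 + pi / n),
    q2 = (pi * mu * lambda - gamma * L_N * (n - pi)) / (2 * n * k))
}

#' Equilibria of the force-balance cubic
#'
#' Real roots of \eqn{u^3 - 3 q_1 u + 2 q_2 = 0} with their local stability:
#' writing the relaxation dynamics as \eqn{\dot u \propto -(u^3 - 3q_1 u +
#' 2q_2)}, an equilibrium \eqn{u^*} is stable iff \eqn{(u^*)^2 > q_1}.
#'
#' @param q1,q2 cubic coefficients (see [force_balance_coefficients()]).
#' @param tol tolerance for recognising real and coincident roots.
#' @return data.frame with columns `u`, `a` (= u^2), `stable`, sorted by
#'   decreasing `u`.
#' @export
solve_force_balance <- function(q1, q2, tol = 1e-9) {
  r <- polyroot(c(2 * q2, -3 * q1, 0, 1))
  re <- Re(r[abs(Im(r)) < 1e-7 * (1 + Mod(r))])
  re <- sort(unique(re), decreasing = TRUE)
  data.frame(u = re, a = re^2, stable = re^2 > q1 + tol)
}

#' Critical density and contractility of the cluster (saddle-node)
#'
#' When \eqn{q_1 > 0} the stable and unstable branches of the force-balance
#' cubic meet at a saddle-node as \eqn{\mu} increases:
#' \deqn{\rho_2 = 1/q_1, \qquad
#'       \mu_2\Lambda = \frac{2 n k}{\pi} q_1^{3/2}
#'         + \Gamma L_N \left(\frac{n}{\pi} - 1\right).}
#' Beyond \eqn{\mu_2} no positive equilibrium exists and the cluster is
#' squeezed out.  When \eqn{q_1 \le 0} there is no bifurcation (the single
#' equilibrium persists for all \eqn{\mu}) and the function returns `NA`s
#' with `bifurcates = FALSE`.
#'
#' @inheritParams force_balance_coefficients
#' @return list with `rho2`, `mu2_lambda`, `a2` (= q1), `u2` (= sqrt(q1)),
#'   `q1`, and `bifurcates`.
#' @export
critical_point <- function(A_N, L_N, lambda, gamma, n,
                           k = hexagon_constant()) {
  q1 <- A_N / 3 - 2 * gamma * (1 + pi / n)
  if (q1 <= 0)
    return(list(rho2 = NA_real_, mu2_lambda = NA_real_, a2 = NA_real_,
                u2 = NA_real_, q1 = q1, bifurcates = FALSE))
  list(rho2 = 1 / q1,
       mu2_lambda = 2 * n * k / pi * q1^1.5 + gamma * L_N * (n / pi - 1),
       a2 = q1, u2 = sqrt(q1), q1 = q1, bifurcates = TRUE)
}

#' Critical contractility corresponding to a homeostatic density
#'
#' Inverts the force-balance cubic at the prescribed density
#' \eqn{\rho_1}: with \eqn{u_1 = \rho_1^{-1/2}},
#' \deqn{\mu_1\Lambda = \frac{2 n k}{\pi}\,\frac{3 q_1 u_1 - u_1^3}{2}
#'   + \Gamma L_N \frac{n - \pi}{\pi}.}
#' At \eqn{\mu = \mu_1} the stable root of the cubic sits exactly at
#' \eqn{u_1}.  Used to place the critical contractility when the mechanical
#' homeostatic density (rather than the saddle-node) is limiting.
#'
#' @param rho1 homeostatic density (> 0), e.g. from [run_fixed_wall()].
#' @inheritParams force_balance_coefficients
#' @return `mu1_lambda` (numeric).  A value below \eqn{\Lambda} (mu < 1) is
#'   returned with a warning.
#' @export
mu1_from_rho1 <- function(rho1, A_N, L_N, lambda, gamma, n,
                          k = hexagon_constant()) {
  stopifnot(rho1 > 0)
  q1 <- A_N / 3 - 2 * gamma * (1 + pi / n)
  u1 <- rho1^-0.5
  mu1l <- 2 * n * k / pi * (3 * q1 * u1 - u1^3) / 2 +
    gamma * L_N * (n - pi) / pi
  if (mu1l < lambda)
    warning("mu1 < 1: contractility below baseline at this rho1")
  mu1l
}

#' Scenario 2 interface calibration
#'
#' Under Scenario 2 the abnormal cluster is denser than the surrounding
#' tissue when contractility switches on, so the ground-state values
#' overestimate the interfacial normal cells' area and perimeter.  They are
#' recalibrated by requiring the force-balance cubic to hold at
#' \eqn{\mu = 1} with abnormal cell area \eqn{a_0} (the mean abnormal area
#' just before onset):
#' \deqn{A_N + \Gamma L_N \frac{n - \pi}{n k \sqrt{a_0}} - a_0
#'   - 6\Gamma\frac{n + \pi}{n} - \frac{\pi\Lambda}{n k \sqrt{a_0}} = 0,}
#' jointly with the hexagonal relation \eqn{A_N = (\sqrt3/24) L_N^2}.  Among
#' the positive roots, the one continuous with the Scenario 1 limit (closest
#' to the ground-state \eqn{L_N}) is selected.
#'
#' @param a0 mean abnormal cell area just before contractility onset.
#' @inheritParams force_balance_coefficients
#' @return list with `A_N`, `L_N`.
#' @export
scenario2_interface_calibration <- function(a0, lambda, gamma, n,
                                            k = hexagon_constant()) {
  stopifnot(a0 > 0)
  gs <- ground_state(lambda, gamma)
  u0 <- sqrt(a0)
  g <- function(L) {
    sqrt(3) / 24 * L^2 + gamma * L * (n - pi) / (n * k * u0) - a0 -
      6 * gamma * (n + pi) / n - pi * lambda / (n * k * u0)
  }
  # bracket every sign change on a generous grid, then pick the root
  # nearest the ground-state perimeter (branch continuity)
  Ls <- seq(1e-3, 3 * gs$L_g, length.out = 400)
  gv <- vapply(Ls, g, 0)
  sc <- which(gv[-1] * gv[-length(gv)] < 0)
  if (!length(sc)) stop("no positive root for the Scenario 2 calibration")
  roots <- vapply(sc, function(i)
    stats::uniroot(g, c(Ls[i], Ls[i + 1]), tol = 1e-12)$root, 0)
  L_N <- roots[which.min(abs(roots - gs$L_g))]
  list(A_N = sqrt(3) / 24 * L_N^2, L_N = L_N)
}

#' Density limit for the mechanical existence of a regular i-gon
#'
#' Reconstructs, as the single-cell analogue of the cluster force balance,
#' the upper limit of surrounding cell density below which a regular polygon
#' with i edges can exist stably.  A single i-sided cell (shape constant
#' \eqn{k_i = \sqrt{4\tan(\pi/i)/i}}, so its edge is \eqn{k_i\sqrt a}) is
#' surrounded by n = i cells of area \eqn{A_s = 1/\rho_s} and hexagonal
#' perimeter \eqn{L_s = \sqrt{24 A_s/\sqrt3}} with no extra contractility
#' (\eqn{\mu = 1}).  As \eqn{\rho_s} grows, the stable positive root of the
#' resulting cubic vanishes through a saddle-node; `rho_mce` returns that
#' threshold density.  The ordering \eqn{\rho_{MCE}(3) < \rho_{MCE}(4) <
#' \rho_{MCE}(5)} links smaller polygon classes to earlier elimination.
#'
#' This reconstruction (the i-gon shape constant and hexagonal
#' surrounding-cell perimeter) is approximate and validated only through the
#' orderings and bracketing relations it is used for.
#'
#' @param i polygon class (3, 4, or 5).
#' @inheritParams ground_state
#' @param rho_max upper end of the scanned density range.
#' @return the density bound (numeric).
#' @export
rho_mce <- function(i, lambda, gamma, rho_max = 1e4) {
  stopifnot(i %in% 3:5)
  k_i <- sqrt(4 * tan(pi / i) / i)
  exists_margin <- function(rho_s) {
    A_s <- 1 / rho_s
    L_s <- sqrt(24 * A_s / sqrt(3))
    q1 <- (A_s - gamma * (i + pi)) / 3
    q2 <- (pi * lambda - gamma * L_s * (i - pi)) / (2 * i * k_i)
    lim <- if (q1 > 0) q1^1.5 else 0
    lim - q2          # > 0 while a stable positive root exists
  }
  lo <- 1e-3
  if (exists_margin(lo) <= 0)
    stop("no stable root even at vanishing density; reconstruction invalid here")
  hi <- rho_max
  if (exists_margin(hi) > 0)
    stop("no saddle-node in the scanned density range (i = ", i, ")")
  stats::uniroot(exists_margin, c(lo, hi), tol = 1e-10)$root
}

#' Regression of the homeostatic density on the single-cell limits
#'
#' Fits \eqn{\rho_1 \approx \sum_{i=3}^5 c_i\, \rho_{MCE}(i)} (no
#' intercept) by least squares across parameter sets, returning the
#' coefficients, fitted values, and a predictor function.
#'
#' @param rho1 numeric vector of simulated homeostatic densities.
#' @param rho_mce_matrix matrix (length(rho1) x 3) of \eqn{\rho_{MCE}(3..5)}
#'   for the same parameter sets.
#' @return list with `coefficients` (c3, c4, c5), `fitted`, `residuals`,
#'   `r_squared` (about the mean of rho1), and `predict(newmat)`.
#' @export
rho1_regression <- function(rho1, rho_mce_matrix) {
  X <- as.matrix(rho_mce_matrix)
  if (nrow(X) != length(rho1)) stop("dimension mismatch")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  fit <- stats::lm.fit(X, rho1)
  fitted <- as.numeric(X %*% fit$coefficients)
  ss_res <- sum((rho1 - fitted)^2)
  ss_tot <- sum((rho1 - mean(rho1))^2)
  co <- stats::setNames(fit$coefficients, c("c3", "c4", "c5"))
  list(coefficients = co, fitted = fitted, residuals = rho1 - fitted,
       r_squared = 1 - ss_res / ss_tot,
       predict = function(newmat) as.numeric(as.matrix(newmat) %*% co))
}

#' Scaling variable of the elimination phase diagram
#'
#' By the 2D Laplace argument, the pressure excess a contractile interface
#' exerts on a cluster of radius \eqn{R \propto \sqrt{N_\theta}} is
#' \eqn{\Lambda\Delta\mu/R}, so elimination success collapses onto
#' \eqn{\Lambda(\mu - 1)/\sqrt{N_\theta}}.
#'
#' @param lambda line tension.
#' @param mu contractility factor (>= 1).
#' @param N_theta cluster size at contractility onset (>= 1).
#' @return the scaling variable (numeric).
#' @export
scaling_variable <- function(lambda, mu, N_theta) {
  stopifnot(all(mu >= 1), all(N_theta >= 1))
  lambda * (mu - 1) / sqrt(N_theta)
}

#' Net radial force on an interfacial cluster cell (ring model)
#'
#' Evaluates the approximate net radial force on an interfacial abnormal
#' cell of the rotationally symmetric ring model,
#' \deqn{F(u) \approx 2\{(A_N - u^2) k u - \pi\mu\Lambda/n
#'       - \pi\Gamma(L_N + 6 k u)/n + \Gamma(L_N - 6 k u)\},}
#' with \eqn{u = \sqrt a} the characteristic length.  This expression is an
#' independent derivation route for the cubic:
#' \eqn{F(u) = -2k\,(u^3 - 3 q_1 u + 2 q_2)} exactly, so its zeros coincide
#' with [solve_force_balance()] roots, and \eqn{F < 0} just above the stable
#' root (restoring).
#'
#' @param u characteristic length(s), \eqn{u > 0}.
#' @inheritParams force_balance_coefficients
#' @return numeric vector of forces.
#' @export
ring_net_force <- function(u, A_N, L_N, lambda, gamma, mu, n,
                           k = hexagon_constant()) {
  2 * ((A_N - u^2) * k * u - pi * mu * lambda / n -
         pi * gamma * (L_N + 6 * k * u) / n + gamma * (L_N - 6 * k * u))
}

#' Assemble a force-balance model for a cluster
#'
#' Convenience constructor tying the pieces together: ground state (or
#' Scenario 2 calibration), interfacial count, cubic coefficients for a
#' given \eqn{\mu}, equilibria, and critical point.
#'
#' @inheritParams ground_state
#' @param mu contractility factor.
#' @param N cluster size (defaults interfacial count to
#'   [interfacial_count()]; override `n` for an explicitly constructed
#'   cluster).
#' @param n interfacial cell count.
#' @param scenario 1 (ground-state interface) or 2 (requires `a0`).
#' @param a0 mean abnormal area at onset (Scenario 2 only).
#' @return object of class `force_balance_model`.
#' @export
force_balance_model <- function(lambda, gamma, mu, N,
                                n = interfacial_count(N),
                                scenario = 1, a0 = NULL) {
  k <- hexagon_constant()
  if (scenario == 2) {
    if (is.null(a0)) stop("Scenario 2 requires a0")
    cal <- scenario2_interface_calibration(a0, lambda, gamma, n, k)
    A_N <- cal$A_N; L_N <- cal$L_N
  } else {
    gs <- ground_state(lambda, gamma)
    A_N <- gs$A_g; L_N <- gs$L_g
  }
  q <- force_balance_coefficients(A_N, L_N, lambda, gamma, mu, n, k)
  structure(list(
    lambda = lambda, gamma = gamma, mu = mu, N = N, n = n, k = k,
    A_N = A_N, L_N = L_N, q1 = q[["q1"]], q2 = q[["q2"]],
    equilibria = solve_force_balance(q[["q1"]], q[["q2"]]),
    critical = critical_point(A_N, L_N, lambda, gamma, n, k)),
    class = "force_balance_model")
}

#' @export
print.force_balance_model <- function(x, ...) {
  cat(sprintf("<force_balance_model> (Lambda,Gamma)=(%g,%g) mu=%g N=%g n=%.2f\n",
              x$lambda, x$gamma, x$mu, x$N, x$n))
  cat(sprintf("  q1=%.5f q2=%.5f", x$q1, x$q2))
  if (x$critical$bifurcates)
    cat(sprintf("  rho2=%.3f mu2*Lambda=%.3f", x$critical$rho2,
                x$critical$mu2_lambda))
  cat("\n")
  print(x$equilibria)
  invisible(x)
}
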