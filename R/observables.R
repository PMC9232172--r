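#' Density of the abnormal cell population
#'
#' \eqn{\rho(t) = N(t) / \sum_i A_i(t)}: number of abnormal cells over
#' their summed area.  Undefined (NA) when no abnormal cells remain.
#'
#' @param x a [tissue_mesh()] or a trajectory (see [simulate_tissue()]).
#' @return a single density for a mesh; the per-sample density series for a
#'   trajectory.
#' @export
abnormal_density <- function(x) {
  if (inherits(x, "tissue_mesh")) {
    ab <- x$type == 1L
    if (!any(ab)) return(NA_real_)
    met <- vm_cell_metrics(unclass(x))
    return(sum(ab) / sum(met$area[ab]))
  }
  s <- x$samples
  ifelse(s$n_abnormal > 0, s$n_abnormal / s$area_abnormal, NA_real_)
}

#' Time-averaged inverse density of a run
#'
#' Computes \eqn{\bar\rho = \min_t E_{\tau_A}[\rho(t)]}: the moving average
#' of \eqn{\rho(t)} with a \eqn{\tau_A}-wide window over the post-onset
#' record, then the minimum over time.  Returns \eqn{1/\bar\rho}; for an
#' elimination-success run (N reaches 0) the value is defined as 0.
#'
#' @param trajectory a trajectory from [simulate_tissue()] and friends.
#' @param tau_A the moving-average window (the abnormal cycle duration).
#' @return list with `inv_rho_bar` (\eqn{1/\bar\rho}) and `rho_bar`.
#' @export
rho_bar <- function(trajectory, tau_A) {
  s <- trajectory$samples
  if (any(s$n_abnormal == 0))
    return(list(inv_rho_bar = 0, rho_bar = Inf))
  onset <- trajectory$onset_time
  if (is.na(onset)) onset <- s$t[1]
  keep <- s$t >= onset
  tt <- s$t[keep]
  rho <- s$n_abnormal[keep] / s$area_abnormal[keep]
  if (length(tt) < 2) stop("trajectory too short for rho_bar")
  dt_s <- stats::median(diff(tt))
  w <- max(1L, round(tau_A / dt_s))
  if (w > length(rho))
    stop("moving-average window longer than the post-onset record")
  ma <- stats::filter(rho, rep(1 / w, w), sides = 1)
  ma <- ma[!is.na(ma)]
  rb <- min(ma)
  list(inv_rho_bar = 1 / rb, rho_bar = rb)
}

#' Classify the outcome of a run
#'
#' Success if the abnormal population reaches 0; growth suspension if it
#' stays below `gs_threshold` over the whole classification window while
#' still present at the end; failure otherwise.  The nominal window is 100
#' abnormal cell cycles; scaled-down studies may pass a shorter `window`.
#'
#' @param trajectory a trajectory.
#' @param N_theta cluster size at onset (only used for the default
#'   `gs_threshold`).
#' @param tau_A abnormal cycle duration.
#' @param gs_threshold growth-suspension ceiling (default `2 * N_theta`).
#' @param window classification window after onset (default `100 * tau_A`).
#' @return one of `"success"`, `"growth_suspension"`, `"failure"`.
#' @export
classify_outcome <- function(trajectory, N_theta, tau_A,
                             gs_threshold = 2 * N_theta,
                             window = 100 * tau_A) {
  s <- trajectory$samples
  if (any(s$n_abnormal == 0)) return("success")
  if (identical(trajectory$status, 2L) || identical(trajectory$status, 2))
    return("failure")                      # bailed out on runaway growth
  onset <- trajectory$onset_time
  if (is.na(onset)) onset <- s$t[1]
  covered <- max(s$t) - onset
  if (covered < window - 1e-9)
    stop(sprintf("trajectory covers %.3g < window %.3g after onset",
                 covered, window))
  inwin <- s$t >= onset & s$t <= onset + window
  if (all(s$n_abnormal[inwin] < gs_threshold)) "growth_suspension"
  else "failure"
}

#' Density in the growth-suspension phase
#'
#' \eqn{1/\rho^* = \langle 1/\bar\rho \rangle_{GS}}: the mean of
#' \eqn{1/\bar\rho} over all runs classified as growth suspension.
#'
#' @param runs data.frame with columns `outcome` and `inv_rho_bar`
#'   (e.g. the `runs` table of a [sweep_contractility()] result).
#' @return `rho_star` (numeric); errors when no GS runs exist.
#' @export
estimate_rho_star <- function(runs) {
  gs <- runs$outcome == "growth_suspension"
  if (!any(gs)) stop("no growth-suspension runs: rho* undefined")
  1 / mean(runs$inv_rho_bar[gs])
}

#' Density at the elimination jump (fluid regime)
#'
#' \eqn{\rho^{**}}: the density under the critical contractile force, read
#' off just before \eqn{1/\bar\rho} jumps to zero.  Operationally: the jump
#' is located at the smallest \eqn{\mu} grid point with >= 50 percent
#' success; \eqn{\rho^{**}} is the mean \eqn{\bar\rho} over the failing
#' runs at the largest grid point with >= 50 percent failure.
#'
#' @param runs per-run table with columns `mu`, `outcome`, `inv_rho_bar`.
#' @return list with `rho_doublestar`, `mu_jump`, `mu_last_fail`.
#' @export
estimate_rho_doublestar <- function(runs) {
  mus <- sort(unique(runs$mu))
  f_succ <- vapply(mus, function(m)
    mean(runs$outcome[runs$mu == m] == "success"), 0)
  f_fail <- vapply(mus, function(m)
    mean(runs$outcome[runs$mu == m] == "failure"), 0)
  if (!any(f_succ >= 0.5) || !any(f_fail >= 0.5))
    stop("no elimination jump inside the mu grid: rho** undefined")
  mu_jump <- mus[which(f_succ >= 0.5)[1]]
  mu_last <- max(mus[f_fail >= 0.5])
  sel <- runs$mu == mu_last & runs$outcome != "success" &
    is.finite(runs$inv_rho_bar) & runs$inv_rho_bar > 0
  if (!any(sel)) stop("no surviving runs at the last failing grid point")
  list(rho_doublestar = mean(1 / runs$inv_rho_bar[sel]),
       mu_jump = mu_jump, mu_last_fail = mu_last)
}

#' Polygon-class (side-number) distribution
#'
#' Frequencies of 3-, 4-, 5-, ...-sided cells over a subset of cells.
#'
#' @param mesh a [tissue_mesh()].
#' @param cells optional cell ids (default: all).
#' @return named numeric vector of frequencies (names = side numbers),
#'   summing to 1.
#' @export
side_distribution <- function(mesh, cells = NULL) {
  idx <- if (is.null(cells)) seq_along(mesh$cells)
         else match(cells, mesh$cell_id)
  if (anyNA(idx) || !length(idx)) stop("empty or unknown cell subset")
  ns <- lengths(mesh$cells[idx])
  tab <- table(factor(ns, levels = seq(3, max(ns))))
  as.numeric(tab) / sum(tab) -> fr
  stats::setNames(fr, names(tab))
}

#' Per-cell stress tensor
#'
#' Standard vertex-model cell stress: isotropic pressure from the area term
#' plus the edge-tension dyadic,
#' \deqn{\sigma = -P I + \frac{1}{2A_\alpha}\sum_{e \in \alpha}
#'       T_e \frac{d_e \otimes d_e}{|d_e|},}
#' with \eqn{P = -(A_\alpha - A_0)} and edge tension
#' \eqn{T_e = \Lambda_e + \Gamma_\alpha L_\alpha + \Gamma_\beta L_\beta}
#' (\eqn{\beta} the other incident cell, when present).  Principal stresses
#' are returned sorted, \eqn{\sigma_1 \ge \sigma_2}; \eqn{\sigma_1} is the
#' tensile and \eqn{\sigma_2} the compressive direction.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [mech_params()].
#' @param cell_id the focal cell.
#' @param cycle a [cycle_params()] (mitotic target).
#' @param t_now current time.
#' @param contractility_active is the interfacial contractility on?
#' @return list with `sigma` (2x2 matrix), `principal` (c(sigma1, sigma2)),
#'   `anisotropy` (sigma1 - sigma2), `pressure`.
#' @export
cell_stress_tensor <- function(mesh, params, cell_id, cycle = cycle_params(),
                               t_now = 0, contractility_active = TRUE) {
  i <- match(cell_id, mesh$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cell_id)
  met <- vm_cell_metrics(unclass(mesh))
  ed <- mesh_edges(mesh)
  A <- met$area[i]
  A0 <- mitotic_target_area(mesh, cycle, t_now)[i]
  P <- -(A - A0)
  gam <- c(params$gamma_normal, params$gamma_abnormal)
  sig <- -P * diag(2)
  onc <- which(ed$c1 == i | (!is.na(ed$c2) & ed$c2 == i))
  V <- mesh$vertices
  for (e in onc) {
    lam_e <- edge_line_tension(mesh, params, ed$v1[e], ed$v2[e],
                               contractility_active)
    other <- if (is.na(ed$c2[e])) NA_integer_
             else if (ed$c1[e] == i) ed$c2[e] else ed$c1[e]
    Te <- lam_e + gam[mesh$type[i] + 1] * met$perimeter[i] +
      if (is.na(other)) 0 else gam[mesh$type[other] + 1] * met$perimeter[other]
    d <- V[ed$v2[e], ] - V[ed$v1[e], ]
    len <- sqrt(sum(d^2))
    if (len < 1e-14) next
    sig <- sig + Te * outer(d, d) / len / (2 * A)
  }
  ev <- eigen(sig, symmetric = TRUE)$values
  list(sigma = sig, principal = c(sigma1 = max(ev), sigma2 = min(ev)),
       anisotropy = max(ev) - min(ev), pressure = P)
}

#' Hill-function fit of outcome frequencies
#'
#' Least-squares fit of \eqn{f(x) = K^h/(x^h + K^h)} (decreasing; failure
#' curves) or \eqn{g(x) = x^h/(x^h + K^h)} (increasing; success curves) to
#' frequencies on a positive grid.  The midpoint \eqn{K} is the operational
#' critical contractility: \eqn{f(K) = g(K) = 1/2} by construction.
#'
#' @param x positive abscissae (>= 3 points).
#' @param freq frequencies in `[0, 1]`.
#' @param direction `"decreasing"` or `"increasing"`.
#' @return list with `K`, `h`, `fitted`, and `fn(xnew)`.
#' @export
hill_fit <- function(x, freq, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  stopifnot(length(x) >= 3, length(x) == length(freq), all(x > 0))
  if (max(freq) - min(freq) < 0.1)
    stop("degenerate frequency data: no transition to fit")
  hill <- function(p, xx) {
    K <- exp(p[1]); h <- exp(p[2])
    r <- (xx / K)^h
    if (direction == "decreasing") 1 / (1 + r) else r / (1 + r)
  }
  target <- if (direction == "decreasing") {
    x[which.min(abs(freq - 0.5))]
  } else x[which.min(abs(freq - 0.5))]
  obj <- function(p) sum((hill(p, x) - freq)^2)
  best <- NULL
  for (h0 in c(1, 2, 4, 8, 16)) {
    o <- stats::optim(c(log(target), log(h0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  K <- exp(best$par[1]); h <- exp(best$par[2])
  list(K = K, h = h, fitted = hill(best$par, x),
       fn = function(xnew) hill(best$par, xnew))
}
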