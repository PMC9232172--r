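#' Mechanical parameters
#'
#' Bundles the coefficients of the tissue energy
#' \deqn{U = \sum_\alpha \tfrac12 (A_\alpha - A_0)^2
#'       + \sum_{<\alpha\beta>} \Lambda_{\alpha\beta}\, l_{\alpha\beta}
#'       + \sum_\alpha \tfrac{\Gamma_\alpha}{2} L_\alpha^2}
#' with type-dependent line tension \eqn{\Lambda} and perimeter elasticity
#' \eqn{\Gamma}, the interfacial contractility factor \eqn{\mu \ge 1}
#' applied to normal-abnormal edges, the (relative) T1/T2 thresholds, and
#' the Euler time step.  The relative thresholds are scaled by the
#' ground-state edge length and cell area of the *normal* type and frozen
#' at their t = 0 values.
#'
#' @param lambda,gamma shared coefficients used for both cell types unless
#'   the per-type arguments are given.
#' @param mu interfacial contractility factor (>= 1); edges between a normal
#'   and an abnormal cell carry \eqn{\mu \Lambda} while contractility is
#'   active. When the two types have unequal \eqn{\Lambda}, the interfacial
#'   base tension is their arithmetic mean.
#' @param lambda_normal,lambda_abnormal,gamma_normal,gamma_abnormal per-type
#'   coefficients.
#' @param theta_t1_rel T1 length threshold relative to the ground-state edge
#'   length (in (0,1); 0.01-0.05 is the sensible range).
#' @param theta_t2_rel T2 area threshold relative to the ground-state cell
#'   area.
#' @param dt explicit Euler time step.
#' @param new_edge_factor length of the reconnected post-T1 edge in units of
#'   the T1 threshold (must exceed 1 to avoid immediate retriggering).
#' @return object of class `mech_params`.
#' @export
mech_params <- function(lambda = 0.12, gamma = 0.04, mu = 1,
                        lambda_normal = lambda, lambda_abnormal = lambda,
                        gamma_normal = gamma, gamma_abnormal = gamma,
                        theta_t1_rel = 0.01, theta_t2_rel = 0.01,
                        dt = 1e-4, new_edge_factor = 1.5) {
  stopifnot(lambda_normal >= 0, lambda_abnormal >= 0,
            gamma_normal >= 0, gamma_abnormal >= 0,
            mu >= 1, dt > 0,
            theta_t1_rel > 0, theta_t1_rel < 1,
            theta_t2_rel > 0, theta_t2_rel < 1)
  structure(list(
    lambda_normal = lambda_normal, lambda_abnormal = lambda_abnormal,
    gamma_normal = gamma_normal, gamma_abnormal = gamma_abnormal,
    mu = mu, theta_t1_rel = theta_t1_rel, theta_t2_rel = theta_t2_rel,
    dt = dt, new_edge_factor = new_edge_factor), class = "mech_params")
}

# full parameter list in the layout the compiled engine expects
engine_params <- function(mech, cycle = cycle_params()) {
  gs <- ground_state(mech$lambda_normal, mech$gamma_normal)
  list(
    lambda_normal = mech$lambda_normal,
    lambda_abnormal = mech$lambda_abnormal,
    gamma_normal = mech$gamma_normal,
    gamma_abnormal = mech$gamma_abnormal,
    mu = mech$mu,
    theta_t1 = mech$theta_t1_rel * gs$l_g,
    theta_t2 = mech$theta_t2_rel * gs$A_g,
    dt = mech$dt,
    b = cycle$growth_rate_b,
    tau_normal = cycle$tau_normal,
    tau_abnormal = cycle$tau_abnormal,
    jitter = cycle$jitter_fraction,
    delta_a = cycle$delta_A,
    rule = if (cycle$division_rule == "adder") 1L
           else if (cycle$doubling_baseline == "entry") 2L else 0L,
    orient = if (cycle$orientation_rule == "long_axis") 1L else 0L,
    new_edge_factor = mech$new_edge_factor,
    tm_cap = cycle$tm_cap,
    step_clamp = 0.5 * mech$theta_t1_rel * gs$l_g
  )
}

#' Line-tension coefficient of one edge
#'
#' Returns the \eqn{\Lambda} carried by the edge between vertices `v1` and
#' `v2`: the common type coefficient for same-type edges, \eqn{\mu}-fold the
#' (mean) base coefficient for a normal-abnormal edge while contractility is
#' active, and the single incident cell's coefficient on the boundary.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [mech_params()].
#' @param v1,v2 vertex indices of the edge.
#' @param contractility_active is the interfacial contractility switched on?
#' @return a single numeric coefficient.
#' @export
edge_line_tension <- function(mesh, params, v1, v2,
                              contractility_active = TRUE) {
  ed <- mesh_edges(mesh)
  i <- which((ed$v1 == min(v1, v2)) & (ed$v2 == max(v1, v2)))
  if (length(i) != 1) stop("no such edge: (", v1, ",", v2, ")")
  lam <- c(params$lambda_normal, params$lambda_abnormal)
  t1 <- mesh$type[ed$c1[i]]
  if (is.na(ed$c2[i])) return(lam[t1 + 1])
  t2 <- mesh$type[ed$c2[i]]
  if (t1 == t2) return(lam[t1 + 1])
  base <- mean(lam)
  if (contractility_active) params$mu * base else base
}

#' Total tissue energy
#'
#' Evaluates the vertex-model energy of the mesh.  Interphase cells have
#' target area 1; mitotic cells have target area \eqn{1 + b\,t_m} with
#' \eqn{t_m} the time since mitosis entry (see [mitotic_target_area()]).
#'
#' @inheritParams edge_line_tension
#' @param cycle a [cycle_params()] (supplies the mitotic growth rate `b`).
#' @param t_now current simulation time (needed for mitotic targets).
#' @return a single numeric energy.
#' @export
total_energy <- function(mesh, params, cycle = cycle_params(), t_now = 0,
                         contractility_active = TRUE) {
  vm_energy(unclass(mesh), engine_params(params, cycle), t_now,
            contractility_active)
}

#' Analytic vertex forces
#'
#' \eqn{F_i = -\partial U/\partial r_i} from the analytic gradients of the
#' shoelace area, edge lengths, and perimeters.  Immobilized vertices get
#' zero force.
#'
#' @inheritParams total_energy
#' @return numeric matrix (n x 2) of forces.
#' @export
vertex_forces <- function(mesh, params, cycle = cycle_params(), t_now = 0,
                          contractility_active = TRUE) {
  vm_forces(unclass(mesh), engine_params(params, cycle), t_now,
            contractility_active)
}

#' Explicit Euler steps (no topological events)
#'
#' Moves every mobile vertex down the energy gradient,
#' \eqn{r_i \leftarrow r_i + \Delta t\, F_i}, for `n_steps` steps.  Cell
#' cycle clocks do not progress and no T1/T2/division surgery is applied;
#' use [resolve_events()] or [simulate_tissue()] for the full dynamics.
#'
#' @inheritParams total_energy
#' @param n_steps number of Euler steps.
#' @return the updated [tissue_mesh()], with the final time in attribute
#'   `"time"`.
#' @export
euler_step <- function(mesh, params, cycle = cycle_params(), n_steps = 1,
                       t_now = 0, contractility_active = TRUE) {
  out <- vm_euler_steps(unclass(mesh), engine_params(params, cycle),
                        as.integer(n_steps), t_now, contractility_active)
  m <- rewrap_mesh(out$mesh, mesh)
  attr(m, "time") <- out$t
  m
}

#' Relax a tissue toward mechanical equilibrium
#'
#' Convenience wrapper: runs gradient descent (with T1/T2 surgery enabled,
#' divisions disabled) for `t_relax` time units.
#'
#' @inheritParams total_energy
#' @param t_relax duration of the relaxation.
#' @return the relaxed [tissue_mesh()].
#' @export
relax_tissue <- function(mesh, params, cycle = cycle_params(), t_relax = 1,
                         contractility_active = TRUE) {
  ctrl <- list(t0 = 0, t_end = t_relax, sample_every = 1e9L,
               activate_at_N = 0L, active = contractility_active,
               divisions = FALSE, stop_on_extinct = FALSE, bailout_n = 0L,
               record_energy = FALSE, max_event_iter = 10L)
  out <- vm_run(unclass(mesh), engine_params(params, cycle), ctrl)
  rewrap_mesh(out$mesh, mesh)
}
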