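#' Simulation configuration
#'
#' Collects everything a run needs: mechanical and cell-cycle parameters,
#' the scenario, the cluster-size threshold \eqn{N_\theta} at which the
#' interfacial contractility switches on, tissue size, duration, seed, and
#' sampling resolution.  Durations are given in units of the abnormal cycle
#' time \eqn{\tau_A} (the published classification window is
#' \eqn{100\,\tau_A}); scaled-down studies shorten `t_end_tau` and say so.
#'
#' @param mech a [mech_params()].
#' @param cycle a [cycle_params()].
#' @param scenario 1 (pre-formed cluster, contractility from t = 0),
#'   2 (single mutant grows to \eqn{N_\theta}, then contractility), or
#'   `"fixed_wall"` (proliferation in an immobile circular wall).
#' @param N_theta cluster size at contractility onset (>= 1).
#' @param tissue_size initial number of (normal) cells.
#' @param wall_rings ring count of the fixed-wall disk (fixed_wall only).
#' @param t_end_tau run duration in units of tau_A.
#' @param sample_dt sampling interval for the time series (time units).
#' @param gs_threshold growth-suspension ceiling (default `2 * N_theta`).
#' @param bailout_factor stop a run early (classified failure) once the
#'   abnormal count reaches `bailout_factor * gs_threshold`; 0 disables.
#' @param t_relax relaxation time before the experiment proper.
#' @param seed RNG seed recorded and used by the drivers.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(mech = mech_params(), cycle = cycle_params(),
                       scenario = 1, N_theta = 10, tissue_size = 200,
                       wall_rings = 5, t_end_tau = 100, sample_dt = 0.1,
                       gs_threshold = 2 * N_theta, bailout_factor = 2,
                       t_relax = 1, seed = 1) {
  stopifnot(N_theta >= 1, t_end_tau > 0, tissue_size >= 1)
  structure(list(mech = mech, cycle = cycle, scenario = scenario,
                 N_theta = N_theta, tissue_size = tissue_size,
                 wall_rings = wall_rings, t_end_tau = t_end_tau,
                 sample_dt = sample_dt, gs_threshold = gs_threshold,
                 bailout_factor = bailout_factor, t_relax = t_relax,
                 seed = seed),
            class = "sim_config")
}

default_control <- function(config, t_end, active, activate_at_N = 0L,
                            divisions = TRUE, record_energy = FALSE) {
  se <- max(1L, round(config$sample_dt / config$mech$dt))
  bail <- if (config$bailout_factor > 0)
    as.integer(ceiling(config$bailout_factor * config$gs_threshold)) else 0L
  list(t0 = 0, t_end = t_end, sample_every = se,
       activate_at_N = as.integer(activate_at_N), active = active,
       divisions = divisions, stop_on_extinct = TRUE, bailout_n = bail,
       record_energy = record_energy, max_event_iter = 10L)
}

new_trajectory <- function(out, config, mesh_template, onset_time) {
  if (is.na(out$onset_time) && !is.na(onset_time)) out$onset_time <- onset_time
  structure(list(samples = out$samples, events = out$events,
                 mesh = rewrap_mesh(out$mesh, mesh_template),
                 energy = out$energy, t_final = out$t_final,
                 status = out$status, onset_time = out$onset_time,
                 a0 = out$a0, t_extinct = out$t_extinct, config = config),
            class = "tissue_trajectory")
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<tissue_trajectory> t in [%.3g, %.3g], N_abnormal %d -> %d, %d events, status %d\n",
    min(s$t), max(s$t), s$n_abnormal[1], s$n_abnormal[nrow(s)],
    nrow(x$events), x$status))
  invisible(x)
}

# build + relax the starting normal tissue for a config
base_tissue <- function(config) {
  gs <- ground_state(config$mech$lambda_normal, config$mech$gamma_normal)
  m <- build_hexagonal_tissue(config$tissue_size, gs$l_g, "free")
  if (config$t_relax > 0)
    m <- relax_tissue(m, config$mech, config$cycle, config$t_relax)
  m
}

relabel_central_cluster <- function(mesh, N_theta) {
  met <- vm_cell_metrics(unclass(mesh))
  d2 <- (met$cx - mean(met$cx))^2 + (met$cy - mean(met$cy))^2
  sel <- order(d2)[seq_len(N_theta)]
  mesh$type[sel] <- 1L
  mesh
}

#' Run Scenario 1: pre-formed cluster, immediate contractility
#'
#' A cluster of \eqn{N_\theta} abnormal cells is created at the tissue
#' centre (the \eqn{N_\theta} cells nearest the centroid) within a relaxed
#' normal tissue, interfacial contractility \eqn{\mu\Lambda} acts from
#' t = 0, and the abnormal cells then proliferate with \eqn{\tau_A}.  At
#' onset the two populations have the same density by construction.
#'
#' @param config a [sim_config()] with `scenario = 1`.
#' @param tissue optional pre-built relaxed tissue (rebuilt from the config
#'   when missing); pass one to share the expensive base tissue across a
#'   sweep.
#' @return a `tissue_trajectory`.
#' @export
run_scenario1 <- function(config, tissue = NULL) {
  if (config$N_theta > config$tissue_size)
    stop("N_theta exceeds the tissue size")
  set.seed(config$seed)
  m <- if (is.null(tissue)) base_tissue(config) else tissue
  m <- relabel_central_cluster(m, config$N_theta)
  m <- init_cell_clocks(m, config$cycle)
  t_end <- config$t_end_tau * config$cycle$tau_abnormal
  ctrl <- default_control(config, t_end, active = TRUE)
  out <- vm_run(unclass(m), engine_params(config$mech, config$cycle), ctrl)
  new_trajectory(out, config, m, onset_time = 0)
}

#' Run Scenario 2: single mutant, delayed contractility
#'
#' One interior cell is relabelled abnormal at t = 0 and proliferates;
#' interfacial contractility switches on at the first time the abnormal
#' count reaches \eqn{N_\theta}.  The mean abnormal area just before onset
#' is recorded as `a0` (it feeds the Scenario 2 interface calibration).
#'
#' @param config a [sim_config()] with `scenario = 2`.
#' @param tissue optional pre-built relaxed tissue.
#' @return a `tissue_trajectory`.
#' @export
run_scenario2 <- function(config, tissue = NULL) {
  set.seed(config$seed)
  m <- if (is.null(tissue)) base_tissue(config) else tissue
  # choose the seed cell among interior cells near the centre so the cluster
  # can reach N_theta before touching the boundary
  met <- vm_cell_metrics(unclass(m))
  d2 <- (met$cx - mean(met$cx))^2 + (met$cy - mean(met$cy))^2
  inner <- which(rank(d2, ties.method = "first") <=
                   max(1L, ceiling(0.25 * length(d2))))
  pick <- inner[sample.int(length(inner), 1)]
  m$type[pick] <- 1L
  m <- init_cell_clocks(m, config$cycle)
  t_end <- config$t_end_tau * config$cycle$tau_abnormal
  ctrl <- default_control(config, t_end, active = FALSE,
                          activate_at_N = config$N_theta)
  out <- vm_run(unclass(m), engine_params(config$mech, config$cycle), ctrl)
  traj <- new_trajectory(out, config, m, onset_time = NA_real_)
  if (is.na(traj$onset_time) && traj$status == 0L &&
      all(traj$samples$n_abnormal > 0))
    warning("cluster never reached N_theta within t_end")
  # abort diagnostic: cluster touching the free boundary before onset
  ed <- mesh_edges(traj$mesh)
  bcells <- unique(ed$c1[is.na(ed$c2)])
  if (any(traj$mesh$type[bcells] == 1L) && is.na(traj$onset_time))
    warning("abnormal cluster reached the tissue boundary before onset; ",
            "increase tissue_size")
  traj
}

#' Generic simulation driver
#'
#' Dispatches on `config$scenario`.
#'
#' @param config a [sim_config()].
#' @param ... passed to the scenario driver.
#' @return a `tissue_trajectory` (scenarios 1 and 2) or a fixed-wall result
#'   (see [run_fixed_wall()]).
#' @export
simulate_tissue <- function(config, ...) {
  if (identical(config$scenario, "fixed_wall")) run_fixed_wall(config, ...)
  else if (identical(config$scenario, 2) || identical(config$scenario, 2L))
    run_scenario2(config, ...)
  else run_scenario1(config, ...)
}

#' Fixed-wall proliferation: the mechanical homeostatic density
#'
#' Cells proliferate inside an immobile circular wall; with no
#' density-dependent rule in the model, the density climbs until cell
#' division is balanced by spontaneous T2 elimination, and plateaus at the
#' mechanical homeostatic density \eqn{\rho_1(\Lambda,\Gamma)}, independent
#' of the wall size.  The estimate is the temporal average of
#' \eqn{N/\sum A} over the second half of the run.
#'
#' @param config a [sim_config()]; `wall_rings` sets the disk size and
#'   `t_end_tau` the duration (30 cycles is ample for a small disk).
#' @return list with `rho1`, `sd` (temporal sd), `trend` (slope of the
#'   second-half densities per tau_A, with a warning if the plateau test
#'   fails), `trajectory`.
#' @export
run_fixed_wall <- function(config) {
  set.seed(config$seed)
  gs <- ground_state(config$mech$lambda_normal, config$mech$gamma_normal)
  n_target <- 1 + 3 * config$wall_rings * (config$wall_rings + 1)
  m <- build_hexagonal_tissue(n_target, gs$l_g, "fixed_wall")
  # proliferating population tracked as "abnormal" (tau_abnormal applies);
  # there is no interface, so mu never enters
  m$type[] <- 1L
  m <- init_cell_clocks(m, config$cycle)
  t_end <- config$t_end_tau * config$cycle$tau_abnormal
  ctrl <- default_control(config, t_end, active = FALSE)
  ctrl$bailout_n <- 0L
  ctrl$stop_on_extinct <- FALSE
  out <- vm_run(unclass(m), engine_params(config$mech, config$cycle), ctrl)
  traj <- new_trajectory(out, config, m, onset_time = 0)
  s <- traj$samples
  half <- s$t >= max(s$t) / 2
  rho <- s$n_abnormal[half] / s$area_abnormal[half]
  sl <- stats::coef(stats::lm(rho ~ s$t[half]))[2] *
    config$cycle$tau_abnormal
  if (abs(sl) > 0.05 * mean(rho))
    warning(sprintf("density still trending (%.3g per tau_A); run longer",
                    sl))
  list(rho1 = mean(rho), sd = stats::sd(rho), trend = unname(sl),
       trajectory = traj)
}

#' Contractility sweep: the elimination phase diagram
#'
#' For each \eqn{\mu} in `mu_grid`, runs `n_runs` seeded replicates of the
#' configured scenario, classifies each run (failure / growth suspension /
#' success), and tabulates outcome frequencies with per-run
#' \eqn{1/\bar\rho} values.  Hill fits of the failure and success curves
#' give the operational critical contractilities.
#'
#' @param base_config a [sim_config()] (its `mu` is overridden).
#' @param mu_grid contractility factors to sweep (>= 1).
#' @param n_runs replicates per grid point.
#' @param window classification window (default the config duration).
#' @return object of class `phase_diagram`: `mu_grid`, `freq` (matrix of
#'   failure/GS/success frequencies), `runs` (per-run table), `hill`
#'   (fits or NULL), `config`.
#' @export
sweep_contractility <- function(base_config, mu_grid, n_runs = 5,
                                window = NULL) {
  stopifnot(n_runs >= 1, all(mu_grid >= 1))
  if (is.null(window))
    window <- base_config$t_end_tau * base_config$cycle$tau_abnormal
  tau_A <- base_config$cycle$tau_abnormal
  set.seed(base_config$seed)
  shared <- if (!identical(base_config$scenario, "fixed_wall"))
    base_tissue(base_config) else NULL
  rows <- list()
  for (i in seq_along(mu_grid)) {
    for (j in seq_len(n_runs)) {
      cfg <- base_config
      cfg$mech$mu <- mu_grid[i]
      cfg$seed <- (base_config$seed * 1009L + i * 97L + j) %% 2147483647L
      traj <- simulate_tissue(cfg, tissue = shared)
      rb <- rho_bar(traj, tau_A)
      oc <- classify_outcome(traj, cfg$N_theta, tau_A,
                             gs_threshold = cfg$gs_threshold,
                             window = min(window,
                                          max(traj$samples$t) -
                                            max(0, traj$onset_time,
                                                na.rm = TRUE)))
      rows[[length(rows) + 1L]] <- data.frame(
        mu = mu_grid[i], seed = cfg$seed, outcome = oc,
        inv_rho_bar = rb$inv_rho_bar,
        a0 = if (is.null(traj$a0)) NA_real_ else traj$a0,
        onset_time = traj$onset_time)
    }
  }
  runs <- do.call(rbind, rows)
  freq <- t(vapply(mu_grid, function(m) {
    oc <- runs$outcome[runs$mu == m]
    c(failure = mean(oc == "failure"),
      growth_suspension = mean(oc == "growth_suspension"),
      success = mean(oc == "success"))
  }, numeric(3)))
  hill <- list(failure = NULL, success = NULL)
  if (length(mu_grid) >= 3) {
    hill$failure <- tryCatch(
      hill_fit(mu_grid * base_config$mech$lambda_normal, freq[, "failure"],
               "decreasing"), error = function(e) NULL)
    hill$success <- tryCatch(
      hill_fit(mu_grid * base_config$mech$lambda_normal, freq[, "success"],
               "increasing"), error = function(e) NULL)
  }
  structure(list(mu_grid = mu_grid, freq = freq, runs = runs, hill = hill,
                 config = base_config),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> outcome frequencies:\n")
  print(cbind(mu = x$mu_grid, round(x$freq, 3)))
  if (!is.null(x$hill$success))
    cat(sprintf("success Hill midpoint: mu*Lambda = %.4g (h = %.3g)\n",
                x$hill$success$K, x$hill$success$h))
  invisible(x)
}

#' Relative-proliferation-rate experiment
#'
#' Sweeps the phase diagram for several relative growth rates
#' \eqn{r = \tau_N/\tau_A}, realized by changing the normal cycle duration
#' while leaving \eqn{\tau_A} unchanged (`r = Inf` recovers non-dividing
#' normal cells).  Slower relative proliferation of abnormal cells makes
#' them *harder* to eliminate.
#'
#' @param base_config a [sim_config()].
#' @param r_values relative growth rates (may include `Inf`).
#' @param mu_grid,n_runs,window passed to [sweep_contractility()].
#' @return named list of `phase_diagram`s, one per r.
#' @export
run_relative_growth_experiment <- function(base_config, r_values, mu_grid,
                                           n_runs = 5, window = NULL) {
  out <- list()
  for (r in r_values) {
    cfg <- base_config
    cfg$cycle$tau_normal <- r * cfg$cycle$tau_abnormal
    out[[paste0("r=", r)]] <- sweep_contractility(cfg, mu_grid, n_runs,
                                                  window)
  }
  out
}
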