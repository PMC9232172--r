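#' Cell-cycle parameters
#'
#' Clock-driven cycle: each cell's clock advances linearly with time; when it
#' reaches the cell's drawn threshold \eqn{\tau (1 + u)},
#' \eqn{u \sim U(-j, j)}, the cell enters the mitotic phase, during which its
#' target area grows as \eqn{1 + b\,t_m}.  The cell divides when its actual
#' area doubles relative to the area at mitosis entry (`"doubling"`) or has
#' grown by a fixed increment \eqn{\delta A} (`"adder"`).  The threshold is
#' redrawn at every birth, which desynchronizes a clonal population.  The
#' cycle duration is deliberately independent of density.
#'
#' @param tau_abnormal cycle duration of abnormal cells (time units; `Inf`
#'   disables division).
#' @param tau_normal cycle duration of normal cells (default `Inf`: only
#'   abnormal cells proliferate).
#' @param jitter_fraction half-width of the uniform threshold jitter
#'   (fraction of tau; default 0.2, i.e. +/- 20 percent).
#' @param growth_rate_b growth rate of the mitotic target area.
#' @param division_rule `"doubling"` or `"adder"`.
#' @param doubling_baseline reference area for the doubling rule:
#'   `"entry"` (default; divide when the actual area reaches twice the area
#'   at mitosis entry, paralleling the adder rule's baseline) or
#'   `"preferred"` (twice the preferred area, i.e. an absolute threshold
#'   of 2).  The entry baseline keeps mitoses brief and gentle; the
#'   preferred baseline makes division stall under crowding and is kept as
#'   a documented alternative.
#' @param delta_A adder increment (used only under the adder rule).
#' @param orientation_rule `"random"` (uniform division angle) or
#'   `"long_axis"` (perpendicular to the cell's long axis).
#' @param tm_cap numerical guard: the mitotic time entering the target area
#'   is capped at this value so a geometrically blocked cell cannot build an
#'   unbounded area stress (default 0.5, i.e. target capped at `1 + 0.5 b`).
#' @return object of class `cycle_params`.
#' @export
cycle_params <- function(tau_abnormal = 5, tau_normal = Inf,
                         jitter_fraction = 0.2, growth_rate_b = 10,
                         division_rule = c("doubling", "adder"),
                         delta_A = 0.15,
                         orientation_rule = c("random", "long_axis"),
                         doubling_baseline = c("entry", "preferred"),
                         tm_cap = 0.5) {
  division_rule <- match.arg(division_rule)
  doubling_baseline <- match.arg(doubling_baseline)
  orientation_rule <- match.arg(orientation_rule)
  stopifnot(tau_abnormal > 0, tau_normal > 0,
            jitter_fraction >= 0, jitter_fraction < 1,
            growth_rate_b > 0, delta_A > 0)
  structure(list(
    tau_abnormal = tau_abnormal, tau_normal = tau_normal,
    jitter_fraction = jitter_fraction, growth_rate_b = growth_rate_b,
    division_rule = division_rule, delta_A = delta_A,
    orientation_rule = orientation_rule,
    doubling_baseline = doubling_baseline, tm_cap = tm_cap),
    class = "cycle_params")
}

tau_of <- function(cycle, type) {
  ifelse(type == 1L, cycle$tau_abnormal, cycle$tau_normal)
}

#' Initialize cell-cycle clocks
#'
#' Draws, for every cell with a finite cycle duration, an initial clock
#' uniform on \eqn{[0, \tau)} and a cycle threshold \eqn{\tau(1+u)},
#' \eqn{u \sim U(-j, j)}.  Starting clocks at random phases prevents a
#' synchronized first division wave.
#'
#' @param mesh a [tissue_mesh()].
#' @param cycle a [cycle_params()].
#' @return the mesh with `clock` and `threshold` filled in.
#' @export
init_cell_clocks <- function(mesh, cycle) {
  tau <- tau_of(cycle, mesh$type)
  fin <- is.finite(tau)
  n <- length(tau)
  thr <- rep(Inf, n)
  clk <- rep(0, n)
  if (any(fin)) {
    j <- cycle$jitter_fraction
    thr[fin] <- tau[fin] * (1 + j * (2 * runif(sum(fin)) - 1))
    clk[fin] <- runif(sum(fin)) * tau[fin]
    clk[fin] <- pmin(clk[fin], thr[fin] * 0.999)
  }
  mesh$threshold <- thr
  mesh$clock <- clk
  mesh
}

#' Advance cell-cycle clocks
#'
#' Adds `dt` to every clock; interphase cells whose clock has reached their
#' threshold enter the mitotic phase (recording entry time and entry area).
#'
#' @param mesh a [tissue_mesh()].
#' @param cycle a [cycle_params()].
#' @param dt time increment.
#' @param t_now current time (stored as the mitosis entry time).
#' @return the updated mesh; the ids of cells that entered mitosis are in
#'   attribute `"mitosis_entries"`.
#' @export
advance_cell_cycle <- function(mesh, cycle, dt, t_now = 0) {
  mesh$clock <- mesh$clock + dt
  entering <- which(mesh$phase == 0L & mesh$clock >= mesh$threshold)
  if (length(entering)) {
    met <- vm_cell_metrics(unclass(mesh))
    mesh$phase[entering] <- 1L
    mesh$t_entry[entering] <- t_now + dt
    mesh$a_entry[entering] <- met$area[entering]
  }
  attr(mesh, "mitosis_entries") <- mesh$cell_id[entering]
  mesh
}

#' Mitotic target area
#'
#' Target area entering the area-elasticity term: `1` in interphase and
#' \eqn{1 + b (t - t_{entry})} during mitosis.
#'
#' @param mesh a [tissue_mesh()].
#' @param cycle a [cycle_params()].
#' @param t_now current time.
#' @return numeric vector of per-cell target areas.
#' @export
mitotic_target_area <- function(mesh, cycle, t_now) {
  tm <- pmax(0, pmin(t_now - mesh$t_entry, cycle$tm_cap))
  ifelse(mesh$phase == 1L, 1 + cycle$growth_rate_b * tm, 1)
}

#' Division trigger
#'
#' A mitotic cell divides when its actual area reaches the doubling
#' reference (twice the preferred area, or twice its entry area under the
#' `"entry"` baseline) or its entry area plus \eqn{\delta A} (adder rule).
#' Interphase cells never trigger.
#'
#' @param mesh a [tissue_mesh()].
#' @param cycle a [cycle_params()].
#' @param current_area optional per-cell areas (computed from the mesh if
#'   missing).
#' @return logical vector.
#' @export
division_trigger <- function(mesh, cycle, current_area = NULL) {
  if (is.null(current_area)) current_area <- vm_cell_metrics(unclass(mesh))$area
  mitotic <- mesh$phase == 1L
  if (cycle$division_rule == "adder") {
    mitotic & current_area >= mesh$a_entry + cycle$delta_A
  } else if (cycle$doubling_baseline == "entry") {
    mitotic & current_area >= 2 * mesh$a_entry
  } else {
    mitotic & current_area >= 2
  }
}
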