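#' T1 edge reconnection
#'
#' Reconnects the interior edge between vertices `v1` and `v2`: the two cells
#' sharing the edge lose it, the two cells meeting it end-on gain it, and the
#' new edge is placed perpendicular to the old one through its midpoint with
#' length `new_edge_factor * theta_T1` (so a fresh edge cannot retrigger
#' immediately).  A reconnection that would create a 2-sided cell, involve a
#' fixed vertex, or hit an irregular junction is skipped.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [mech_params()].
#' @param v1,v2 vertex indices of the edge.
#' @param t_now current time (for the event record).
#' @return the updated mesh; attribute `"applied"` reports whether the
#'   reconnection happened.
#' @export
apply_t1 <- function(mesh, params, v1, v2, t_now = 0) {
  out <- vm_apply_t1(unclass(mesh), engine_params(params), as.integer(v1),
                     as.integer(v2), t_now)
  m <- rewrap_mesh(out$mesh, mesh)
  attr(m, "applied") <- out$applied
  m
}

#' T2 cell removal
#'
#' Removes a cell (of any polygon class) whose area has fallen below the T2
#' threshold: all its vertices merge into a single vertex at its centroid and
#' the neighbours' loops are rewired.  A removal that would pinch a
#' neighbour below 3 vertices is skipped.
#'
#' @inheritParams apply_t1
#' @param cell_id id of the cell to remove.
#' @return the updated mesh; attribute `"applied"` as in [apply_t1()].
#' @export
apply_t2 <- function(mesh, params, cell_id, t_now = 0) {
  i <- match(cell_id, mesh$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cell_id)
  out <- vm_apply_t2(unclass(mesh), engine_params(params), i, t_now)
  m <- rewrap_mesh(out$mesh, mesh)
  attr(m, "applied") <- out$applied
  m
}

#' Cell division
#'
#' Splits a cell by a straight line through its (area) centroid.  Under the
#' random rule the angle is uniform on \eqn{[0, \pi)}; under the long-axis
#' rule it is perpendicular to the principal axis of the vertex
#' second-moment tensor.  Two new vertices are inserted on the crossed
#' edges; both daughters inherit the mother's type, reset their clocks to
#' zero, and redraw their cycle thresholds.  If the chosen line does not
#' cross exactly two edges the orientation is resampled (bounded retries).
#'
#' @inheritParams apply_t2
#' @param cycle a [cycle_params()] (threshold redraw + orientation rule).
#' @param angle optional fixed division angle (radians); when `NULL` the
#'   orientation rule decides.
#' @param max_retries resampling attempts for a failing line.
#' @return the updated mesh; attribute `"applied"` as in [apply_t1()].
#' @export
divide_cell <- function(mesh, params, cell_id, cycle = cycle_params(),
                        angle = NULL, t_now = 0, max_retries = 16) {
  i <- match(cell_id, mesh$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cell_id)
  ep <- engine_params(params, cycle)
  if (!is.null(angle)) {
    out <- vm_divide_cell(unclass(mesh), ep, i, angle, t_now)
  } else {
    out <- NULL
    for (k in seq_len(max_retries)) {
      a <- if (cycle$orientation_rule == "long_axis") {
        g <- cell_geometry(mesh, cell_id)
        loop <- mesh$cells[[i]]
        V <- sweep(mesh$vertices[loop, , drop = FALSE], 2, g$centroid)
        s <- crossprod(V)
        0.5 * atan2(2 * s[1, 2], s[1, 1] - s[2, 2]) + pi / 2 +
          if (k > 1) (runif(1) - 0.5) * 0.5 else 0
      } else {
        runif(1) * pi
      }
      out <- vm_divide_cell(unclass(mesh), ep, i, a, t_now)
      if (out$applied) break
    }
  }
  m <- rewrap_mesh(out$mesh, mesh)
  attr(m, "applied") <- out$applied
  m
}

#' Resolve all pending topological events
#'
#' Scans the mesh for T1 candidates (shortest first), then T2 candidates
#' (smallest first), then division triggers, applies one event and re-scans,
#' up to `max_iter` events per call.  This is the per-step event resolution
#' used inside [simulate_tissue()].
#'
#' @inheritParams divide_cell
#' @param divisions_on scan for division triggers?
#' @param max_iter event cap per call (default 10).
#' @param contractility_active is the interfacial contractility on?
#' @return list with `mesh` (updated), `n_applied`, and `events`
#'   (data.frame: time, kind 1=T1 / 2=T2 / 3=division, cell_id, x, y).
#' @export
resolve_events <- function(mesh, params, cycle = cycle_params(), t_now = 0,
                           divisions_on = TRUE, max_iter = 10,
                           contractility_active = TRUE) {
  out <- vm_resolve_events(unclass(mesh), engine_params(params, cycle),
                           t_now, divisions_on, as.integer(max_iter),
                           contractility_active)
  list(mesh = rewrap_mesh(out$mesh, mesh), n_applied = out$n_applied,
       events = out$events)
}
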