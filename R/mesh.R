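#' Planar polygonal tissue mesh
#'
#' A `tissue_mesh` represents the apical surface of an epithelial sheet as a
#' planar polygonal tiling: a table of 2D vertex positions plus one
#' counter-clockwise vertex loop per cell.  Each cell carries its type
#' (normal or abnormal), a cell-cycle clock, the drawn cycle threshold, and
#' the bookkeeping needed by the mitotic growth rule.  All coordinates are in
#' the nondimensional units of the energy function (preferred cell area = 1).
#'
#' @param vertices numeric matrix (n x 2) of vertex positions.
#' @param cells list of integer vectors; each is a CCW vertex loop (1-based).
#' @param type integer vector, 0 = normal, 1 = abnormal (recycled if length 1).
#' @param fixed logical vector of immobilized-vertex flags (default all free).
#' @param boundary_condition `"free"` or `"fixed_wall"`.
#' @param cell_id integer ids (default `seq_along(cells)`).
#' @param clock,threshold,t_entry,a_entry,area_birth cell-cycle state vectors;
#'   sensible defaults are supplied (interphase, clock 0, infinite threshold).
#' @param phase integer vector, 0 = interphase, 1 = mitotic.
#' @return an object of class `tissue_mesh`.
#' @seealso [build_hexagonal_tissue()], [validate_mesh()], [cell_geometry()]
#' @export
tissue_mesh <- function(vertices, cells, type = 0L, fixed = NULL,
                        boundary_condition = c("free", "fixed_wall"),
                        cell_id = NULL, clock = NULL, threshold = NULL,
                        phase = NULL, t_entry = NULL, a_entry = NULL,
                        area_birth = NULL) {
  boundary_condition <- match.arg(boundary_condition)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L) stop("vertices must be an n x 2 matrix")
  nc <- length(cells)
  cells <- lapply(cells, as.integer)
  n <- nrow(vertices)
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  m <- list(
    vertices = vertices,
    fixed = as.logical(fixed),
    cells = cells,
    cell_id = if (is.null(cell_id)) seq_len(nc) else as.integer(cell_id),
    type = as.integer(rep_len(type, nc)),
    phase = as.integer(if (is.null(phase)) rep(0L, nc) else phase),
    clock = as.double(if (is.null(clock)) rep(0, nc) else clock),
    threshold = as.double(if (is.null(threshold)) rep(Inf, nc) else threshold),
    t_entry = as.double(if (is.null(t_entry)) rep(-1, nc) else t_entry),
    a_entry = as.double(if (is.null(a_entry)) rep(-1, nc) else a_entry),
    area_birth = as.double(if (is.null(area_birth)) rep(NA_real_, nc)
                           else area_birth)
  )
  structure(m, class = "tissue_mesh", boundary_condition = boundary_condition)
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf(
    "<tissue_mesh> %d cells (%d abnormal), %d vertices, boundary: %s\n",
    length(x$cells), sum(x$type == 1L), nrow(x$vertices),
    attr(x, "boundary_condition")))
  invisible(x)
}

# re-wrap an engine-exported mesh list as a tissue_mesh
rewrap_mesh <- function(m, template) {
  structure(m, class = "tissue_mesh",
            boundary_condition = attr(template, "boundary_condition"))
}

#' Build a hexagonal tissue patch
#'
#' Constructs a roughly circular patch of regular hexagons centred at the
#' origin, the standard initial condition for vertex-model simulations.  The
#' patch is assembled ring by ring (ring `k` holds `1 + 3k(k+1)` cells), and
#' the ring count is chosen to bring the cell count as close as possible to
#' `n_cells_target`.  With `edge_length` equal to the ground-state edge
#' length of the mechanical parameters in use, the interior of the patch is
#' already the energy-minimizing configuration.
#'
#' @param n_cells_target desired number of cells (>= 1).
#' @param edge_length hexagon edge length (> 0).
#' @param boundary_condition `"free"` or `"fixed_wall"`; under `fixed_wall`
#'   every vertex on the outer rim is immobilized.
#' @return a [tissue_mesh()] of normal cells in interphase.
#' @examples
#' m <- build_hexagonal_tissue(7, 1.0)
#' length(m$cells)     # 7
#' @export
build_hexagonal_tissue <- function(n_cells_target, edge_length,
                                   boundary_condition = c("free", "fixed_wall")) {
  boundary_condition <- match.arg(boundary_condition)
  if (n_cells_target < 1) stop("n_cells_target must be >= 1")
  if (edge_length <= 0) stop("edge_length must be > 0")
  counts <- 1 + 3 * (0:60) * (1:61)
  k <- which.min(abs(counts - n_cells_target)) - 1L

  # axial coordinates of hexagon centres within k rings
  centres <- list()
  for (q in -k:k) for (r in max(-k, -q - k):min(k, -q + k))
    centres[[length(centres) + 1L]] <- c(q, r)
  l <- edge_length
  ang <- pi / 6 + (0:5) * pi / 3     # pointy-top hexagon, CCW
  vkey <- new.env(hash = TRUE, parent = emptyenv())
  vx <- numeric(0); vy <- numeric(0)
  cells <- vector("list", length(centres))
  for (i in seq_along(centres)) {
    q <- centres[[i]][1]; r <- centres[[i]][2]
    cx <- l * sqrt(3) * (q + r / 2)
    cy <- l * 1.5 * r
    loop <- integer(6)
    for (j in 1:6) {
      x <- cx + l * cos(ang[j]); y <- cy + l * sin(ang[j])
      key <- paste(round(x / l * 1e6), round(y / l * 1e6))
      id <- vkey[[key]]
      if (is.null(id)) {
        vx <- c(vx, x); vy <- c(vy, y)
        id <- length(vx)
        assign(key, id, envir = vkey)
      }
      loop[j] <- id
    }
    cells[[i]] <- loop
  }
  m <- tissue_mesh(cbind(vx, vy), cells,
                   boundary_condition = boundary_condition)
  if (boundary_condition == "fixed_wall") {
    ed <- mesh_edges(m)
    bverts <- unique(c(ed$v1[is.na(ed$c2)], ed$v2[is.na(ed$c2)]))
    m$fixed[bverts] <- TRUE
  }
  m
}

#' Edge table of a mesh
#'
#' Derives the undirected edge list with the one or two incident cells of
#' each edge (`c2` is `NA` on the tissue boundary).  This R-side derivation
#' is independent of the compiled engine and is used by the validator and
#' the stress-tensor calculation.
#'
#' @param mesh a [tissue_mesh()].
#' @return data.frame with columns `v1`, `v2`, `c1`, `c2`, `length`.
#' @export
mesh_edges <- function(mesh) {
  v1 <- integer(0); v2 <- integer(0); cc <- integer(0)
  for (c in seq_along(mesh$cells)) {
    loop <- mesh$cells[[c]]
    nxt <- c(loop[-1], loop[1])
    v1 <- c(v1, pmin(loop, nxt))
    v2 <- c(v2, pmax(loop, nxt))
    cc <- c(cc, rep.int(c, length(loop)))
  }
  key <- paste(v1, v2)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  c1 <- cc[first]
  c2 <- rep(NA_integer_, sum(first))
  dup <- which(!first)
  c2[idx[dup]] <- cc[dup]
  over <- tabulate(idx, nbins = sum(first))
  V <- mesh$vertices
  len <- sqrt((V[v2[first], 1] - V[v1[first], 1])^2 +
              (V[v2[first], 2] - V[v1[first], 2])^2)
  out <- data.frame(v1 = v1[first], v2 = v2[first], c1 = c1, c2 = c2,
                    length = len)
  attr(out, "multiplicity") <- over
  out
}

#' Geometry of one cell
#'
#' Area (shoelace formula on the ordered loop), perimeter, and area centroid.
#'
#' @param mesh a [tissue_mesh()].
#' @param cell_id a cell id present in `mesh$cell_id`.
#' @return list with `area`, `perimeter`, `centroid` (length-2 numeric),
#'   and `n_sides`.
#' @export
cell_geometry <- function(mesh, cell_id) {
  i <- match(cell_id, mesh$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cell_id)
  loop <- mesh$cells[[i]]
  V <- mesh$vertices[loop, , drop = FALSE]
  n <- nrow(V)
  j <- c(2:n, 1)
  cr <- V[, 1] * V[j, 2] - V[j, 1] * V[, 2]
  area <- sum(cr) / 2
  per <- sum(sqrt(rowSums((V[j, , drop = FALSE] - V)^2)))
  if (abs(area) < 1e-14) {
    cen <- colMeans(V)
  } else {
    cen <- c(sum((V[, 1] + V[j, 1]) * cr), sum((V[, 2] + V[j, 2]) * cr)) /
      (6 * area)
  }
  list(area = area, perimeter = per, centroid = cen, n_sides = n)
}

# do segments (p1,p2) and (p3,p4) properly intersect?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Validate a tissue mesh
#'
#' Checks the structural invariants of the polygonal tiling: each loop has at
#' least 3 distinct vertices, is counter-clockwise (positive shoelace area),
#' and is simple; no edge is claimed by more than two cells; vertex indices
#' are in range.
#'
#' @param mesh a [tissue_mesh()].
#' @param check_simple also run the O(m^2)-per-cell self-intersection test
#'   (default `TRUE`; disable for very large meshes).
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_mesh <- function(mesh, check_simple = TRUE) {
  bad <- character(0)
  nv <- nrow(mesh$vertices)
  for (c in seq_along(mesh$cells)) {
    loop <- mesh$cells[[c]]
    if (any(loop < 1 | loop > nv)) {
      bad <- c(bad, sprintf("cell %d: vertex index out of range", c))
      next
    }
    if (length(loop) < 3)
      bad <- c(bad, sprintf("cell %d: fewer than 3 vertices", c))
    if (anyDuplicated(loop))
      bad <- c(bad, sprintf("cell %d: degenerate loop (repeated vertex)", c))
    a <- cell_geometry(mesh, mesh$cell_id[c])$area
    if (!is.na(a) && a <= 0)
      bad <- c(bad, sprintf("cell %d: non-positive area (clockwise loop?)", c))
    if (check_simple && length(loop) >= 4 && !anyDuplicated(loop)) {
      V <- mesh$vertices
      n <- length(loop)
      for (i in seq_len(n - 2)) {
        jmax <- if (i == 1) n - 1 else n
        for (j in (i + 2):jmax) {
          if (j > n - 1 && i == 1) next
          p1 <- V[loop[i], ]; p2 <- V[loop[i %% n + 1], ]
          p3 <- V[loop[j], ]; p4 <- V[loop[j %% n + 1], ]
          if (segments_cross(p1, p2, p3, p4)) {
            bad <- c(bad, sprintf("cell %d: self-intersecting loop", c))
            break
          }
        }
      }
    }
  }
  ed <- mesh_edges(mesh)
  mult <- attr(ed, "multiplicity")
  if (any(mult > 2))
    bad <- c(bad, sprintf("incidence: edge (%d,%d) shared by %d cells",
                          ed$v1[mult > 2][1], ed$v2[mult > 2][1],
                          max(mult)))
  bad
}

#' Write / read a tissue snapshot
#'
#' Lossless, versioned structured-text serialization of a mesh: header,
#' vertex table, cell table (type, cycle state, ordered loop).  Values are
#' written with full double precision so that `read(write(m))` reproduces
#' `m` to machine precision.
#'
#' @param mesh a [tissue_mesh()].
#' @param path file path.
#' @param time simulation time stored in the header.
#' @param params_hash optional provenance string stored in the header.
#' @return `write_tissue_snapshot` returns `path` invisibly;
#'   `read_tissue_snapshot` returns a [tissue_mesh()] (with the stored time
#'   in attribute `"time"`).
#' @export
write_tissue_snapshot <- function(mesh, path, time = 0, params_hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  wl("# vertexcomp snapshot v1")
  wl("time ", num(time))
  wl("boundary ", attr(mesh, "boundary_condition"))
  wl("params_hash ", params_hash)
  wl("vertices ", nrow(mesh$vertices))
  for (i in seq_len(nrow(mesh$vertices)))
    wl(i, " ", num(mesh$vertices[i, 1]), " ", num(mesh$vertices[i, 2]), " ",
       as.integer(mesh$fixed[i]))
  wl("cells ", length(mesh$cells))
  labels <- c("normal", "abnormal")
  for (c in seq_along(mesh$cells))
    wl(mesh$cell_id[c], " ", labels[mesh$type[c] + 1L], " ", mesh$phase[c],
       " ", num(mesh$clock[c]), " ", num(mesh$threshold[c]), " ",
       num(mesh$t_entry[c]), " ", num(mesh$a_entry[c]), " ",
       num(mesh$area_birth[c]), " ", length(mesh$cells[[c]]), " ",
       paste(mesh$cells[[c]], collapse = " "))
  invisible(path)
}

#' @rdname write_tissue_snapshot
#' @export
read_tissue_snapshot <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "# vertexcomp snapshot v1"))
    stop("snapshot parse error: unrecognized header: ", ln[1])
  fields <- strsplit(ln, " +")
  num_tok <- function(x) {           # "NA"/"Inf" tokens without coercion noise
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & x != "NA"
    out[ok] <- as.numeric(x[ok])
    out
  }
  get1 <- function(i, key) {
    if (fields[[i]][1] != key)
      stop("snapshot parse error at line ", i, ": expected '", key, "'")
    fields[[i]][2]
  }
  time <- num_tok(get1(2, "time"))
  boundary <- get1(3, "boundary")
  if (!boundary %in% c("free", "fixed_wall"))
    stop("snapshot parse error: unknown boundary '", boundary, "'")
  nv <- as.integer(get1(5, "vertices"))
  V <- matrix(0, nv, 2); fixed <- logical(nv)
  for (i in seq_len(nv)) {
    f <- fields[[5 + i]]
    if (length(f) != 4) stop("snapshot parse error: vertex record ", i)
    V[i, ] <- num_tok(f[2:3]); fixed[i] <- f[4] == "1"
  }
  off <- 5 + nv
  ncl <- as.integer(get1(off + 1, "cells"))
  cells <- vector("list", ncl)
  cell_id <- integer(ncl); type <- integer(ncl); phase <- integer(ncl)
  clock <- threshold <- t_entry <- a_entry <- area_birth <- numeric(ncl)
  for (c in seq_len(ncl)) {
    f <- fields[[off + 1 + c]]
    if (length(f) < 10) stop("snapshot parse error: cell record ", c)
    cell_id[c] <- as.integer(f[1])
    ty <- match(f[2], c("normal", "abnormal"))
    if (is.na(ty)) stop("snapshot parse error: unknown cell_type '", f[2],
                        "' in cell record ", c)
    type[c] <- ty - 1L
    phase[c] <- as.integer(f[3])
    clock[c] <- num_tok(f[4]); threshold[c] <- num_tok(f[5])
    t_entry[c] <- num_tok(f[6]); a_entry[c] <- num_tok(f[7])
    area_birth[c] <- num_tok(f[8])
    k <- as.integer(f[9])
    if (length(f) != 9 + k)
      stop("snapshot parse error: cell record ", c, " loop length mismatch")
    cells[[c]] <- as.integer(f[10:(9 + k)])
  }
  m <- tissue_mesh(V, cells, type = type, fixed = fixed,
                   boundary_condition = boundary, cell_id = cell_id,
                   clock = clock, threshold = threshold, phase = phase,
                   t_entry = t_entry, a_entry = a_entry,
                   area_birth = area_birth)
  attr(m, "time") <- time
  m
}

#' @export
plot.tissue_mesh <- function(x, col_normal = "grey90",
                             col_abnormal = "indianred2", ...) {
  V <- x$vertices
  plot(NA, xlim = range(V[, 1]), ylim = range(V[, 2]), asp = 1,
       xlab = "", ylab = "", axes = FALSE, ...)
  for (c in seq_along(x$cells)) {
    loop <- x$cells[[c]]
    polygon(V[loop, 1], V[loop, 2],
            col = if (x$type[c] == 1L) col_abnormal else col_normal,
            border = "grey30", lwd = 0.5)
  }
  invisible(x)
}
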