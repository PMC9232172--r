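test_that("T1 on the pinwheel: reconnection combinatorics", {
  pw <- make_fixture("pinwheel4")
  p <- solid_params()
  before <- lengths(pw$cells)
  out <- apply_t1(pw, p, 1, 2)
  expect_true(attr(out, "applied"))
  expect_length(validate_mesh(out), 0)
  after <- lengths(out$cells)
  # side counts change by exactly (-1, -1, +1, +1)
  expect_equal(sort(after - before), c(-1, -1, 1, 1))
  # cell count and vertex count conserved
  expect_length(out$cells, 4)
  expect_equal(nrow(out$vertices), nrow(pw$vertices))
  # the previously non-incident pair (top, bottom) now shares the edge
  ed <- mesh_edges(out)
  shares <- ed[!is.na(ed$c2), c("c1", "c2")]
  expect_true(any((shares$c1 == 3 & shares$c2 == 4) |
                  (shares$c1 == 4 & shares$c2 == 3)))
  # new edge length 1.5 * theta_T1 does not retrigger
  gs <- ground_state(0.12, 0.04)
  newe <- ed[(ed$c1 %in% 3:4) & (ed$c2 %in% 3:4) & !is.na(ed$c2), ]
  expect_equal(newe$length, 1.5 * 0.01 * gs$l_g, tolerance = 1e-9)
  expect_gt(newe$length, 0.01 * gs$l_g)
})

test_that("T1 skips degenerate cases", {
  pw <- make_fixture("pinwheel4")
  p <- solid_params()
  # reconnecting an edge of a triangle would create a 2-sided cell
  ed <- mesh_edges(pw)
  tri_edge <- ed[!is.na(ed$c2) & (lengths(pw$cells)[ed$c1] == 3 |
                                  lengths(pw$cells)[ed$c2] == 3), ][1, ]
  out <- apply_t1(pw, p, tri_edge$v1, tri_edge$v2)
  expect_false(attr(out, "applied"))
  # fixed vertices block the move
  pw2 <- pw; pw2$fixed[1] <- TRUE
  expect_false(attr(apply_t1(pw2, p, 1, 2), "applied"))
})

test_that("T2 removes a cell and rewires the neighbours", {
  r7 <- make_fixture("rosette7")
  p <- solid_params()
  ctr <- which.min(colSums(vapply(r7$cell_id, function(id)
    cell_geometry(r7, id)$centroid, numeric(2))^2))
  nv_cell <- length(r7$cells[[ctr]])
  out <- apply_t2(r7, p, r7$cell_id[ctr])
  expect_true(attr(out, "applied"))
  expect_length(validate_mesh(out), 0)
  expect_length(out$cells, 6)
  # vertex count decreases by (n_vertices_of_cell - 1)
  expect_equal(nrow(out$vertices), nrow(r7$vertices) - (nv_cell - 1))
  # each neighbour loses one vertex pair
  expect_true(all(lengths(out$cells) == 5))
  expect_error(apply_t2(r7, p, 999))
})

test_that("division surgery: conservation and combinatorics", {
  p <- solid_params()
  cyc <- cycle_params()
  # hexagon split through two opposite edges -> two pentagons
  h <- make_fixture("hex1")
  hd <- divide_cell(h, p, 1, cyc, angle = 0)
  expect_true(attr(hd, "applied"))
  expect_equal(lengths(hd$cells), c(5, 5))
  met <- cell_geometry(hd, hd$cell_id[1])$area +
    cell_geometry(hd, hd$cell_id[2])$area
  expect_equal(met, cell_geometry(h, 1)$area, tolerance = 1e-12)
  expect_length(validate_mesh(hd), 0)
  # daughters inherit type, reset clocks, record birth area
  r7 <- make_fixture("rosette7")
  ctr <- which.min(colSums(vapply(r7$cell_id, function(id)
    cell_geometry(r7, id)$centroid, numeric(2))^2))
  r7$type[ctr] <- 1L
  r7$clock[ctr] <- 4.2
  set.seed(1)
  rd <- divide_cell(r7, p, r7$cell_id[ctr], cyc, angle = 0)
  expect_true(attr(rd, "applied"))
  expect_length(validate_mesh(rd), 0)
  newc <- which(!(rd$cell_id %in% r7$cell_id))
  expect_length(newc, 2)
  expect_true(all(rd$type[newc] == 1L))
  expect_true(all(rd$clock[newc] == 0))
  expect_true(all(is.finite(rd$area_birth[newc])))
  # the two cells adjacent to the crossed edges each gain one vertex
  old <- setdiff(seq_along(rd$cells), newc)
  gained <- sum(lengths(rd$cells[old]) -
                  lengths(r7$cells[match(rd$cell_id[old], r7$cell_id)]) == 1)
  expect_equal(gained, 2)
  # sibling thresholds are independent draws
  expect_false(rd$threshold[newc[1]] == rd$threshold[newc[2]])
})

test_that("division line through vertices is rejected, resampling works", {
  p <- solid_params()
  h <- make_fixture("hex1")
  # vertical line passes through two vertices of the pointy-top hexagon
  out <- divide_cell(h, p, 1, cycle_params(), angle = pi / 2)
  expect_false(attr(out, "applied"))
  # free resampling succeeds
  set.seed(2)
  out2 <- divide_cell(h, p, 1, cycle_params())
  expect_true(attr(out2, "applied"))
})

test_that("resolve_events: ordering, idempotence on quiet meshes", {
  p <- solid_params()
  cyc <- cycle_params()
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(19, gs$l_g)
  out <- resolve_events(m, p, cyc)
  expect_equal(out$n_applied, 0)
  expect_identical(out$mesh$cells, m$cells)
  # a mesh with two short disjoint edges: both reconnected in one pass
  pw <- make_fixture("pinwheel4")
  # shrink an edge of the rosette far from another shrunk edge
  m2 <- build_hexagonal_tissue(19, gs$l_g)
  ed <- mesh_edges(m2)
  inter <- ed[!is.na(ed$c2), ]
  # pick two interior edges with disjoint vertices, both interior junctions
  # both endpoints must be interior tri-junctions (3 incident cells)
  ncell <- tabulate(unlist(lapply(seq_along(m2$cells), function(c)
    unique(m2$cells[[c]]))), nbins = nrow(m2$vertices))
  ok <- inter[ncell[inter$v1] == 3 & ncell[inter$v2] == 3, ]
  e1 <- ok[1, ]
  e2 <- ok[which(!(ok$v1 %in% c(e1$v1, e1$v2)) &
                 !(ok$v2 %in% c(e1$v1, e1$v2)))[8], ]
  shrink <- function(m, a, b) {
    mid <- colMeans(m$vertices[c(a, b), ])
    m$vertices[a, ] <- mid + c(1e-4, 0)
    m$vertices[b, ] <- mid - c(1e-4, 0)
    m
  }
  m2 <- shrink(m2, e1$v1, e1$v2)
  m2 <- shrink(m2, e2$v1, e2$v2)
  out2 <- resolve_events(m2, p, cyc)
  expect_equal(sum(out2$events$kind == 1), 2)
  expect_length(validate_mesh(out2$mesh), 0)
})

test_that("event surgery preserves mesh validity under random hammering", {
  # property test: repeated divisions + resolutions keep the mesh valid
  set.seed(31)
  p <- solid_params(dt = 1e-3)
  cyc <- cycle_params()
  gs <- ground_state(0.12, 0.04)
  m <- build_hexagonal_tissue(19, gs$l_g)
  for (k in 1:12) {
    id <- sample(m$cell_id, 1)
    m2 <- divide_cell(m, p, id, cyc)
    if (attr(m2, "applied")) m <- m2
    m <- euler_step(m, p, cyc, n_steps = 50)
    m <- resolve_events(m, p, cyc)$mesh
    expect_length(validate_mesh(m, check_simple = FALSE), 0)
  }
  expect_length(m$cells, 19 + 12)
})
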