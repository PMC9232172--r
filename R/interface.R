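#' Load a simulation configuration from a JSON file
#'
#' Reads a JSON configuration, validates it against the known schema,
#' applies the published defaults (time step 1e-4, growth rate b = 10,
#' relative T1/T2 thresholds 0.01, tau_A = 5), and returns a
#' [sim_config()].  Unknown keys are rejected with their paths;
#' `tau_normal` accepts the string `"inf"`.
#'
#' @param path path to a JSON file.
#' @return a [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("lambda", "gamma", "lambda_normal", "lambda_abnormal",
             "gamma_normal", "gamma_abnormal", "mu", "dt",
             "theta_t1_rel", "theta_t2_rel", "new_edge_factor",
             "tau_abnormal", "tau_normal", "jitter_fraction",
             "growth_rate_b", "division_rule", "delta_A",
             "orientation_rule", "scenario", "N_theta", "tissue_size",
             "wall_rings", "t_end_tau", "sample_dt", "gs_threshold",
             "bailout_factor", "t_relax", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  num <- function(key, default) {
    v <- raw[[key]]
    if (is.null(v)) return(default)
    if (identical(v, "inf") || identical(v, "Inf")) return(Inf)
    if (!is.numeric(v)) stop("config key '", key, "' must be numeric")
    v
  }
  str <- function(key, default) {
    v <- raw[[key]]
    if (is.null(v)) default else as.character(v)
  }
  lambda <- num("lambda", 0.12)
  gamma <- num("gamma", 0.04)
  mech <- mech_params(
    lambda = lambda, gamma = gamma, mu = num("mu", 1),
    lambda_normal = num("lambda_normal", lambda),
    lambda_abnormal = num("lambda_abnormal", lambda),
    gamma_normal = num("gamma_normal", gamma),
    gamma_abnormal = num("gamma_abnormal", gamma),
    theta_t1_rel = num("theta_t1_rel", 0.01),
    theta_t2_rel = num("theta_t2_rel", 0.01),
    dt = num("dt", 1e-4),
    new_edge_factor = num("new_edge_factor", 1.5))
  cycle <- cycle_params(
    tau_abnormal = num("tau_abnormal", 5),
    tau_normal = num("tau_normal", Inf),
    jitter_fraction = num("jitter_fraction", 0.2),
    growth_rate_b = num("growth_rate_b", 10),
    division_rule = str("division_rule", "doubling"),
    delta_A = num("delta_A", 0.15),
    orientation_rule = str("orientation_rule", "random"))
  scn <- raw[["scenario"]]
  if (is.null(scn)) scn <- 1
  if (!identical(scn, "fixed_wall")) scn <- as.numeric(scn)
  N_theta <- num("N_theta", 10)
  sim_config(mech = mech, cycle = cycle, scenario = scn,
             N_theta = N_theta,
             tissue_size = num("tissue_size", 200),
             wall_rings = num("wall_rings", 5),
             t_end_tau = num("t_end_tau", 100),
             sample_dt = num("sample_dt", 0.1),
             gs_threshold = num("gs_threshold", 2 * N_theta),
             bailout_factor = num("bailout_factor", 2),
             t_relax = num("t_relax", 1),
             seed = num("seed", 1))
}

#' Deterministic test fixtures
#'
#' Small, programmatically built meshes used across the test-suite and the
#' analytic cross-checks:
#' \describe{
#'   \item{`hex1`}{a single regular hexagon of unit area.}
#'   \item{`rosette7`}{a central hexagon with its 6 neighbours.}
#'   \item{`patch19`}{two rings (19 hexagons).}
#'   \item{`ring_oracle`}{a 19-cell abnormal hexagonal disk embedded in
#'     rings of normal cells, the rotationally symmetric fixture for the
#'     force-balance oracle; `n_normal_rings` controls the annulus.}
#'   \item{`fixed_wall_disk`}{a disk with the rim immobilized.}
#'   \item{`pinwheel4`}{four cells around a short central edge, the minimal
#'     T1 test case.}
#' }
#'
#' @param name fixture name.
#' @param edge_length hexagon edge length (default: unit-area hexagons).
#' @param n_normal_rings annulus thickness for `ring_oracle`.
#' @param rings ring count for `fixed_wall_disk`.
#' @return a [tissue_mesh()].
#' @export
make_fixture <- function(name = c("hex1", "rosette7", "patch19",
                                  "ring_oracle", "fixed_wall_disk",
                                  "pinwheel4"),
                         edge_length = sqrt(2 / (3 * sqrt(3))),
                         n_normal_rings = 3, rings = 4) {
  name <- match.arg(name)
  switch(name,
    hex1 = build_hexagonal_tissue(1, edge_length),
    rosette7 = build_hexagonal_tissue(7, edge_length),
    patch19 = build_hexagonal_tissue(19, edge_length),
    ring_oracle = {
      n_tot_rings <- 2 + n_normal_rings
      n_cells <- 1 + 3 * n_tot_rings * (n_tot_rings + 1)
      m <- build_hexagonal_tissue(n_cells, edge_length)
      m <- relabel_central_cluster(m, 19L)
      m
    },
    fixed_wall_disk = build_hexagonal_tissue(1 + 3 * rings * (rings + 1),
                                             edge_length, "fixed_wall"),
    pinwheel4 = {
      # four quadrilaterals around a short vertical edge at the origin
      eps <- 0.05
      V <- rbind(c(0, -eps / 2), c(0, eps / 2),     # 1,2: central edge
                 c(-1, -1), c(1, -1),               # 3,4: bottom corners
                 c(1, 1), c(-1, 1),                 # 5,6: top corners
                 c(-1.8, 0), c(1.8, 0))             # 7,8: side apexes
      cells <- list(c(3, 1, 2, 6, 7),   # left (P)
                    c(4, 8, 5, 2, 1),   # right (Q)
                    c(2, 5, 6),         # top (R)
                    c(1, 3, 4))         # bottom (S)
      tissue_mesh(V, cells)
    })
}

#' @useDynLib vertexcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom graphics polygon
#' @importFrom stats runif
#' @keywords internal
"_PACKAGE"
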