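# Shared fixtures, built once per test run and memoised. All heavy objects
# are deliberately small: a 6-um round cell at 0.5-um spacing is enough to
# exercise every code path, and the acceptance checks that need the
# full-size reference geometry build it themselves.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

tiny_geometry <- function() make_round_cell(6, 2, 0.4)

tiny_grid <- function() memo("tiny_grid",
  voxelize(tiny_geometry(), c(0.5, 0.5, 0.25), half_cell = TRUE))

tiny_roi <- function() roi_spec(center = c(2.5, 0), radius = 0.75)

# 5 x 5 reduced library on the tiny geometry, 10-s recordings.
tiny_library <- function() memo("tiny_library",
  generate_library(
    grid_spec(F = seq(60, 140, by = 20), K_dep = seq(0.02, 0.10, by = 0.02),
              geometry_id = "tiny_round"),
    tiny_grid(), tiny_roi(), t_post = 10))

tiny_fitgrid <- function() fit_grid(end = 10)

# Reference round-cell geometry meshed at the working resolution used by the
# cross-geometry acceptance checks (both geometries meshed identically).
geoA_grid <- function() memo("geoA_grid",
  voxelize(make_round_cell(20, 3.5, 0.3), c(0.4, 0.4, 0.2), half_cell = TRUE))

geoA_roi <- function() roi_spec(center = c(10, 0), radius = 1)

# 3 x 3 library on the reference geometry, 5-s recordings.
geoA_library <- function() memo("geoA_library",
  generate_library(
    grid_spec(F = c(60, 100, 140), K_dep = c(0.02, 0.06, 0.10),
              geometry_id = "round_20"),
    geoA_grid(), geoA_roi(), t_post = 5))

geoA_fitgrid <- function() fit_grid(end = 5)

# Monte-Carlo volume oracle: classify uniform points in the bounding box.
mc_volume <- function(geom, n = 1e6, seed = 42) {
  set.seed(seed)
  bb <- geometry_bbox(geom)
  x <- runif(n, bb[1], bb[2])
  y <- runif(n, bb[3], bb[4])
  z <- runif(n, 0, bb[5])
  mean(is_inside(geom, x, y, z)) * (bb[2] - bb[1]) * (bb[4] - bb[3]) * bb[5]
}

# Analytic oracle: fraction of mass remaining in a disc of radius a after
# free 2D diffusion for time t (Green's-function quadrature).
disc_retention <- function(D, t, a = 1) {
  inner <- function(r) vapply(r, function(ri) stats::integrate(function(rho)
    (rho / (2 * D * t)) * exp(-(ri - rho)^2 / (4 * D * t)) *
      besselI(ri * rho / (2 * D * t), 0, expon.scaled = TRUE),
    0, a)$value, numeric(1))
  2 / a^2 * stats::integrate(function(r) r * inner(r), 0, a)$value
}
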