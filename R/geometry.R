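#' Analytic cell geometries for photoactivation simulations
#'
#' A `maap_geometry` describes a membrane-bounded cytoplasmic volume in which
#' the reaction-diffusion simulation runs. Three analytic shapes are provided:
#' a rounded, fully spread cell whose height falls smoothly from `H` at the
#' center to the lamellipodium thickness `t_e` at the rim
#' ([make_round_cell()]), an axon-like cylinder lying on the substrate
#' ([make_axon()]), and an amoeboid body with long narrow projections
#' ([make_projection_cell()]). Arbitrary shapes can be supplied as a voxel
#' occupancy mask ([make_mask_geometry()]).
#'
#' Coordinates: the cell center is at the origin, the substrate is the plane
#' `z = 0`, and the cytoplasm occupies `0 <= z <= h(x, y)`. All lengths are in
#' micrometres.
#'
#' The rounded-cell height profile is
#' `h(r) = t_e + (H - t_e) * (1 - (r/R)^2)^p` with dome exponent `p = 2` by
#' default: a smooth monotone dome honouring the prescribed center height and
#' edge thickness. Simulated ROI decay is insensitive to the detailed profile
#' (flat and domed profiles differ by well under one percentage point of ROI
#' signal), consistent with the observation that rounded geometries of rather
#' different height and spread give indistinguishable decay curves.
#'
#' @param R cell radius (um)
#' @param H height at the cell center (um)
#' @param t_e cytoplasm thickness at the edge of the lamellipodium (um)
#' @param dome_exponent exponent `p` of the height profile
#' @return an object of class `maap_geometry`
#' @seealso [voxelize()], [roi_spec()]
#' @examples
#' geo <- make_round_cell(20, 3.5, 0.3)
#' cell_height(geo, 0)   # 3.5
#' cell_height(geo, 20)  # 0.3
#' @export
make_round_cell <- function(R, H, t_e, dome_exponent = 2) {
  stopifnot(is.numeric(R), is.numeric(H), is.numeric(t_e))
  if (R <= 0) stop("cell radius R must be positive")
  if (t_e <= 0 || t_e > H) stop("edge thickness t_e must satisfy 0 < t_e <= H")
  structure(
    list(kind = "round_cell", R = R, H = H, t_e = t_e, p = dome_exponent),
    class = "maap_geometry"
  )
}

#' Height profile of a geometry above the substrate
#'
#' @param geom a `maap_geometry`
#' @param r radial distance from the cell center (um); vectorized
#' @return cytoplasm height (um), 0 outside the footprint
#' @export
cell_height <- function(geom, r) {
  switch(geom$kind,
    round_cell = {
      u <- pmax(1 - (r / geom$R)^2, 0)
      ifelse(r <= geom$R, geom$t_e + (geom$H - geom$t_e) * u^geom$p, 0)
    },
    stop("cell_height() is defined for round_cell geometries")
  )
}

#' Axon-like cylindrical geometry
#'
#' A cylinder of length `L` and radius `r_a` lying on the substrate with its
#' axis along `x`, spanning `x` in `[-L/2, L/2]` (axis at `z = r_a`). The
#' photoactivated region is the through-cytoplasm vertical cylinder of radius
#' `roi_radius`, by default centred at mid-length -- in the experiments the
#' activated spot sits at least 20 um from both the cell body and the tip,
#' which mid-length reproduces for the 40-um default.
#'
#' @param L axon length (um)
#' @param r_a axon radius (um)
#' @param roi_radius radius of the photoactivated spot (um)
#' @param roi_center position of the spot centre along the axis (um,
#'   default 0 = mid-length)
#' @return a list with elements `geometry` (a `maap_geometry`) and
#'   `roi` (a `maap_roi`)
#' @export
make_axon <- function(L, r_a, roi_radius, roi_center = 0) {
  if (L <= 0 || r_a <= 0 || roi_radius <= 0) stop("axon dimensions must be positive")
  if (roi_radius > r_a)
    stop("ROI radius ", roi_radius, " exceeds the axon radius ", r_a,
         ": ROI outside cylinder")
  if (abs(roi_center) + 2 * roi_radius > L / 2)
    stop("ROI must lie at least 2 ROI radii from either end of the axon")
  geom <- structure(
    list(kind = "axon", L = L, r_a = r_a),
    class = "maap_geometry"
  )
  list(geometry = geom, roi = roi_spec(center = c(roi_center, 0), radius = roi_radius))
}

#' Amoeboid cell with long narrow projections
#'
#' A procedural stand-in for an amoeboid cell: a flattened round body plus
#' `n_projections` straight projections of radius `proj_radius` radiating from
#' it at equally spaced angles. Each projection is a horizontal cylinder with
#' its axis at height `proj_radius`, starting inside the body (at
#' `attach_radius`, default 3/4 of the body radius) so that body and
#' projection volumes overlap and the domain is connected.
#'
#' @param body_radius radius of the central body (um)
#' @param n_projections number of projections (0 reduces to the round body)
#' @param proj_length projection length measured from the attachment
#'   point (um)
#' @param proj_radius projection radius (um)
#' @param H,t_e body height profile parameters, as in [make_round_cell()]
#' @param attach_radius radial distance at which projections attach (um)
#' @return a `maap_geometry`
#' @export
make_projection_cell <- function(body_radius, n_projections, proj_length = NULL,
                                 proj_radius = NULL, H = 3.5, t_e = 0.3,
                                 attach_radius = 0.75 * body_radius) {
  if (body_radius <= 0) stop("body_radius must be positive")
  n_projections <- as.integer(n_projections)
  if (n_projections < 0) stop("n_projections must be >= 0")
  if (n_projections > 0) {
    if (is.null(proj_length) || is.null(proj_radius) ||
        proj_length <= 0 || proj_radius <= 0)
      stop("proj_length and proj_radius must be positive when n_projections > 0")
    if (attach_radius >= body_radius)
      stop("projections attach outside the body: disconnected domain")
  }
  structure(
    list(kind = "projection_cell", R = body_radius, H = max(H, t_e),
         t_e = min(t_e, H), p = 2, n_proj = n_projections,
         proj_length = proj_length, proj_radius = proj_radius,
         attach_radius = attach_radius,
         proj_angles = if (n_projections > 0) 2 * pi * (seq_len(n_projections) - 1) / n_projections),
    class = "maap_geometry"
  )
}

#' Geometry from a voxel occupancy mask
#'
#' Wraps a user-supplied 3D logical array (TRUE = cytoplasm) so that imported
#' shapes, e.g. segmented from microscopy, can be used in place of the
#' analytic geometries. The mask is used as-is by [voxelize()].
#'
#' @param mask 3D logical array of voxel occupancy
#' @param spacing voxel spacing, one value or `c(dx, dy, dz)` (um)
#' @param origin coordinates of the corner of voxel `[1,1,1]` (um)
#' @return a `maap_geometry`
#' @export
make_mask_geometry <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!any(mask)) stop("mask has no interior voxels")
  structure(
    list(kind = "mask", mask = array(as.logical(mask), dim(mask)),
         spacing = spacing, origin = origin),
    class = "maap_geometry"
  )
}

# Vectorized point-membership predicate: is (x, y, z) inside the cytoplasm?
# Used for voxel-center classification and by the Monte-Carlo volume oracle.
#' Point membership of the cytoplasm
#' @param geom a `maap_geometry`
#' @param x,y,z point coordinates (um); vectors are recycled to common length
#' @return logical vector
#' @export
is_inside <- function(geom, x, y, z) {
  nmax <- max(length(x), length(y), length(z))
  x <- rep_len(x, nmax); y <- rep_len(y, nmax); z <- rep_len(z, nmax)
  switch(geom$kind,
    round_cell = {
      r <- sqrt(x^2 + y^2)
      z >= 0 & r <= geom$R & z <= cell_height(geom, r)
    },
    axon = {
      abs(x) <= geom$L / 2 & z >= 0 & (y^2 + (z - geom$r_a)^2) <= geom$r_a^2
    },
    projection_cell = {
      r <- sqrt(x^2 + y^2)
      u <- pmax(1 - (r / geom$R)^2, 0)
      inside <- z >= 0 & r <= geom$R &
        z <= geom$t_e + (geom$H - geom$t_e) * u^geom$p
      if (geom$n_proj > 0) {
        for (th in geom$proj_angles) {
          s <- x * cos(th) + y * sin(th)        # along-projection coordinate
          q <- -x * sin(th) + y * cos(th)       # transverse
          inproj <- s >= geom$attach_radius &
            s <= geom$attach_radius + geom$proj_length &
            (q^2 + (z - geom$proj_radius)^2) <= geom$proj_radius^2 & z >= 0
          inside <- inside | inproj
        }
      }
      inside
    },
    mask = {
      i <- floor((x - geom$origin[1]) / geom$spacing[1]) + 1
      j <- floor((y - geom$origin[2]) / geom$spacing[2]) + 1
      k <- floor((z - geom$origin[3]) / geom$spacing[3]) + 1
      d <- dim(geom$mask)
      ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
      out <- logical(length(x))
      out[ok] <- geom$mask[cbind(i[ok], j[ok], k[ok])]
      out
    }
  )
}

# Bounding box of the geometry footprint, c(xmin, xmax, ymin, ymax, zmax).
#' @noRd
geometry_bbox <- function(geom) {
  switch(geom$kind,
    round_cell = c(-geom$R, geom$R, -geom$R, geom$R, geom$H),
    axon = c(-geom$L / 2, geom$L / 2, -geom$r_a, geom$r_a, 2 * geom$r_a),
    projection_cell = {
      ext <- if (geom$n_proj > 0) geom$attach_radius + geom$proj_length else geom$R
      ext <- max(ext, geom$R)
      zmax <- max(geom$H, if (geom$n_proj > 0) 2 * geom$proj_radius else 0)
      c(-ext, ext, -ext, ext, zmax)
    },
    mask = {
      d <- dim(geom$mask)
      c(geom$origin[1], geom$origin[1] + d[1] * geom$spacing[1],
        geom$origin[2], geom$origin[2] + d[2] * geom$spacing[2],
        geom$origin[3] + d[3] * geom$spacing[3])
    }
  )
}

# Smallest geometric feature the voxel spacing has to resolve.
#' @noRd
min_feature <- function(geom) {
  switch(geom$kind,
    round_cell = geom$t_e,
    axon = geom$r_a,
    projection_cell = min(geom$t_e, geom$proj_radius %||% geom$t_e),
    mask = Inf
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelize a geometry onto a regular rectangular grid
#'
#' Classifies voxel centers with [is_inside()] and returns the interior mask
#' together with the book-keeping the solver needs. With `half_cell = TRUE`
#' only the half-space `y >= 0` is meshed; because the boundary condition is
#' zero-flux everywhere, the mirror plane `y = 0` (which contains both the
#' cell center and the default ROI center) is automatically a symmetry plane
#' and the half-cell solution equals the full-cell solution restricted to
#' `y >= 0`.
#'
#' @param geom a `maap_geometry`
#' @param spacing voxel spacing, one value or `c(dx, dy, dz)` (um). Must be
#'   finer than the smallest geometric feature (edge thickness, axon radius).
#' @param half_cell mesh only `y >= 0` (round and projection cells)
#' @param check_connected verify that the interior is a single connected
#'   component and error otherwise
#' @return an object of class `maap_grid` with fields `dims`, `spacing`,
#'   `axes` (voxel-center coordinates), `mask` (3D logical), `n` (number of
#'   interior voxels), `half_cell`, `geometry`
#' @export
voxelize <- function(geom, spacing, half_cell = FALSE, check_connected = FALSE) {
  stopifnot(inherits(geom, "maap_geometry"))
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  feat <- min_feature(geom)
  if (spacing[3] >= feat || max(spacing[1:2]) > 2 * feat)
    stop(sprintf(
      "spacing (%.3g, %.3g, %.3g) um too coarse to resolve the smallest geometric feature (%.3g um)",
      spacing[1], spacing[2], spacing[3], feat))

  if (geom$kind == "mask") {
    mask <- geom$mask
    spacing <- geom$spacing
    axes <- lapply(1:3, function(a)
      geom$origin[a] + (seq_len(dim(mask)[a]) - 0.5) * spacing[a])
  } else {
    bb <- geometry_bbox(geom)
    if (half_cell && geom$kind == "axon") half_cell <- FALSE  # nothing to gain
    ylo <- if (half_cell) 0 else bb[3]
    # voxel centers placed so that x = 0, y = 0 and z = 0 are voxel faces:
    # the symmetry plane then coincides with a reflecting (zero-flux) face
    xs <- grid_axis(bb[1], bb[2], spacing[1])
    ys <- grid_axis(ylo, bb[4], spacing[2])
    zs <- seq(spacing[3] / 2, bb[5], by = spacing[3])
    pts <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
    mask <- array(is_inside(geom, pts$x, pts$y, pts$z),
                  c(length(xs), length(ys), length(zs)))
    axes <- list(xs, ys, zs)
  }
  n <- sum(mask)
  if (n == 0) stop("voxelization produced no interior voxels")
  grid <- structure(
    list(dims = dim(mask), spacing = spacing, axes = axes, mask = mask,
         n = n, half_cell = isTRUE(half_cell), geometry = geom,
         cache = new.env(parent = emptyenv())),
    class = "maap_grid"
  )
  if (check_connected && !grid_is_connected(grid))
    stop("voxelized interior is not a single connected component")
  grid
}

# Axis of voxel centers covering [lo, hi] with faces on multiples of d.
#' @noRd
grid_axis <- function(lo, hi, d) {
  i0 <- floor(lo / d)
  i1 <- ceiling(hi / d)
  (seq(i0, i1 - 1) + 0.5) * d
}

#' Total interior volume of a voxelized geometry
#'
#' @param grid a `maap_grid`
#' @param full for half-cell grids, double the meshed volume to report the
#'   whole-cell value
#' @return volume in um^3
#' @export
grid_volume <- function(grid, full = TRUE) {
  v <- grid$n * prod(grid$spacing)
  if (full && grid$half_cell) 2 * v else v
}

# Connectivity check by vectorized label flooding over the 6-neighbourhood.
#' @noRd
grid_is_connected <- function(grid) {
  m <- grid$mask
  lab <- array(FALSE, dim(m))
  seed <- which(m)[1]
  lab[seed] <- TRUE
  repeat {
    grown <- lab
    grown[-1, , ] <- grown[-1, , ] | lab[-dim(m)[1], , ]
    grown[-dim(m)[1], , ] <- grown[-dim(m)[1], , ] | lab[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | lab[, -dim(m)[2], ]
    grown[, -dim(m)[2], ] <- grown[, -dim(m)[2], ] | lab[, -1, ]
    grown[, , -1] <- grown[, , -1] | lab[, , -dim(m)[3]]
    grown[, , -dim(m)[3]] <- grown[, , -dim(m)[3]] | lab[, , -1]
    grown <- grown & m
    if (identical(grown, lab)) break
    lab <- grown
  }
  sum(lab) == sum(m)
}

#' Photoactivated region of interest
#'
#' The ROI is a vertical cylinder through the whole cytoplasm: a circle of
#' radius `radius` in the substrate plane, centred at `center`, extruded in
#' `z`. Both photoactivation and the readout of the mean photoactivated-actin
#' concentration use this region.
#'
#' @param center `c(x, y)` offset of the ROI centre from the cell
#'   center (um)
#' @param radius ROI radius (um); 1 um (a 2-um diameter spot) for rounded
#'   cells, 0.5 um for axons
#' @return an object of class `maap_roi`
#' @export
roi_spec <- function(center = c(10, 0), radius = 1) {
  if (radius <= 0) stop("ROI radius must be positive")
  structure(list(center = as.numeric(center[1:2]), radius = radius),
            class = "maap_roi")
}

#' Default ROI for a geometry
#'
#' Rounded cells: a 2-um diameter spot centred 10 um from the cell center
#' (or at half the radius for small cells). Projection cells: a 1-um diameter
#' spot at mid-length of the first projection. Axons carry their ROI from
#' [make_axon()].
#'
#' @param geom a `maap_geometry`
#' @return a `maap_roi`
#' @export
default_roi <- function(geom) {
  switch(geom$kind,
    round_cell = {
      off <- min(10, geom$R / 2)
      roi_spec(center = c(off, 0), radius = min(1, geom$R / 4))
    },
    axon = roi_spec(center = c(0, 0), radius = geom$r_a),
    projection_cell = {
      if (geom$n_proj > 0)
        roi_spec(center = c(geom$attach_radius + geom$proj_length / 2, 0),
                 radius = min(0.5, geom$proj_radius))
      else roi_spec(center = c(geom$R / 2, 0), radius = min(1, geom$R / 4))
    },
    stop("no default ROI for geometry kind ", geom$kind)
  )
}

# Interior-voxel indices belonging to the ROI cylinder, with basic validation.
#' @noRd
roi_interior_index <- function(grid, roi) {
  xs <- grid$axes[[1]]; ys <- grid$axes[[2]]
  inroi2d <- outer(xs, ys, function(x, y)
    (x - roi$center[1])^2 + (y - roi$center[2])^2 < roi$radius^2)
  if (!any(inroi2d)) stop("ROI contains no voxels at this grid spacing")
  roi3d <- array(inroi2d, grid$dims) & grid$mask
  if (!any(roi3d)) stop("ROI cylinder does not intersect the cytoplasm")
  which(roi3d[grid$mask])
}

# Validate that the ROI footprint lies inside the geometry footprint: every
# point of the ROI perimeter must meet cytoplasm at some height (domains like
# axons and projections taper towards the substrate, so a single z probe
# would reject valid ROIs).
#' @noRd
check_roi_inside <- function(geom, roi, grid = NULL) {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  px <- roi$center[1] + roi$radius * cos(th)
  py <- roi$center[2] + roi$radius * sin(th)
  zmax <- geometry_bbox(geom)[5]
  zs <- seq(zmax / 64, zmax, length.out = 32)
  # include the cylinder-axis heights where tapering domains are widest
  zs <- c(zs, switch(geom$kind, axon = geom$r_a,
                     projection_cell = geom$proj_radius, NULL))
  ok <- rep(FALSE, length(px))
  for (z in zs) ok <- ok | is_inside(geom, px, py, z)
  if (!all(ok))
    stop("ROI cylinder is not entirely inside the cytoplasm")
  invisible(TRUE)
}

#' @export
print.maap_geometry <- function(x, ...) {
  cat("<maap_geometry>", x$kind, "\n")
  switch(x$kind,
    round_cell = cat(sprintf("  R = %g um, H = %g um, t_e = %g um (dome exponent %g)\n",
                             x$R, x$H, x$t_e, x$p)),
    axon = cat(sprintf("  L = %g um, r_a = %g um\n", x$L, x$r_a)),
    projection_cell = cat(sprintf(
      "  body R = %g um (H = %g, t_e = %g), %d projection(s) length %g um radius %g um\n",
      x$R, x$H, x$t_e, x$n_proj, x$proj_length %||% NA, x$proj_radius %||% NA)),
    mask = cat(sprintf("  %s voxels at (%g, %g, %g) um\n",
                       paste(dim(x$mask), collapse = " x "),
                       x$spacing[1], x$spacing[2], x$spacing[3]))
  )
  invisible(x)
}

#' @export
print.maap_grid <- function(x, ...) {
  cat(sprintf("<maap_grid> %s voxels at (%g, %g, %g) um%s: %d interior, volume %.1f um^3\n",
              paste(x$dims, collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              if (x$half_cell) " (half cell)" else "",
              x$n, grid_volume(x, full = FALSE)))
  invisible(x)
}

#' @export
print.maap_roi <- function(x, ...) {
  cat(sprintf("<maap_roi> cylinder r = %g um at (%g, %g) um\n",
              x$radius, x$center[1], x$center[2]))
  invisible(x)
}
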