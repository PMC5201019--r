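# Run configuration: defaults, YAML loading, validation.

#' Default run configuration
#'
#' All defaults are the reference protocol values: D = 3 um^2/s, 200 uM
#' total actin, a 65-ms pulse, normalization at 0.035 s, 25 s of recorded
#' decay, the 20/3.5/0.3-um round-cell geometry with a 2-um ROI 10 um from
#' the center, the default 19 x 20 library grid, and the 0.05 s / 0.2 s fit
#' grid split at 3 s.
#'
#' @return a nested list of class `maap_config`
#' @export
default_config <- function() {
  structure(list(
    geometry = list(kind = "round_cell", R = 20, H = 3.5, t_e = 0.3,
                    dome_exponent = 2,
                    spacing = c(0.25, 0.25, 0.15), half_cell = TRUE),
    roi = list(center = c(10, 0), radius = 1),
    simulation = list(D = 3, A_tot = 200, t_pulse = 0.065,
                      laser_rate = log(1e3) / 0.065,
                      t_post = 25, t_norm = 0.035, dt_pulse = 1e-3),
    library = list(F_min = 10, F_max = 190, F_step = 10,
                   K_min = 0.01, K_max = 0.20, K_step = 0.01),
    fit = list(breakpoint = 3, fine = 0.05, coarse = 0.2, end = 25, k = 9),
    seed = 1L, verbosity = "info"
  ), class = "maap_config")
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) file and merges it over [default_config()]:
#' every omitted key keeps its default, every supplied key overrides it.
#' Unknown keys are an error in strict mode, so typos cannot silently
#' deactivate an override. Overridden keys are recorded under
#' `attr(, "overridden")` for provenance.
#'
#' @param path config file; `NULL` or a missing/empty file gives the pure
#'   defaults
#' @param strict error on keys that are not part of the schema
#' @return a `maap_config`
#' @export
load_config <- function(path = NULL, strict = TRUE) {
  base <- default_config()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(base)
  if (!is.list(user)) stop("config must be a mapping of sections")
  overridden <- character(0)
  merged <- unclass(base)
  for (sec in names(user)) {
    if (!sec %in% names(merged)) {
      if (strict) stop("unknown config section '", sec, "'")
      next
    }
    if (is.list(merged[[sec]])) {
      if (!is.list(user[[sec]]))
        stop("config section '", sec, "' must be a mapping")
      for (key in names(user[[sec]])) {
        if (!key %in% names(merged[[sec]]) && strict &&
            !(sec == "geometry"))  # geometry keys depend on 'kind'
          stop("unknown config key '", sec, ".", key, "'")
        merged[[sec]][[key]] <- user[[sec]][[key]]
        overridden <- c(overridden, paste0(sec, ".", key))
      }
    } else {
      merged[[sec]] <- user[[sec]]
      overridden <- c(overridden, sec)
    }
  }
  cfg <- structure(merged, class = "maap_config")
  validate_config(cfg)
  attr(cfg, "overridden") <- overridden
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  s <- cfg$simulation
  num_pos <- function(x, what) {
    if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x)) || any(x <= 0))
      stop("config: ", what, " must be positive and numeric")
  }
  num_pos(s$A_tot, "simulation.A_tot")
  num_pos(s$t_pulse, "simulation.t_pulse")
  num_pos(s$t_post, "simulation.t_post")
  if (s$D < 0) stop("config: simulation.D must be >= 0")
  l <- cfg$library
  num_pos(l$F_step, "library.F_step")
  if (l$K_min < 0) stop("config: library.K_min must be >= 0")
  if (l$F_max >= s$A_tot) stop("config: library F values must stay below A_tot")
  if (l$F_min <= 0) stop("config: library.F_min must be positive")
  invisible(cfg)
}

#' Build package objects from a configuration
#'
#' @param cfg a `maap_config`
#' @return list with `geometry`, `grid`, `roi`, `spec` (library grid) and
#'   `fitgrid`
#' @export
config_objects <- function(cfg) {
  g <- cfg$geometry
  geom <- switch(g$kind,
    round_cell = make_round_cell(g$R, g$H, g$t_e,
                                 dome_exponent = g$dome_exponent %||% 2),
    axon = make_axon(g$L, g$r_a, g$roi_radius %||% g$r_a)$geometry,
    projection_cell = make_projection_cell(g$body_radius, g$n_projections,
                                           g$proj_length, g$proj_radius),
    stop("unsupported geometry kind '", g$kind, "' in config"))
  grid <- voxelize(geom, g$spacing, half_cell = isTRUE(g$half_cell))
  roi <- roi_spec(center = cfg$roi$center, radius = cfg$roi$radius)
  l <- cfg$library
  spec <- grid_spec(A_tot = cfg$simulation$A_tot,
                    F = seq(l$F_min, l$F_max, by = l$F_step),
                    K_dep = seq(max(l$K_min, l$K_step), l$K_max, by = l$K_step),
                    D = cfg$simulation$D, geometry_id = g$kind)
  f <- cfg$fit
  list(geometry = geom, grid = grid, roi = roi, spec = spec,
       fitgrid = fit_grid(f$breakpoint, f$fine, f$coarse, f$end,
                          t_norm = cfg$simulation$t_norm))
}
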