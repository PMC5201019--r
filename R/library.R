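# The simulation library: one decay curve per cell of the
# (F-actin concentration x depolymerization rate) grid.

#' Parameter grid for a simulation library
#'
#' The default grid sweeps the F-actin concentration from 10 to 190 uM in
#' 10-uM steps (G:F ratios 19:1 down to 1:19 at 200 uM total actin) and the
#' depolymerization rate from 0.01 to 0.20 1/s in 0.01 1/s steps -- 19 x 20 =
#' 380 scenarios. A `K_dep = 0` row can be added explicitly via the `K_dep`
#' argument if a no-turnover reference is wanted.
#'
#' @param A_tot total actin concentration (uM)
#' @param F F-actin concentrations (uM); all must be below `A_tot`
#' @param K_dep depolymerization rates (1/s)
#' @param D G-actin diffusion coefficient (um^2/s)
#' @param geometry_id free-text identifier of the geometry the library is
#'   simulated in
#' @return an object of class `maap_gridspec`
#' @export
grid_spec <- function(A_tot = 200, F = seq(10, 190, by = 10),
                      K_dep = seq(0.01, 0.20, by = 0.01), D = 3,
                      geometry_id = "round_cell") {
  F <- as.numeric(F); K_dep <- as.numeric(K_dep); A_tot <- as.numeric(A_tot)
  if (any(F <= 0) || any(F >= A_tot)) stop("all F must lie in (0, A_tot)")
  if (any(K_dep < 0)) stop("K_dep must be >= 0")
  if (anyDuplicated(F) || anyDuplicated(K_dep))
    stop("duplicated grid values")
  structure(list(A_tot = A_tot, F = sort(F), K_dep = sort(K_dep), D = D,
                 geometry_id = geometry_id),
            class = "maap_gridspec")
}

#' @export
print.maap_gridspec <- function(x, ...) {
  cat(sprintf(
    "<maap_gridspec> %d F values x %d K_dep values = %d scenarios (A_tot = %g uM, D = %g um^2/s, geometry '%s')\n",
    length(x$F), length(x$K_dep), length(x$F) * length(x$K_dep),
    x$A_tot, x$D, x$geometry_id))
  invisible(x)
}

#' Generate the simulation library
#'
#' Runs one forward simulation per grid cell and stores the normalized decay
#' curve, interpolated onto a common output schedule (video rate to 3 s, then
#' 10 frames/s). Cells are computed independently and deterministically, so an
#' interrupted sweep can be resumed by passing the partial library as
#' `existing`: cells already present are kept, missing ones are simulated.
#' Diffusion-solve factorizations are shared across all cells.
#'
#' @param spec a [grid_spec()]
#' @param grid a [voxelize()]d geometry
#' @param roi a [roi_spec()]; default [default_roi()]
#' @param t_post,t_norm protocol settings passed to [sim_params()]
#' @param existing a partial `maap_library` to resume from
#' @param progress print one line per simulated cell
#' @return an object of class `maap_library`: `spec`, `times`, `curves`
#'   (matrix, one column per cell), `F`, `K_dep` (per column), `meta`
#' @export
generate_library <- function(spec, grid, roi = NULL, t_post = 25,
                             t_norm = 0.035, existing = NULL,
                             progress = FALSE) {
  stopifnot(inherits(spec, "maap_gridspec"), inherits(grid, "maap_grid"))
  if (is.null(roi)) roi <- default_roi(grid$geometry)
  cells <- expand.grid(F = spec$F, K_dep = spec$K_dep,
                       KEEP.OUT.ATTRS = FALSE)
  tt <- output_schedule(t_norm, t_post)
  curves <- matrix(NA_real_, length(tt), nrow(cells))
  colnames(curves) <- sprintf("F%g_K%g", cells$F, cells$K_dep)
  if (!is.null(existing)) {
    stopifnot(inherits(existing, "maap_library"))
    if (!isTRUE(all.equal(existing$times, tt)))
      stop("existing library uses a different output schedule")
    hit <- match(colnames(existing$curves), colnames(curves))
    curves[, hit[!is.na(hit)]] <- existing$curves[, !is.na(hit)]
  }
  for (j in seq_len(nrow(cells))) {
    if (!anyNA(curves[, j])) next
    p <- sim_params(D = spec$D, A_tot = spec$A_tot, F0 = cells$F[j],
                    K_dep = cells$K_dep[j], t_post = t_post, t_norm = t_norm)
    sim <- tryCatch(
      simulate_photoactivation(p, grid, roi),
      error = function(e) stop(sprintf(
        "library cell (F = %g uM, K_dep = %g /s) failed: %s",
        cells$F[j], cells$K_dep[j], conditionMessage(e)), call. = FALSE))
    cur <- normalize_curve(sim, t_norm = t_norm)
    curves[, j] <- curve_value(cur, tt)
    if (progress)
      message(sprintf("[%d/%d] F = %g uM, K_dep = %g /s",
                      j, nrow(cells), cells$F[j], cells$K_dep[j]))
  }
  structure(
    list(spec = spec, times = tt, curves = curves,
         F = cells$F, K_dep = cells$K_dep,
         meta = list(
           t_norm = t_norm, t_post = t_post,
           roi = unclass(roi), half_cell = grid$half_cell,
           grid_dims = grid$dims, grid_spacing = grid$spacing,
           geometry = grid$geometry[setdiff(names(grid$geometry), "mask")],
           created = format(Sys.time(), tz = "UTC", usetz = TRUE),
           version = as.character(utils::packageVersion("maap")))),
    class = "maap_library"
  )
}

#' Number of scenarios in a library or grid spec
#' @param x a `maap_gridspec` or `maap_library`
#' @return integer count
#' @export
n_scenarios <- function(x) {
  if (inherits(x, "maap_library")) ncol(x$curves)
  else length(x$F) * length(x$K_dep)
}

#' Extract one library curve
#' @param library a `maap_library`
#' @param F,K_dep cell coordinates (must match a grid cell exactly)
#' @return a `maap_curve`
#' @export
library_curve <- function(library, F, K_dep) {
  j <- which(library$F == F & library$K_dep == K_dep)
  if (length(j) != 1) stop("no library cell at (F = ", F, ", K_dep = ", K_dep, ")")
  new_curve(library$times, library$curves[, j], library$meta$t_norm,
            meta = list(F = F, K_dep = K_dep,
                        ratio = (library$spec$A_tot - F) / F))
}

#' @export
print.maap_library <- function(x, ...) {
  cat(sprintf(
    "<maap_library> %d curves (%d F x %d K_dep), %d time points to %g s, geometry '%s'\n",
    ncol(x$curves), length(x$spec$F), length(x$spec$K_dep),
    nrow(x$curves), max(x$times), x$spec$geometry_id))
  if (anyNA(x$curves))
    cat(sprintf("  partial: %d cell(s) not yet simulated\n",
                sum(apply(x$curves, 2, anyNA))))
  invisible(x)
}

#' Save / load a simulation library
#'
#' The on-disk format is a single plain-text file: a header of '#'-prefixed
#' lines carrying the grid spec and provenance as JSON, followed by a
#' comma-separated table (first column time, one column per grid cell).
#' Values are written with 17 significant digits, so a load/save round trip
#' reproduces every double bit-for-bit.
#'
#' @param library a `maap_library`
#' @param path file path (conventionally `.maaplib.csv`)
#' @return `save_library` returns `path` invisibly; `load_library` returns
#'   the `maap_library`
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "maap_library"))
  hdr <- jsonlite::toJSON(
    list(format = "maap_library", format_version = 1L,
         spec = unclass(library$spec), meta = library$meta),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  tab <- cbind(time = library$times, library$curves)
  writeLines(paste0("time,", paste(colnames(library$curves), collapse = ",")),
             con)
  body <- apply(tab, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# "))
    stop("not a maap library store: missing metadata header")
  hdr <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  if (!identical(hdr$format, "maap_library"))
    stop("not a maap library store: wrong format tag")
  tab <- utils::read.csv(text = lines[-1], check.names = FALSE)
  spec <- grid_spec(A_tot = hdr$spec$A_tot, F = hdr$spec$F,
                    K_dep = hdr$spec$K_dep, D = hdr$spec$D,
                    geometry_id = hdr$spec$geometry_id)
  curves <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(curves) <- list(NULL, colnames(curves))
  cells <- expand.grid(F = spec$F, K_dep = spec$K_dep,
                       KEEP.OUT.ATTRS = FALSE)
  want <- sprintf("F%g_K%g", cells$F, cells$K_dep)
  if (!identical(colnames(curves), want))
    stop("library store is inconsistent with its grid spec")
  structure(
    list(spec = spec, times = tab$time, curves = curves,
         F = cells$F, K_dep = cells$K_dep, meta = hdr$meta),
    class = "maap_library"
  )
}
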