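# Sensitivity of the ROI signal to small parameter changes, computed by
# finite differences across the simulation library.

#' Differential curves between adjacent library cells
#'
#' For each pair of curves adjacent along `axis` (with the other parameter
#' held at `fixed_value`), the absolute difference of the normalized ROI
#' intensity is taken at every time point. On the default grid, adjacent F
#' cells differ by 10 uM and adjacent K_dep cells by 0.01 1/s. Where and when
#' these differential curves peak shows which part of the decay carries
#' information about which parameter: F-differences peak seconds after the
#' pulse, K_dep-differences vanish at early times (pure diffusion) and peak
#' late for slow turnover.
#'
#' @param library a `maap_library`
#' @param axis `"F"` or `"K_dep"`: the parameter that varies within a pair
#' @param fixed_value value of the other parameter selecting the curve
#'   family
#' @return data.frame in long format: `pair` (label `lo->hi`), `lo`, `hi`,
#'   `time`, `diff`
#' @export
differential_curves <- function(library, axis = c("F", "K_dep"),
                                fixed_value) {
  axis <- match.arg(axis)
  stopifnot(inherits(library, "maap_library"))
  other <- if (axis == "F") "K_dep" else "F"
  sel <- abs(library[[other]] - fixed_value) < 1e-12
  if (!any(sel)) stop("no library cells with ", other, " = ", fixed_value)
  av <- library[[axis]][sel]
  if (length(av) < 2) stop("need at least 2 values along axis ", axis)
  o <- order(av)
  cur <- library$curves[, sel, drop = FALSE][, o, drop = FALSE]
  av <- av[o]
  do.call(rbind, lapply(seq_len(length(av) - 1), function(i) {
    data.frame(pair = sprintf("%g->%g", av[i], av[i + 1]),
               lo = av[i], hi = av[i + 1], time = library$times,
               diff = abs(cur[, i + 1] - cur[, i]))
  }))
}

#' Time-averaged sensitivity map
#'
#' Each differential curve is reduced to a single scalar: its unweighted
#' mean over the fit-grid points (the times that actually enter the RMSD
#' fit). The full map over adjacent pairs along `axis` and all values of the
#' other parameter summarizes where in parameter space the decay curves are
#' most informative: sensitivity to K_dep is highest at high F-actin with
#' slow turnover, while F-sensitivity is highest for slow rates and high
#' G:F.
#'
#' @param library a `maap_library`
#' @param axis `"F"` or `"K_dep"`: the parameter being perturbed
#' @param grid a [fit_grid()] defining the averaging time points (clipped to
#'   the library support)
#' @return an object of class `maap_sensitivity`: `axis`, `map` (matrix,
#'   one row per adjacent pair, one column per value of the other
#'   parameter), `pairs`, `other_values`
#' @export
time_averaged_sensitivity <- function(library, axis = c("F", "K_dep"),
                                      grid = fit_grid()) {
  axis <- match.arg(axis)
  stopifnot(inherits(library, "maap_library"))
  other <- if (axis == "F") "K_dep" else "F"
  tt <- as.numeric(grid)
  tt <- tt[tt <= max(library$times) + 1e-9]
  axv <- sort(unique(library[[axis]]))
  otv <- sort(unique(library[[other]]))
  if (length(axv) < 2) stop("need at least 2 values along axis ", axis)
  map <- matrix(NA_real_, length(axv) - 1, length(otv),
                dimnames = list(sprintf("%g->%g", axv[-length(axv)], axv[-1]),
                                sprintf("%s=%g", other, otv)))
  for (j in seq_along(otv)) {
    sel <- abs(library[[other]] - otv[j]) < 1e-12
    o <- order(library[[axis]][sel])
    cur <- library$curves[, sel, drop = FALSE][, o, drop = FALSE]
    rs <- apply(cur, 2, function(v) stats::approx(library$times, v, tt)$y)
    map[, j] <- colMeans(abs(rs[, -1, drop = FALSE] -
                             rs[, -ncol(rs), drop = FALSE]))
  }
  structure(list(axis = axis, map = map,
                 pairs = rownames(map), other_values = otv),
            class = "maap_sensitivity")
}

#' @export
print.maap_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<maap_sensitivity> axis %s: %d adjacent pairs x %d values; max %.4g at [%s, %s]\n",
    x$axis, nrow(x$map), ncol(x$map), max(x$map),
    rownames(x$map)[which(x$map == max(x$map), arr.ind = TRUE)[1, 1]],
    colnames(x$map)[which(x$map == max(x$map), arr.ind = TRUE)[1, 2]]))
  invisible(x)
}
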