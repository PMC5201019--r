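# Matching experimental decay curves against the simulation library.

#' Non-uniform time grid for curve comparison
#'
#' RMSDs are evaluated on a grid that is dense where the curve is dominated
#' by fast G-actin diffusion and sparse afterwards: `fine`-spaced points up
#' to `breakpoint`, then `coarse`-spaced points to `end`. The grid starts at
#' the normalization time.
#'
#' @param breakpoint boundary between the fine and coarse segments (s)
#' @param fine,coarse step sizes of the two segments (s)
#' @param end last grid point (s)
#' @param t_norm first grid point, the normalization time (s)
#' @return an object of class `maap_fitgrid` (numeric time vector)
#' @export
fit_grid <- function(breakpoint = 3, fine = 0.05, coarse = 0.2, end = 25,
                     t_norm = 0.035) {
  if (fine >= coarse) stop("fine step must be smaller than coarse step")
  if (!(t_norm < breakpoint && breakpoint < end))
    stop("need t_norm < breakpoint < end")
  tt <- c(t_norm, seq(ceiling(t_norm / fine) * fine, breakpoint, by = fine),
          seq(breakpoint + coarse, end, by = coarse))
  tt <- unique(round(tt, 9))
  structure(tt, class = c("maap_fitgrid", "numeric"),
            breakpoint = breakpoint, fine = fine, coarse = coarse)
}

#' Resample a decay curve onto a fit grid
#'
#' Linear interpolation onto the grid points; the grid is truncated to the
#' curve's support (and the truncation recorded). Curves that do not span the
#' fine segment are rejected.
#'
#' @param curve a `maap_curve`
#' @param grid a [fit_grid()]
#' @return a `maap_curve` sampled exactly on (a prefix of) the grid, with
#'   `meta$truncated_at` set when the grid was cut short
#' @export
resample_to_fit_grid <- function(curve, grid = fit_grid()) {
  stopifnot(inherits(curve, "maap_curve"))
  tmax <- max(curve$time)
  if (tmax < attr(grid, "breakpoint"))
    stop(sprintf(
      "curve ends at %.3g s, before the end of the fine fit segment (%g s)",
      tmax, attr(grid, "breakpoint")))
  tt <- as.numeric(grid)
  keep <- tt <= tmax + 1e-9
  out <- new_curve(tt[keep], curve_value(curve, tt[keep], rule = 2),
                   curve$t_norm, curve$meta)
  if (any(!keep)) out$meta$truncated_at <- tmax
  out
}

#' Root-mean-square deviation between two curves on a shared grid
#'
#' @param a,b `maap_curve`s sampled on identical time grids (numeric vectors
#'   are also accepted)
#' @return `sqrt(mean((a - b)^2))`
#' @export
rmsd <- function(a, b) {
  va <- if (inherits(a, "maap_curve")) a$value else a
  vb <- if (inherits(b, "maap_curve")) b$value else b
  if (inherits(a, "maap_curve") && inherits(b, "maap_curve") &&
      !isTRUE(all.equal(a$time, b$time)))
    stop("curves are sampled on different time grids")
  if (length(va) != length(vb)) stop("curves have different lengths")
  sqrt(mean((va - vb)^2))
}

#' Fit a decay curve against the simulation library
#'
#' Exhaustive scan: the curve and every library curve are resampled onto the
#' fit grid (restricted to their common support) and compared by RMSD. The
#' best-fit cell and the `k` next-best alternatives are returned. Ties in
#' RMSD are broken deterministically towards the smallest `K_dep`, then the
#' smallest `F`.
#'
#' @param curve a `maap_curve`, normalized at the library's normalization
#'   time
#' @param library a `maap_library`
#' @param grid a [fit_grid()]
#' @param k number of runner-up fits to report
#' @return an object of class `maap_fit`: `F`, `K_dep`, `ratio`
#'   (G:F = (A_tot - F)/F), `rmsd`, `alternatives` (data.frame of the top
#'   `k + 1` cells), `window` (time span compared), `truncated`
#' @export
fit_curve <- function(curve, library, grid = fit_grid(), k = 9) {
  stopifnot(inherits(curve, "maap_curve"), inherits(library, "maap_library"))
  if (n_scenarios(library) == 0 || anyNA(library$curves))
    stop("library is empty or partial")
  if (abs(curve$t_norm - library$meta$t_norm) > 1e-9)
    stop("curve and library use different normalization times")
  tmax <- min(max(curve$time), max(library$times))
  rs <- resample_to_fit_grid(curve, grid)
  tt <- rs$time[rs$time <= tmax + 1e-9]
  vv <- rs$value[seq_along(tt)]
  dev <- vapply(seq_len(ncol(library$curves)), function(j) {
    lv <- stats::approx(library$times, library$curves[, j], tt)$y
    sqrt(mean((lv - vv)^2))
  }, numeric(1))
  ord <- order(dev, library$K_dep, library$F)
  top <- ord[seq_len(min(k + 1, length(ord)))]
  alt <- data.frame(F = library$F[top], K_dep = library$K_dep[top],
                    ratio = (library$spec$A_tot - library$F[top]) / library$F[top],
                    rmsd = dev[top])
  structure(
    list(F = alt$F[1], K_dep = alt$K_dep[1], ratio = alt$ratio[1],
         rmsd = alt$rmsd[1], alternatives = alt,
         window = range(tt),
         truncated = !is.null(rs$meta$truncated_at) || tmax < max(as.numeric(grid))),
    class = "maap_fit"
  )
}

#' @export
print.maap_fit <- function(x, ...) {
  cat(sprintf(
    "<maap_fit> F = %g uM, K_dep = %g /s (G:F ratio %.3g), RMSD = %.4g over [%.3g, %.3g] s%s\n",
    x$F, x$K_dep, x$ratio, x$rmsd, x$window[1], x$window[2],
    if (x$truncated) " (truncated support)" else ""))
  invisible(x)
}

#' Subtract the immobile fraction from a decay curve
#'
#' Signal remaining in the ROI at `t_ref` is attributed to filament-bound
#' (immobile) molecules; subtracting it isolates the freely diffusing
#' component over the first `window` seconds, after which filament turnover
#' starts to bias the correction. The corrected curve is renormalized to 1
#' at its normalization time and truncation to `window` is left to the
#' consumer (the diffusion fit), so that the late plateau remains
#' inspectable.
#'
#' @param curve a `maap_curve` extending beyond `t_ref`
#' @param t_ref reference time whose value defines the immobile fraction (s)
#' @param window duration after `t_norm` over which the correction is
#'   considered valid (s); recorded in `meta$immobile_window`
#' @return a corrected `maap_curve`, with `meta$immobile_fraction` set
#' @export
subtract_immobile_fraction <- function(curve, t_ref = 2.5, window = 1.5) {
  stopifnot(inherits(curve, "maap_curve"))
  if (max(curve$time) < t_ref)
    stop("curve does not extend to the immobile-fraction reference time")
  p <- curve_value(curve, t_ref)
  denom <- 1 - p  # value at t_norm is 1 by construction
  if (denom <= 0)
    stop("no mobile signal: curve value at t_norm does not exceed the plateau")
  out <- new_curve(curve$time, (curve$value - p) / denom, curve$t_norm,
                   utils::modifyList(curve$meta,
                                     list(immobile_fraction = p,
                                          immobile_window = window)))
  out
}

#' Fit the diffusion coefficient with diffusion-only simulations
#'
#' Compares a mobile-only (immobile-fraction-corrected) decay curve against
#' diffusion-only simulations for each candidate `D`, by RMSD over the early
#' window where diffusion dominates.
#'
#' @param curve a `maap_curve` (after [subtract_immobile_fraction()] for
#'   data containing filaments)
#' @param D_candidates diffusion coefficients to try (um^2/s)
#' @param grid,roi simulation domain, as in [simulate_photoactivation()]
#' @param window comparison window after `t_norm` (s)
#' @param fine comparison grid step (s)
#' @return list with `D` (best candidate), `rmsd`, and `table` (RMSD per
#'   candidate)
#' @export
fit_diffusion <- function(curve, D_candidates, grid, roi = NULL,
                          window = 1.5, fine = 0.05) {
  stopifnot(inherits(curve, "maap_curve"), length(D_candidates) >= 1)
  t_end <- curve$t_norm + window
  if (max(curve$time) < t_end) stop("curve shorter than the comparison window")
  tt <- seq(curve$t_norm, t_end, by = fine)
  vv <- curve_value(curve, tt)
  dev <- vapply(D_candidates, function(D) {
    ref <- simulate_diffusion_only(D, grid, roi, t_post = window + 0.2,
                                   t_norm = curve$t_norm)
    sqrt(mean((curve_value(ref, tt) - vv)^2))
  }, numeric(1))
  best <- order(dev, D_candidates)[1]
  list(D = D_candidates[best], rmsd = dev[best],
       table = data.frame(D = D_candidates, rmsd = dev))
}

#' Compare fitted parameters between two groups of experiments
#'
#' Per-parameter summary of two cohorts of [fit_curve()] results: the
#' percentiles drawn in box-and-whisker plots (5/25/50/75/95), mean with a
#' 95% confidence interval, a two-tailed two-sample t-test between the
#' groups (Welch by default; `pooled = TRUE` for the classical equal-variance
#' form), and the within-group Pearson correlation between `K_dep` and the
#' G:F ratio.
#'
#' @param groupA,groupB lists of `maap_fit` objects, or data.frames with
#'   columns `K_dep` and `ratio`
#' @param pooled use the pooled-variance t-test instead of Welch
#' @return an object of class `maap_cohorts`: `summary` (data.frame),
#'   `t_test` (per-parameter p-values and statistics), `correlation`
#'   (per-group Pearson r)
#' @export
cohort_stats <- function(groupA, groupB, pooled = FALSE) {
  ga <- fits_to_df(groupA); gb <- fits_to_df(groupB)
  if (nrow(ga) < 2 || nrow(gb) < 2) stop("need at least 2 fits per group")
  pars <- c("K_dep", "ratio")
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  summ <- do.call(rbind, lapply(pars, function(p) {
    do.call(rbind, lapply(list(A = ga, B = gb), function(g) {
      x <- g[[p]]
      ci <- tryCatch(stats::t.test(x)$conf.int, error = function(e) c(NA, NA))
      data.frame(parameter = p, n = length(x), mean = mean(x),
                 ci_lo = ci[1], ci_hi = ci[2],
                 t(stats::setNames(stats::quantile(x, qs),
                                   paste0("p", 100 * qs))))
    }))
  }))
  summ <- cbind(group = rep(c("A", "B"), length(pars)), summ)
  rownames(summ) <- NULL
  tt <- lapply(stats::setNames(pars, pars), function(p) {
    x <- ga[[p]]; y <- gb[[p]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate variance (grid-quantized fits often are): identical
      # constants compare equal, different constants separate perfectly
      return(if (isTRUE(all.equal(mean(x), mean(y))))
        list(p_value = 1, statistic = 0, df = NA_real_)
      else list(p_value = 0, statistic = Inf, df = NA_real_))
    }
    ht <- stats::t.test(x, y, var.equal = pooled)
    list(p_value = ht$p.value, statistic = unname(ht$statistic),
         df = unname(ht$parameter))
  })
  corr <- vapply(list(A = ga, B = gb), function(g)
    if (stats::sd(g$K_dep) == 0 || stats::sd(g$ratio) == 0) NA_real_
    else stats::cor(g$K_dep, g$ratio), numeric(1))
  structure(list(summary = summ, t_test = tt, correlation = corr,
                 pooled = pooled),
            class = "maap_cohorts")
}

#' @noRd
fits_to_df <- function(g) {
  if (is.data.frame(g)) {
    stopifnot(all(c("K_dep", "ratio") %in% names(g)))
    return(g)
  }
  do.call(rbind, lapply(g, function(f) {
    stopifnot(inherits(f, "maap_fit"))
    data.frame(F = f$F, K_dep = f$K_dep, ratio = f$ratio, rmsd = f$rmsd)
  }))
}

#' @export
print.maap_cohorts <- function(x, ...) {
  cat("<maap_cohorts>", if (x$pooled) "pooled-variance" else "Welch",
      "two-tailed t-test\n")
  for (p in names(x$t_test))
    cat(sprintf("  %s: p = %.3g (t = %.3g, df = %.3g)\n", p,
                x$t_test[[p]]$p_value, x$t_test[[p]]$statistic,
                x$t_test[[p]]$df))
  cat(sprintf("  Pearson r(K_dep, ratio): A = %.3g, B = %.3g\n",
              x$correlation[["A"]], x$correlation[["B"]]))
  invisible(x)
}

#' Read / write experimental decay curves
#'
#' Curves are stored as delimited text with two columns, time (s, relative
#' to the end of the activation pulse) and intensity; '#' lines are
#' comments, a single non-numeric header line is tolerated, and comma, tab
#' or whitespace delimiters are auto-detected. Input data are assumed
#' background-subtracted and normalized to the first post-activation frame;
#' set `renormalize = TRUE` to renormalize at `t_norm` by interpolation when
#' the frame times differ from the library convention.
#'
#' @param path file to read or write
#' @param t_norm normalization time the curve should carry (s)
#' @param renormalize divide by the interpolated value at `t_norm` instead
#'   of trusting the stored normalization
#' @return a `maap_curve`
#' @export
read_decay_curve <- function(path, t_norm = 0.035, renormalize = FALSE) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  if (!length(lines)) stop("no data in ", path)
  first <- strsplit(trimws(lines[1]), "[,;\t ]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "[,;\t ]+")
  bad <- lengths(parts) < 2
  if (any(bad)) stop("malformed row(s) in ", path)
  tt <- as.numeric(vapply(parts, `[[`, character(1), 1))
  vv <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(tt) || anyNA(vv)) stop("non-numeric values in ", path)
  o <- order(tt)
  tt <- tt[o]; vv <- vv[o]
  if (renormalize) return(normalize_curve(tt, vv, t_norm,
                                          meta = list(source = path)))
  new_curve(tt, vv, t_norm, meta = list(source = path))
}

#' @rdname read_decay_curve
#' @param curve the `maap_curve` to write
#' @param comment extra '#' comment lines to embed
#' @export
write_decay_curve <- function(curve, path, comment = character(0)) {
  stopifnot(inherits(curve, "maap_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", c(
    "maap decay curve: time_s, intensity (normalized)",
    sprintf("t_norm = %g s", curve$t_norm), comment)),
    "time_s,intensity",
    sprintf("%.17g,%.17g", curve$time, curve$value)), con)
  invisible(path)
}
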