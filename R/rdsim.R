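# Forward simulation of photoactivation and fluorescence decay.
#
# State: per-voxel concentrations of photoactivated G-actin (PA-G, diffusing)
# and photoactivated F-actin (PA-F, immobile), in uM. Because dark and PA
# forms share all rates and the bulk pools are at detailed balance, the total
# (dark + PA) fields stay uniform at (G0, F0) for all time; the dark pools
# are therefore represented implicitly as (G0 - PA-G, F0 - PA-F) and the
# laser source during the pulse is laser_rate * (steady state - PA) inside
# the ROI, applied to G and F alike. This halves the state relative to the
# explicit six-species scheme and is exactly equivalent to it under the
# steady-state assumption.
#
# Numerics: operator splitting per time step -- an implicit (backward-Euler)
# diffusion solve for PA-G on the masked grid with zero-flux boundaries,
# followed by the exact solution of the local linear exchange (+ laser)
# system. Both sub-steps are unconditionally stable and positivity
# preserving, and the exchange update conserves PA-G + PA-F exactly.

# exp(M * dt) for the 2x2 exchange/laser generator, closed form.
#' @noRd
expm2 <- function(M, dt) {
  mu <- (M[1, 1] + M[2, 2]) / 2
  N <- M - diag(mu, 2)
  delta2 <- N[1, 1]^2 + N[1, 2] * N[2, 1]  # -det(N); >= 0 for this kinetics
  delta <- sqrt(max(delta2, 0))
  if (delta * dt < 1e-8) {
    sh_over <- dt * (1 + (delta * dt)^2 / 6)
    ch <- 1 + (delta * dt)^2 / 2
  } else {
    sh_over <- sinh(delta * dt) / delta
    ch <- cosh(delta * dt)
  }
  exp(mu * dt) * (diag(ch, 2) + sh_over * N)
}

# Exact exchange update over dt for all voxels (no laser): PA-G <-> PA-F.
#' @noRd
exchange_update <- function(G, F, k_pol, K_dep, efac) {
  s <- k_pol + K_dep
  if (s == 0) return(list(G = G, F = F))
  tot <- G + F
  Geq <- (K_dep / s) * tot
  G <- Geq + (G - Geq) * efac
  list(G = G, F = tot - G)
}

#' Simulate photoactivation and decay of photoactivated actin
#'
#' Runs the full protocol: a `t_pulse`-long activation pulse that converts
#' dark actin (monomeric and filamentous alike) to its photoactivated form
#' inside the ROI cylinder while diffusion is already active, followed by
#' `t_post` seconds of free evolution in which PA-G diffuses and exchanges
#' with the immobile PA-F pool. The mean PA concentration over the ROI and
#' the total PA in the domain are recorded at every solver step.
#'
#' @param params a [sim_params()] object
#' @param grid a [voxelize()]d geometry
#' @param roi a [roi_spec()]; defaults to the geometry's [default_roi()]
#' @param snapshot_times times (s, relative to pulse end) at which to store
#'   the full PA-G and PA-F fields
#' @return an object of class `maap_sim`: `times` (s, relative to pulse end;
#'   negative during the pulse), `roi_raw` (mean PA in the ROI, uM),
#'   `total_pa` (total PA in the meshed domain, attomol-scaled uM um^3),
#'   `snapshots`, and the inputs
#' @export
simulate_photoactivation <- function(params, grid, roi = NULL,
                                     snapshot_times = NULL) {
  stopifnot(inherits(params, "maap_params"), inherits(grid, "maap_grid"))
  if (is.null(roi)) roi <- default_roi(grid$geometry)
  check_roi_inside(grid$geometry, roi)
  ridx <- roi_interior_index(grid, roi)
  n <- grid$n
  voxvol <- prod(grid$spacing)
  kp <- params$k_pol; kd <- params$K_dep; lam <- params$laser_rate
  D <- params$D

  G <- numeric(n); F <- numeric(n)
  nrec <- 0L
  times <- roim <- total <- numeric(0)
  snaps <- list()
  record <- function(t) {
    nrec <<- nrec + 1L
    times[nrec] <<- t
    roim[nrec] <<- mean(G[ridx] + F[ridx])
    total[nrec] <<- sum(G) + sum(F)
    if (length(snapshot_times) &&
        any(ok <- abs(snapshot_times - t) < 1e-6)) {
      snaps[[length(snaps) + 1L]] <<- list(time = snapshot_times[which(ok)[1]],
                                           G = G, F = F)
    }
  }

  # --- pulse phase -------------------------------------------------------
  # The reaction sub-step acts on disjoint voxel sets: inside the ROI the
  # exchange and the laser source form a 2x2 affine system solved exactly
  # (fixed point xss, propagator Elaser); elsewhere plain exchange applies.
  dtp <- params$dt_pulse
  npulse <- max(1L, round(params$t_pulse / dtp))
  dtp <- params$t_pulse / npulse
  Mlaser <- matrix(c(-(kp + lam), kp, kd, -(kd + lam)), 2, 2)
  Elaser <- expm2(Mlaser, dtp)
  xss <- solve(Mlaser, -lam * c(params$G0, params$F0))
  efac_p <- exp(-(kp + kd) * dtp)
  out_idx <- setdiff(seq_len(n), ridx)
  record(-params$t_pulse)
  for (k in seq_len(npulse)) {
    if (D > 0) G <- diffusion_step(grid, G, D * dtp)
    up <- exchange_update(G[out_idx], F[out_idx], kp, kd, efac_p)
    Gi <- G[ridx] - xss[1]; Fi <- F[ridx] - xss[2]
    G[out_idx] <- up$G; F[out_idx] <- up$F
    G[ridx] <- xss[1] + Elaser[1, 1] * Gi + Elaser[1, 2] * Fi
    F[ridx] <- xss[2] + Elaser[2, 1] * Gi + Elaser[2, 2] * Fi
    record(-params$t_pulse + k * dtp)
  }

  # --- decay phase -------------------------------------------------------
  dts <- decay_schedule(params$t_post, dt0 = min(params$dt_pulse, 1e-3))
  efacs <- stats::setNames(exp(-(kp + kd) * unique(dts)),
                           sprintf("%.12g", unique(dts)))
  t <- 0
  for (dt in dts) {
    if (D > 0) G <- diffusion_step(grid, G, D * dt)
    up <- exchange_update(G, F, kp, kd, efacs[[sprintf("%.12g", dt)]])
    G <- up$G; F <- up$F
    t <- t + dt
    record(round(t, 9))
  }

  structure(
    list(times = times, roi_raw = roim, total_pa = total * voxvol,
         roi_n = length(ridx), snapshots = snaps,
         params = params, roi = roi, grid_dims = grid$dims,
         grid_spacing = grid$spacing),
    class = "maap_sim"
  )
}

#' @export
print.maap_sim <- function(x, ...) {
  cat(sprintf(
    "<maap_sim> %d time points in [%.3f, %.3f] s; ROI mean at pulse end %.3g uM\n",
    length(x$times), min(x$times), max(x$times),
    stats::approx(x$times, x$roi_raw, 0)$y))
  invisible(x)
}

#' Mean photoactivated-actin concentration over the ROI
#'
#' Averages PA-G + PA-F over the ROI voxels for a series of stored fields.
#' The per-step ROI trace of a simulation is produced by the same reduction
#' internally; this operation exists to post-process stored snapshots (e.g.
#' of a simulation re-run with `snapshot_times`).
#'
#' @param fields a list of snapshots, each with elements `time`, `G`, `F`
#'   (as in `maap_sim$snapshots`)
#' @param grid the grid the fields live on
#' @param roi the readout region
#' @return data.frame with columns `time` and `roi_mean` (uM)
#' @export
roi_mean_timeseries <- function(fields, grid, roi) {
  ridx <- roi_interior_index(grid, roi)
  if (!length(fields)) stop("no fields supplied")
  data.frame(
    time = vapply(fields, `[[`, numeric(1), "time"),
    roi_mean = vapply(fields, function(f) mean(f$G[ridx] + f$F[ridx]),
                      numeric(1))
  )
}

#' Decay curve: normalized ROI intensity versus time
#'
#' Normalizes a raw ROI trace by its value at `t_norm` (linear interpolation
#' if `t_norm` is not sampled), mimicking the experimental normalization to
#' the first recorded frame. The returned curve starts exactly at `t_norm`
#' with value 1.
#'
#' @param x a `maap_sim`, or a numeric vector of times (s, relative to pulse
#'   end)
#' @param values raw intensities, if `x` is a time vector
#' @param t_norm normalization time (s)
#' @param meta optional metadata list carried along
#' @return an object of class `maap_curve` with fields `time`, `value`,
#'   `t_norm`, `meta`
#' @export
normalize_curve <- function(x, values = NULL, t_norm = 0.035, meta = list()) {
  if (inherits(x, "maap_sim")) {
    meta <- utils::modifyList(list(params = x$params, roi = x$roi), meta)
    values <- x$roi_raw
    x <- x$times
  }
  stopifnot(is.numeric(x), is.numeric(values), length(x) == length(values))
  if (t_norm < min(x) || t_norm > max(x))
    stop("t_norm outside the sampled time range")
  v0 <- stats::approx(x, values, t_norm)$y
  if (!is.finite(v0) || v0 <= 0)
    stop("value at t_norm is not positive; cannot normalize")
  keep <- x > t_norm + 1e-12
  tt <- c(t_norm, x[keep])
  vv <- c(1, values[keep] / v0)
  new_curve(tt, vv, t_norm, meta)
}

#' @noRd
new_curve <- function(time, value, t_norm, meta = list()) {
  stopifnot(all(diff(time) > 0))
  structure(list(time = time, value = value, t_norm = t_norm, meta = meta),
            class = "maap_curve")
}

#' Interpolate a decay curve
#' @param curve a `maap_curve`
#' @param t times (s)
#' @param rule interpolation rule passed to [stats::approx()]
#' @return interpolated values
#' @export
curve_value <- function(curve, t, rule = 1) {
  stats::approx(curve$time, curve$value, t, rule = rule)$y
}

#' @export
print.maap_curve <- function(x, ...) {
  cat(sprintf(
    "<maap_curve> %d points, t in [%.3f, %.3f] s (normalized at %g s); final value %.3f\n",
    length(x$time), min(x$time), max(x$time), x$t_norm,
    x$value[length(x$value)]))
  invisible(x)
}

#' Diffusion-only decay simulation
#'
#' The protocol of [simulate_photoactivation()] with no filamentous pool
#' (`F0 = 0`, `K_dep = 0`): all actin diffuses freely, as for
#' polymerization-deficient actin point mutants. Used to measure the
#' diffusion coefficient and to quantify activation- and delay-phase losses.
#'
#' @param D diffusion coefficient (um^2/s), must be positive
#' @param grid,roi as in [simulate_photoactivation()]
#' @param t_post,t_norm,... protocol overrides passed to [sim_params()]
#' @param keep_sim attach the raw simulation as `meta$sim` of the curve
#' @return a `maap_curve`, normalized at `t_norm`
#' @export
simulate_diffusion_only <- function(D, grid, roi = NULL, t_post = 25,
                                    t_norm = 0.035, keep_sim = FALSE, ...) {
  if (D <= 0) stop("D must be positive for a diffusion-only simulation")
  p <- sim_params(D = D, F0 = 0, K_dep = 0, t_post = t_post, t_norm = t_norm,
                  ...)
  sim <- simulate_photoactivation(p, grid, roi)
  cur <- normalize_curve(sim, t_norm = t_norm)
  if (keep_sim) cur$meta$sim <- sim
  cur
}

#' Fluorescence loss during a post-activation delay
#'
#' Fraction of the ROI signal present at the end of the activation pulse that
#' has left the ROI a given delay later, in a diffusion-only system. This is
#' the loss that goes unobserved when the first frame is recorded `delay`
#' seconds after the pulse: it is invisible in first-frame-normalized data
#' but substantial even at moderate diffusion coefficients.
#'
#' @param D diffusion coefficient (um^2/s)
#' @param delay one or more delays (s)
#' @param grid,roi as in [simulate_photoactivation()]
#' @param sim optionally, a precomputed diffusion-only `maap_sim` to read
#'   the losses from
#' @return named numeric vector of fractional losses in `[0, 1]`
#' @export
delay_loss <- function(D, delay, grid = NULL, roi = NULL, sim = NULL) {
  stopifnot(all(delay >= 0))
  if (is.null(sim)) {
    p <- sim_params(D = D, F0 = 0, K_dep = 0,
                    t_post = max(max(delay), 0.05) + 0.05)
    sim <- simulate_photoactivation(p, grid, roi)
  }
  v0 <- stats::approx(sim$times, sim$roi_raw, 0)$y
  v <- stats::approx(sim$times, sim$roi_raw, delay)$y
  stats::setNames(1 - v / v0, sprintf("%g", delay))
}

# Default output schedule for stored library curves: the normalization frame,
# then video rate (30 frames/s) out to 3 s, then 10 frames/s to t_post.
#' @noRd
output_schedule <- function(t_norm = 0.035, t_post = 25) {
  fine <- t_norm + seq(0, by = 1 / 30, length.out = floor((min(3, t_post) - t_norm) * 30) + 1)
  if (t_post <= 3) return(fine)
  coarse <- seq(fine[length(fine)] + 0.1, t_post, by = 0.1)
  c(fine, coarse)
}
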